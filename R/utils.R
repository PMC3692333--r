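# internal helpers shared across modules

#' Round half away from zero
#'
#' Reporting rule for percentage cells: two decimals, ties rounded up
#' (5 always moves away from zero), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded helpers don't perturb sessions
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_param <- function(...) stop(..., call. = FALSE)
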