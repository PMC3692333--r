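# Per-locus exclusion rules and non-conformity (mismatching-locus) tables.
#
# Duo (motherless) exclusion: alleged father and child share no allele.
# Trio exclusion: the alleged father carries no obligate paternal allele,
# i.e. no child allele that must have come from the father given the
# mother's genotype. Non-conformity counts per pair are tabulated into
# distribution / cumulative / adjusted-rate tables, the study's main
# exclusion-side output.

as_genotype <- function(g, what) {
  if (length(g) != 2 || anyNA(g)) stop_param("'", what, "' must be a length-2 genotype")
  g
}

#' Duo (motherless) per-locus exclusion
#'
#' The alleged father is excluded at a locus exactly when his allele set and
#' the child's are disjoint. The rule is symmetric in its arguments.
#'
#' @param alleged_father,child length-2 vectors of allele labels (or
#'   indices) at one locus.
#' @return logical: `TRUE` if excluded.
#' @examples
#' duo_locus_excluded(c("a", "b"), c("a", "c"))  # share a -> FALSE
#' duo_locus_excluded(c("a", "b"), c("c", "d"))  # TRUE
#' @export
duo_locus_excluded <- function(alleged_father, child) {
  f <- as_genotype(alleged_father, "alleged_father")
  c_ <- as_genotype(child, "child")
  !any(f %in% c_)
}

#' Obligate paternal alleles
#'
#' The child allele(s) that must have been transmitted by the father, given
#' the mother's genotype: a homozygous child `aa` obligates `a`; a
#' heterozygous child `ab` obligates the allele the mother does not carry,
#' or both `a` and `b` when the mother carries both.
#'
#' @param mother,child length-2 genotypes at one locus.
#' @return vector of obligate alleles (length 1 or 2).
#' @examples
#' obligate_paternal_alleles(c("a", "a"), c("a", "b"))  # "b"
#' obligate_paternal_alleles(c("a", "b"), c("a", "b"))  # "a" "b"
#' @export
obligate_paternal_alleles <- function(mother, child) {
  m <- as_genotype(mother, "mother")
  c_ <- as_genotype(child, "child")
  if (c_[1] == c_[2]) {
    if (!c_[1] %in% m) {
      stop("mother and child are Mendelian-incompatible at this locus", call. = FALSE)
    }
    return(c_[1])
  }
  has1 <- c_[1] %in% m
  has2 <- c_[2] %in% m
  if (has1 && has2) c_ else if (has1) c_[2] else if (has2) c_[1] else {
    stop("mother and child are Mendelian-incompatible at this locus", call. = FALSE)
  }
}

#' Trio per-locus exclusion
#'
#' The alleged father is excluded when he carries none of the obligate
#' paternal alleles. Duo exclusion implies trio exclusion, since the
#' obligate set is a subset of the child's alleles.
#'
#' @param alleged_father,mother,child length-2 genotypes at one locus; the
#'   mother must be Mendelian-compatible with the child (always true for
#'   true mothers in a mutation-free simulation).
#' @return logical: `TRUE` if excluded.
#' @examples
#' trio_locus_excluded(c("b", "c"), c("a", "a"), c("a", "b"))  # FALSE
#' trio_locus_excluded(c("c", "d"), c("a", "b"), c("a", "b"))  # TRUE
#' @export
trio_locus_excluded <- function(alleged_father, mother, child) {
  f <- as_genotype(alleged_father, "alleged_father")
  obl <- obligate_paternal_alleles(mother, child)
  !any(f %in% obl)
}

#' Count non-matching loci for one scenario pairing in one family
#'
#' Applies the duo or trio per-locus exclusion rule across the panel for
#' the pairing's alleged father / (mother /) child roles.
#'
#' @param pairing one row of [scenario_pairings()] (a list or one-row
#'   data.frame with `relationship`, `mode`, `father_role`, `mother_role`,
#'   `child_role`).
#' @param family an `str_family`.
#' @return a list (`mismatch_record`) with `family_id`, `relationship`,
#'   `mode` and `k`, the number of non-matching loci in `[0, L]`.
#' @examples
#' fs <- generate_synthetic_frequencies(n_loci = 5, seed = 2)
#' fam <- simulate_population(fs, 1, seed = 3)[[1]]
#' sc <- scenario_pairings()
#' count_nonconformities(sc[sc$relationship == "parent" & sc$mode == "duo", ], fam)
#' @export
count_nonconformities <- function(pairing, family) {
  stopifnot(inherits(family, "str_family"))
  pairing <- as.list(pairing)
  need <- c(pairing$father_role, pairing$child_role,
            if (identical(pairing$mode, "trio")) pairing$mother_role)
  missing_roles <- setdiff(need, names(family$members))
  if (length(missing_roles)) {
    stop_param("family lacks role(s): ", paste(missing_roles, collapse = ", "))
  }
  gf <- family$members[[pairing$father_role]]$genotypes
  gc <- family$members[[pairing$child_role]]$genotypes
  L <- nrow(gc)
  if (identical(pairing$mode, "duo")) {
    k <- sum(vapply(seq_len(L), function(l) duo_locus_excluded(gf[l, ], gc[l, ]), logical(1)))
  } else {
    gm <- family$members[[pairing$mother_role]]$genotypes
    k <- sum(vapply(seq_len(L), function(l) trio_locus_excluded(gf[l, ], gm[l, ], gc[l, ]),
                    logical(1)))
  }
  structure(list(family_id = family$family_id, relationship = pairing$relationship,
                 mode = pairing$mode, k = as.integer(k)),
            class = "mismatch_record")
}

#' Agresti-Coull (modified Wald) proportion estimate
#'
#' With `z` the exact standard-normal `1 - alpha/2` quantile, the adjusted
#' sample size is `n~ = n + z^2`, the adjusted proportion
#' `p~ = (x + z^2/2) / n~`, and the interval half-width
#' `z * sqrt(p~ (1 - p~) / n~)`. Both are reported as percentages; the
#' adjusted center (not the raw proportion `x/n`) is the reported rate, so
#' it is strictly positive even at `x = 0`. Values are kept unrounded;
#' rounding to two decimals (half-up) happens only in formatting.
#'
#' @param x success count(s), `0 <= x <= n` (vectorized).
#' @param n trial count, >= 1.
#' @param alpha significance level in (0, 1); 0.05 gives the conventional
#'   95% interval.
#' @return a data.frame of class `proportion_estimate` with columns `x`,
#'   `n`, `alpha`, `center` and `half_width` (both in percent, unrounded).
#' @examples
#' agresti_coull(1902, 10000)   # 19.03 +/- 0.77
#' agresti_coull(0, 10000)      # 0.02 +/- 0.03: positive despite x = 0
#' @export
agresti_coull <- function(x, n, alpha = 0.05) {
  if (length(n) != 1 || is.na(n) || n < 1) stop_param("'n' must be a single integer >= 1")
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop_param("'alpha' must be in (0, 1)")
  }
  if (anyNA(x) || any(x < 0) || any(x > n)) stop_param("'x' must satisfy 0 <= x <= n")
  z <- stats::qnorm(1 - alpha / 2)
  n_adj <- n + z^2
  p_adj <- (x + z^2 / 2) / n_adj
  structure(
    data.frame(x = x, n = n, alpha = alpha,
               center = 100 * p_adj,
               half_width = 100 * z * sqrt(p_adj * (1 - p_adj) / n_adj)),
    class = c("proportion_estimate", "data.frame")
  )
}

#' Format a proportion estimate as "center ± half-width"
#'
#' @param x a `proportion_estimate`.
#' @param digits decimals (default 2, half-up).
#' @param ... unused.
#' @return character vector like `"19.03 ± 0.77"`.
#' @export
format.proportion_estimate <- function(x, digits = 2, ...) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          round_half_up(x$center, digits), round_half_up(x$half_width, digits))
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Build a non-conformity distribution table
#'
#' Tabulates mismatch counts for one relationship x mode into the study's
#' three-row layout: per-k pair counts, running cumulative counts
#' (pairs with at most k non-matching loci, the accumulative non-exclusion
#' numerators), and the Agresti-Coull adjusted rate with interval
#' half-width for each cumulative count.
#'
#' @param records mismatch records sharing one relationship and mode:
#'   either a list of `mismatch_record` objects or a data.frame with
#'   columns `relationship`, `mode`, `k`.
#' @param L panel locus count (k runs 0..L).
#' @param alpha significance level for the intervals.
#' @return an object of class `nonconformity_table`: list with
#'   `relationship`, `mode`, `n`, `L`, `alpha`, `counts` (length `L + 1`,
#'   named `k0`..`kL`), `cumulative`, and `rate`, a [agresti_coull()]
#'   estimate per k.
#' @examples
#' recs <- data.frame(relationship = "sibling", mode = "duo",
#'                    k = c(0, 0, 1, 2, 2, 3))
#' build_nonconformity_table(recs, L = 3)
#' @export
build_nonconformity_table <- function(records, L, alpha = 0.05) {
  if (inherits(records, "mismatch_record")) records <- list(records)
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(relationship = r$relationship, mode = r$mode, k = r$k)
    }))
  }
  if (is.null(records) || nrow(records) == 0) stop_param("no mismatch records supplied")
  rel <- unique(records$relationship)
  mode <- unique(records$mode)
  if (length(rel) != 1 || length(mode) != 1) {
    stop_param("records must share one relationship and one mode")
  }
  if (any(records$k < 0) || any(records$k > L)) stop_param("mismatch counts outside [0, L]")
  n <- nrow(records)
  counts <- tabulate(records$k + 1L, nbins = L + 1L)
  names(counts) <- paste0("k", 0:L)
  cumulative <- cumsum(counts)
  structure(list(relationship = rel, mode = mode, n = n, L = L, alpha = alpha,
                 counts = counts, cumulative = cumulative,
                 rate = agresti_coull(cumulative, n, alpha)),
            class = "nonconformity_table")
}

#' @export
print.nonconformity_table <- function(x, max_k = x$L, ...) {
  cat(sprintf("Non-conformity table: %s as alleged father, %s mode (n = %d, %d loci)\n",
              x$relationship, x$mode, x$n, x$L))
  kk <- 0:max_k
  m <- rbind(count = x$counts[kk + 1], cumulative = x$cumulative[kk + 1])
  rates <- format(x$rate)[kk + 1]
  out <- rbind(format(m), rate = rates)
  colnames(out) <- paste0("k=", kk)
  print(out, quote = FALSE)
  invisible(x)
}
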