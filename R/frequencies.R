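# STR allele-frequency sets: construction, synthetic generation, CSV I/O.
#
# A frequency set is the population model: one entry per locus with allele
# labels (opaque tokens such as "9.3" -- repeat-count semantics are never
# used by any computation) and frequencies that are strictly positive and
# sum to one. Founder sampling and random-man denominators both read from it.

#' Construct an STR allele-frequency set
#'
#' Bundles per-locus allele labels and frequencies into a validated
#' `freq_set` object, the population model used for Hardy-Weinberg founder
#' sampling and paternity-index denominators.
#'
#' @param loci a list; each element a list with components `locus` (scalar
#'   character name), `alleles` (character vector of unique labels, length
#'   >= 2) and `freqs` (positive numeric vector summing to 1 within 1e-9).
#' @return an object of class `freq_set`: the validated list of loci, with
#'   one element per locus in panel order.
#' @examples
#' fs <- freq_set(list(
#'   list(locus = "L1", alleles = c("9", "9.3", "10"),
#'        freqs = c(0.2, 0.3, 0.5))
#' ))
#' print(fs)
#' @export
freq_set <- function(loci) {
  if (!is.list(loci) || length(loci) < 1) {
    stop_param("'loci' must be a non-empty list of locus entries")
  }
  loci <- lapply(loci, validate_locus)
  nms <- vapply(loci, function(l) l$locus, character(1))
  if (anyDuplicated(nms)) {
    stop_param("duplicate locus names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(loci) <- nms
  structure(loci, class = "freq_set")
}

validate_locus <- function(l) {
  if (!is.list(l) || !all(c("locus", "alleles", "freqs") %in% names(l))) {
    stop_param("each locus needs components 'locus', 'alleles', 'freqs'")
  }
  l$locus <- as.character(l$locus)
  l$alleles <- as.character(l$alleles)
  l$freqs <- as.numeric(l$freqs)
  if (length(l$alleles) < 2) stop_param("locus '", l$locus, "': at least 2 alleles required")
  if (anyDuplicated(l$alleles)) stop_param("locus '", l$locus, "': duplicate allele labels")
  if (length(l$freqs) != length(l$alleles)) {
    stop_param("locus '", l$locus, "': allele/frequency length mismatch")
  }
  if (any(l$freqs <= 0)) stop_param("locus '", l$locus, "': frequencies must be > 0")
  if (abs(sum(l$freqs) - 1) > 1e-9) {
    stop_param("locus '", l$locus, "': frequencies sum to ", format(sum(l$freqs)),
               ", not 1")
  }
  l[c("locus", "alleles", "freqs")]
}

#' Number of loci in a frequency set
#' @param freqs a `freq_set`.
#' @return integer locus count.
#' @export
n_loci <- function(freqs) {
  stopifnot(inherits(freqs, "freq_set"))
  length(freqs)
}

#' @export
print.freq_set <- function(x, ...) {
  k <- lengths(lapply(x, `[[`, "alleles"))
  het <- expected_heterozygosity(x)
  cat("STR allele-frequency set:", length(x), "loci\n")
  cat(sprintf("  alleles per locus: %d-%d; mean expected heterozygosity %.3f\n",
              min(k), max(k), mean(het)))
  invisible(x)
}

#' Per-locus expected heterozygosity
#'
#' Computes `1 - sum(p^2)` at each locus, the probability that a random
#' Hardy-Weinberg genotype is heterozygous. Forensic identification panels
#' typically sit around 0.75-0.90.
#'
#' @param freqs a `freq_set`.
#' @return named numeric vector, one value per locus.
#' @export
expected_heterozygosity <- function(freqs) {
  stopifnot(inherits(freqs, "freq_set"))
  vapply(freqs, function(l) 1 - sum(l$freqs^2), numeric(1))
}

#' Generate a synthetic forensic-style STR frequency set
#'
#' Draws a stand-in allele-frequency panel emulating the multi-allelic,
#' high-heterozygosity character of a 15-locus forensic identification kit.
#' Per locus, the allele count is uniform on `allele_count_range` and the
#' frequency vector is a symmetric Dirichlet draw with the given
#' concentration, floored at 1e-4 and renormalized so no allele has zero
#' probability (which would make paternity indices unbounded).
#'
#' @param n_loci number of loci (default 15).
#' @param allele_count_range integer length-2 vector, inclusive bounds for
#'   the per-locus allele count; must lie within \[2, 30\].
#' @param concentration positive Dirichlet concentration; 1 gives flat
#'   (uniform-simplex) draws, larger values more even frequencies.
#' @param seed integer seed; identical seed gives an identical panel. `NULL`
#'   uses the current RNG state.
#' @return a [freq_set] with loci named `"L01"`, `"L02"`, ... and allele
#'   labels `"a01"`, `"a02"`, ...
#' @examples
#' fs <- generate_synthetic_frequencies(seed = 1)
#' n_loci(fs)
#' mean(expected_heterozygosity(fs))
#' @export
generate_synthetic_frequencies <- function(n_loci = 15,
                                           allele_count_range = c(8, 15),
                                           concentration = 1,
                                           seed = NULL) {
  if (length(n_loci) != 1 || is.na(n_loci) || n_loci < 1) {
    stop_param("'n_loci' must be a single integer >= 1")
  }
  r <- as.integer(allele_count_range)
  if (length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < 2 || r[2] > 30) {
    stop_param("'allele_count_range' must be an increasing integer pair within [2, 30]")
  }
  if (length(concentration) != 1 || is.na(concentration) || concentration <= 0) {
    stop_param("'concentration' must be a single positive number")
  }
  with_seed(seed, {
    loci <- lapply(seq_len(n_loci), function(i) {
      k <- sample(seq.int(r[1], r[2]), 1)
      g <- stats::rgamma(k, shape = concentration)
      p <- g / sum(g)
      p <- pmax(p, 1e-4)
      p <- p / sum(p)
      list(locus = sprintf("L%02d", i),
           alleles = sprintf("a%02d", seq_len(k)),
           freqs = p)
    })
    freq_set(loci)
  })
}

#' Read an allele-frequency table from CSV
#'
#' Expects the dialect `locus,allele,frequency` (UTF-8, one row per allele,
#' loci in panel order). Frequencies at each locus must sum to 1 within
#' 1e-3; sums deviating by more than 1e-6 are renormalized with a warning.
#'
#' @param path file path.
#' @return a [freq_set].
#' @seealso [write_frequency_csv()] for the inverse; the round trip
#'   reproduces the set up to renormalization.
#' @export
read_frequency_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character", "numeric"),
                        strip.white = TRUE)
  if (!identical(names(df), c("locus", "allele", "frequency"))) {
    stop_param("frequency CSV must have header 'locus,allele,frequency', got: ",
               paste(names(df), collapse = ","))
  }
  if (anyDuplicated(df[c("locus", "allele")])) {
    dup <- df[duplicated(df[c("locus", "allele")]), ]
    stop_param("duplicate (locus, allele) rows, e.g. ", dup$locus[1], "/", dup$allele[1])
  }
  loci_order <- unique(df$locus)
  loci <- lapply(loci_order, function(nm) {
    sub <- df[df$locus == nm, ]
    s <- sum(sub$frequency)
    if (abs(s - 1) > 1e-3) {
      stop_param("locus '", nm, "': frequencies sum to ", format(s),
                 " (deviation > 1e-3)")
    }
    if (abs(s - 1) > 1e-6) {
      warning("locus '", nm, "': frequencies sum to ", format(s),
              "; renormalizing", call. = FALSE)
    }
    list(locus = nm, alleles = sub$allele, freqs = sub$frequency / s)
  })
  freq_set(loci)
}

#' Write an allele-frequency table to CSV
#'
#' @param freqs a [freq_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_csv <- function(freqs, path) {
  stopifnot(inherits(freqs, "freq_set"))
  df <- do.call(rbind, lapply(freqs, function(l) {
    data.frame(locus = l$locus, allele = l$alleles, frequency = l$freqs)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
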