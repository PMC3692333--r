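# Paternity index (likelihood ratio) calculations.
#
# Per locus, the PI compares P(genotypes | tested man is the father)
# against P(genotypes | a random man is the father). In the duo case the
# untyped mother is marginalized over population frequencies; in the trio
# case the mother's transmitted allele is marginalized uniformly over her
# two alleles. Combined LR is the product over loci; excluded loci carry
# PI = 0, which annihilates the product, so pairs with any excluded locus
# never enter log-LR summaries. Logs are base 10 throughout.

locus_prob <- function(locus, alleles) {
  if (is.numeric(alleles)) {
    idx <- as.integer(alleles)
    if (any(idx < 1) || any(idx > length(locus$alleles))) {
      stop_param("allele index outside locus '", locus$locus, "' allele set")
    }
  } else {
    idx <- match(as.character(alleles), locus$alleles)
    if (anyNA(idx)) {
      stop_param("allele '", alleles[which(is.na(idx))[1]], "' absent from locus '",
                 locus$locus, "'")
    }
  }
  locus$freqs[idx]
}

# P(child genotype {c1,c2} | one parental allele = a, other from population)
child_prob_given_allele <- function(a, child, p_child) {
  if (child[1] == child[2]) {
    if (a == child[1]) p_child[1] else 0
  } else {
    (a == child[1]) * p_child[2] + (a == child[2]) * p_child[1]
  }
}

#' Duo (motherless) paternity index at one locus
#'
#' Numerator: probability of the child's genotype when the tested man
#' transmits one of his alleles uniformly and the untyped mother
#' contributes an allele by population frequency. Denominator: the
#' Hardy-Weinberg probability of the child's genotype (random man).
#' Excluded pairs (no shared allele) give PI = 0.
#'
#' @param alleged_father,child length-2 genotypes (allele labels, or
#'   indices into the locus's allele vector).
#' @param locus one locus entry of a [freq_set] (list with `locus`,
#'   `alleles`, `freqs`).
#' @return the paternity index, a nonnegative number.
#' @examples
#' loc <- list(locus = "L", alleles = c("a", "b", "c", "d"),
#'             freqs = c(0.5, 0.25, 0.15, 0.1))
#' duo_pi(c("a", "a"), c("a", "a"), loc)  # 1 / p_a = 2
#' duo_pi(c("c", "d"), c("a", "b"), loc)  # excluded -> 0
#' @export
duo_pi <- function(alleged_father, child, locus) {
  f <- as_genotype(alleged_father, "alleged_father")
  c_ <- as_genotype(child, "child")
  p_c <- locus_prob(locus, c_)
  locus_prob(locus, f)  # validates father's alleles against the locus
  num <- mean(vapply(f, child_prob_given_allele, numeric(1),
                     child = c_, p_child = p_c))
  den <- if (c_[1] == c_[2]) p_c[1]^2 else 2 * p_c[1] * p_c[2]
  num / den
}

#' Trio paternity index at one locus
#'
#' Numerator: probability of the child's genotype when the mother and the
#' tested man each transmit one of their alleles uniformly. Denominator:
#' same with the paternal allele drawn from population frequencies.
#' Excluded configurations (father carries no obligate paternal allele)
#' give PI = 0.
#'
#' @param alleged_father,mother,child length-2 genotypes; mother must be
#'   Mendelian-compatible with the child.
#' @param locus one locus entry of a [freq_set].
#' @return the paternity index, a nonnegative number.
#' @examples
#' loc <- list(locus = "L", alleles = c("a", "b"), freqs = c(0.3, 0.7))
#' trio_pi(c("b", "b"), c("a", "a"), c("a", "b"), loc)  # 1 / p_b
#' @export
trio_pi <- function(alleged_father, mother, child, locus) {
  f <- as_genotype(alleged_father, "alleged_father")
  m <- as_genotype(mother, "mother")
  c_ <- as_genotype(child, "child")
  obligate_paternal_alleles(m, c_)  # errors on mother-child incompatibility
  p_c <- locus_prob(locus, c_)
  locus_prob(locus, f)
  matches <- function(mm, ff) {
    if (c_[1] == c_[2]) mm == c_[1] && ff == c_[1]
    else (mm == c_[1] && ff == c_[2]) || (mm == c_[2] && ff == c_[1])
  }
  num <- mean(c(matches(m[1], f[1]), matches(m[1], f[2]),
                matches(m[2], f[1]), matches(m[2], f[2])))
  den <- mean(vapply(m, child_prob_given_allele, numeric(1),
                     child = c_, p_child = p_c))
  num / den
}

#' Combine per-locus paternity indices into a pair-level likelihood ratio
#'
#' The combined LR is the product over loci. The base-10 log LR is defined
#' only when every locus PI is positive; a single zero (an excluded locus)
#' flags the pair as excluded, with no log LR.
#'
#' @param per_locus numeric vector of per-locus PIs, one per panel locus.
#' @param relationship,mode,family_id optional identifiers carried on the
#'   result.
#' @param prior prior probability of paternity for the posterior
#'   conversion (default 0.5).
#' @return an object of class `pair_lr`: list with `lr`, `log_lr` (`NA` if
#'   excluded), `excluded`, `probability_of_paternity` (percent, `NA` if
#'   excluded) and the identifiers.
#' @examples
#' combine_lr(rep(10, 15))$log_lr   # 15
#' combine_lr(c(2, 0, 3))$excluded  # TRUE
#' @export
combine_lr <- function(per_locus, relationship = NA_character_,
                       mode = NA_character_, family_id = NA_integer_,
                       prior = 0.5) {
  if (anyNA(per_locus) || any(per_locus < 0)) {
    stop_param("per-locus PIs must be nonnegative numbers")
  }
  excluded <- any(per_locus == 0)
  log_lr <- if (excluded) NA_real_ else sum(log10(per_locus))
  structure(list(
    relationship = relationship, mode = mode, family_id = family_id,
    lr = prod(per_locus), log_lr = log_lr, excluded = excluded,
    probability_of_paternity =
      if (excluded) NA_real_ else probability_of_paternity_log10(log_lr, prior)
  ), class = "pair_lr")
}

#' @export
print.pair_lr <- function(x, ...) {
  if (x$excluded) {
    cat("Pair excluded (some locus PI = 0); LR = 0\n")
  } else {
    cat(sprintf("Combined LR = %.4g, log10 LR = %.4f, P(paternity) = %.4f%%\n",
                x$lr, x$log_lr, x$probability_of_paternity))
  }
  invisible(x)
}

#' Probability of paternity from a likelihood ratio
#'
#' The posterior probability (percent) that the tested man is the father:
#' `W = 100 * LR * prior / (LR * prior + 1 - prior)`. At the conventional
#' flat prior 0.5 this is `100 * LR / (LR + 1)`.
#'
#' @param lr positive likelihood ratio(s).
#' @param prior prior probability of paternity in (0, 1).
#' @return percentage(s) in (0, 100).
#' @examples
#' probability_of_paternity(10^2.8206)  # 99.8491
#' probability_of_paternity(1)          # 50
#' @export
probability_of_paternity <- function(lr, prior = 0.5) {
  if (anyNA(lr) || any(lr <= 0)) stop_param("'lr' must be positive")
  if (length(prior) != 1 || is.na(prior) || prior <= 0 || prior >= 1) {
    stop_param("'prior' must be in (0, 1)")
  }
  100 * lr * prior / (lr * prior + 1 - prior)
}

# log10-scale version, numerically safe for very large LRs
probability_of_paternity_log10 <- function(log_lr, prior = 0.5) {
  odds <- 10^log_lr * prior / (1 - prior)
  ifelse(is.infinite(odds), 100, 100 * odds / (odds + 1))
}

#' Summarize log likelihood ratios over non-excluded pairs
#'
#' Computes the count, minimum, maximum and mean of base-10 log LRs over
#' pairs with positive combined LR, with a t-based confidence half-width
#' of the mean (`t_{1-alpha/2, n-1} * sd / sqrt(n)`) and
#' probability-of-paternity conversions of each statistic. With a single
#' pair the half-width is undefined; with none, all statistics are absent.
#'
#' @param pairs either a numeric vector of log10 LRs (taken to be the
#'   non-excluded pairs) or a list of [combine_lr()] `pair_lr` objects,
#'   from which excluded pairs are dropped.
#' @param alpha significance level for the half-width (default 0.05).
#' @param prior prior probability of paternity for the conversions.
#' @return an object of class `lr_summary`: list with `relationship`,
#'   `mode`, `n_nonexcluded`, `min_log_lr`, `max_log_lr`, `mean_log_lr`,
#'   `ci_half_width` and `prob` (percent conversions of min/max/mean).
#' @examples
#' s <- summarize_log_lr(c(2.8206, 3.2468))
#' s$mean_log_lr       # 3.0337
#' s$ci_half_width     # ~2.71 (t with 1 df)
#' @export
summarize_log_lr <- function(pairs, alpha = 0.05, prior = 0.5) {
  relationship <- NA_character_
  mode <- NA_character_
  if (is.list(pairs) && length(pairs) && inherits(pairs[[1]], "pair_lr")) {
    relationship <- pairs[[1]]$relationship
    mode <- pairs[[1]]$mode
    x <- vapply(pairs, `[[`, numeric(1), "log_lr")
    x <- x[!vapply(pairs, `[[`, logical(1), "excluded")]
  } else {
    x <- as.numeric(pairs)
    x <- x[!is.na(x)]
  }
  n <- length(x)
  if (n == 0) {
    stats <- list(min_log_lr = NA_real_, max_log_lr = NA_real_,
                  mean_log_lr = NA_real_, ci_half_width = NA_real_)
  } else {
    hw <- if (n >= 2) {
      stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(x) / sqrt(n)
    } else {
      NA_real_
    }
    stats <- list(min_log_lr = min(x), max_log_lr = max(x),
                  mean_log_lr = mean(x), ci_half_width = hw)
  }
  prob <- lapply(stats[c("min_log_lr", "max_log_lr", "mean_log_lr")], function(v) {
    if (is.na(v)) NA_real_ else probability_of_paternity_log10(v, prior)
  })
  names(prob) <- c("min", "max", "mean")
  structure(c(list(relationship = relationship, mode = mode,
                   n_nonexcluded = n, alpha = alpha),
              stats, list(prob = prob)),
            class = "lr_summary")
}

#' @export
print.lr_summary <- function(x, ...) {
  hdr <- if (!is.na(x$relationship)) {
    sprintf("Log10 LR summary: %s as alleged father, %s mode\n", x$relationship, x$mode)
  } else {
    "Log10 LR summary\n"
  }
  cat(hdr)
  cat("  non-excluded pairs:", x$n_nonexcluded, "\n")
  if (x$n_nonexcluded >= 1) {
    fmt <- function(v, p) sprintf("%.4f (%.4f%%)", v, p)
    cat("  min: ", fmt(x$min_log_lr, x$prob$min), "\n")
    cat("  max: ", fmt(x$max_log_lr, x$prob$max), "\n")
    if (is.na(x$ci_half_width)) {
      cat("  mean:", fmt(x$mean_log_lr, x$prob$mean), "\n")
    } else {
      cat(sprintf("  mean: %.4f ± %.4f (%.4f%%)\n",
                  x$mean_log_lr, x$ci_half_width, x$prob$mean))
    }
  } else {
    cat("  (all pairs excluded; no LR statistics)\n")
  }
  invisible(x)
}
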