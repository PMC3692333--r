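# Full study orchestration: frequencies -> population -> non-conformity
# tables -> LR summaries, with rendering of the four report tables.
#
# The per-pair statistics are computed by vectorized kernels operating on
# allele-index matrices (families x loci) extracted from the population;
# they implement exactly the same rules as the per-genotype functions in
# exclusion.R / paternity_lr.R, and the test suite cross-checks the two
# routes on small populations.

# stack one role's genotypes across families: list(A, B), each n x L
role_matrices <- function(pop, role) {
  L <- nrow(pop[[1]]$members[[role]]$genotypes)
  A <- t(vapply(pop, function(f) f$members[[role]]$genotypes[, 1], numeric(L)))
  B <- t(vapply(pop, function(f) f$members[[role]]$genotypes[, 2], numeric(L)))
  if (L == 1) { A <- matrix(A, ncol = 1); B <- matrix(B, ncol = 1) }
  list(A = A, B = B)
}

# population frequency of each allele index in an n x L index matrix
freq_lookup <- function(freqs, idx) {
  out <- idx
  for (l in seq_len(ncol(idx))) out[, l] <- freqs[[l]]$freqs[idx[, l]]
  out
}

# n x L logical: duo exclusion (no shared allele) per family per locus
duo_excluded_matrix <- function(fa, ch) {
  !(fa$A == ch$A | fa$A == ch$B | fa$B == ch$A | fa$B == ch$B)
}

# n x L logical: trio exclusion (father carries no obligate paternal allele)
trio_excluded_matrix <- function(fa, mo, ch) {
  het <- ch$A != ch$B
  m_has_a <- mo$A == ch$A | mo$B == ch$A
  m_has_b <- mo$A == ch$B | mo$B == ch$B
  if (any(ifelse(het, !m_has_a & !m_has_b, !m_has_a))) {
    stop("mother-child Mendelian incompatibility in a simulated family; ",
         "this indicates a pipeline bug", call. = FALSE)
  }
  f_has_a <- fa$A == ch$A | fa$B == ch$A
  f_has_b <- fa$A == ch$B | fa$B == ch$B
  # heterozygous child: allele a is obligate iff mother carries b, and vice versa
  nonexcl <- ifelse(het, (m_has_b & f_has_a) | (m_has_a & f_has_b), f_has_a)
  !nonexcl
}

# n x L matrix of duo paternity indices
duo_pi_matrix <- function(freqs, fa, ch) {
  p_ca <- freq_lookup(freqs, ch$A)
  p_cb <- freq_lookup(freqs, ch$B)
  het <- ch$A != ch$B
  trans <- function(f) {
    ifelse(het, (f == ch$A) * p_cb + (f == ch$B) * p_ca, (f == ch$A) * p_ca)
  }
  num <- (trans(fa$A) + trans(fa$B)) / 2
  den <- ifelse(het, 2 * p_ca * p_cb, p_ca^2)
  num / den
}

# n x L matrix of trio paternity indices
trio_pi_matrix <- function(freqs, fa, mo, ch) {
  p_ca <- freq_lookup(freqs, ch$A)
  p_cb <- freq_lookup(freqs, ch$B)
  het <- ch$A != ch$B
  match_mf <- function(m, f) {
    ifelse(het, (m == ch$A & f == ch$B) | (m == ch$B & f == ch$A),
           m == ch$A & f == ch$A)
  }
  num <- (match_mf(mo$A, fa$A) + match_mf(mo$A, fa$B) +
          match_mf(mo$B, fa$A) + match_mf(mo$B, fa$B)) / 4
  den_m <- function(m) {
    ifelse(het, (m == ch$A) * p_cb + (m == ch$B) * p_ca, (m == ch$A) * p_ca)
  }
  den <- (den_m(mo$A) + den_m(mo$B)) / 2
  num / den
}

#' Run the full in-silico parentage study
#'
#' Simulates a population of three-generation families and evaluates, for
#' each of the seven alleged-father relationships in both duo and trio
#' mode, the distribution of non-matching loci (with accumulative
#' non-exclusion rates and Agresti-Coull intervals) and the paternity-index
#' log LR summary over non-excluded (zero-mismatch) pairs.
#'
#' @param freqs a [freq_set]; if `NULL`, a synthetic forensic-style panel
#'   is generated (see [generate_synthetic_frequencies()]) using
#'   `n_loci`, `allele_count_range` and `concentration`.
#' @param n_families number of simulated families (default 10000, the
#'   study scale; reduce for quick runs).
#' @param seed master seed governing panel generation and simulation.
#' @param alpha significance level for intervals (default 0.05).
#' @param prior prior probability of paternity (default 0.5).
#' @param freq_file optional path to a `locus,allele,frequency` CSV of real
#'   population frequencies; overrides `freqs` and the synthetic panel.
#' @param n_loci,allele_count_range,concentration synthetic-panel
#'   parameters, used only when no `freqs`/`freq_file` is given.
#' @param out_dir optional directory; when given, [render_tables()] writes
#'   the report files there.
#' @param keep_population if `TRUE`, the simulated `str_population` is
#'   retained on the returned object (memory-heavy at full scale).
#' @param verbose print progress messages.
#' @return an object of class `parentage_study`: list with `tables` (a
#'   named list of [build_nonconformity_table()] results, one per
#'   relationship x mode), `lr` (named list of [summarize_log_lr()]
#'   results), `mismatch` (data.frame of per-pair mismatch counts),
#'   `pair_log_lr` (data.frame of per-pair log LRs, `NA` where excluded),
#'   `freqs`, and provenance fields (`seed`, `n_families`, `alpha`,
#'   `prior`, `timings`).
#' @examples
#' st <- run_study(n_families = 200, seed = 1)
#' print(st)
#' st$tables[["sibling.duo"]]
#' @export
run_study <- function(freqs = NULL, n_families = 10000, seed = 1,
                      alpha = 0.05, prior = 0.5, freq_file = NULL,
                      n_loci = 15, allele_count_range = c(8, 15),
                      concentration = 1, out_dir = NULL,
                      keep_population = FALSE, verbose = FALSE) {
  if (n_families < 1) stop_param("'n_families' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_param("'alpha' must be in (0, 1)")
  if (prior <= 0 || prior >= 1) stop_param("'prior' must be in (0, 1)")
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)

  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2))
  if (!is.null(freq_file)) {
    if (!file.exists(freq_file)) {
      stop("cannot read frequency file '", freq_file, "': no such file", call. = FALSE)
    }
    freqs <- read_frequency_csv(freq_file)
    say("loaded frequency table: ", length(freqs), " loci from ", freq_file)
  } else if (is.null(freqs)) {
    freqs <- generate_synthetic_frequencies(n_loci, allele_count_range,
                                            concentration, seed = seeds[1])
    say("generated synthetic panel: ", length(freqs), " loci")
  }
  stopifnot(inherits(freqs, "freq_set"))
  L <- length(freqs)

  pop <- simulate_population(freqs, n_families, seed = seeds[2])
  t_sim <- proc.time()[["elapsed"]]
  say(sprintf("simulated %d families in %.1fs", n_families, t_sim - t0))

  roles <- unique(unlist(scenario_pairings()[c("father_role", "mother_role", "child_role")]))
  roles <- roles[!is.na(roles)]
  mats <- lapply(roles, role_matrices, pop = pop)
  names(mats) <- roles

  sc <- scenario_pairings()
  tables <- list()
  lr <- list()
  mismatch <- list()
  pair_lr <- list()
  for (i in seq_len(nrow(sc))) {
    rel <- sc$relationship[i]; mode <- sc$mode[i]
    fa <- mats[[sc$father_role[i]]]
    ch <- mats[[sc$child_role[i]]]
    if (mode == "duo") {
      excl <- duo_excluded_matrix(fa, ch)
      pim <- duo_pi_matrix(freqs, fa, ch)
    } else {
      mo <- mats[[sc$mother_role[i]]]
      excl <- trio_excluded_matrix(fa, mo, ch)
      pim <- trio_pi_matrix(freqs, fa, mo, ch)
    }
    k <- rowSums(excl)
    recs <- data.frame(relationship = rel, mode = mode,
                       family_id = seq_len(n_families), k = k)
    key <- paste(rel, mode, sep = ".")
    tables[[key]] <- build_nonconformity_table(recs, L = L, alpha = alpha)
    log_lr <- ifelse(k == 0, rowSums(log10(pmax(pim, .Machine$double.xmin))), NA_real_)
    lr[[key]] <- summarize_log_lr(log_lr, alpha = alpha, prior = prior)
    lr[[key]]$relationship <- rel
    lr[[key]]$mode <- mode
    mismatch[[key]] <- recs
    pair_lr[[key]] <- data.frame(
      relationship = rel, mode = mode, family_id = seq_len(n_families),
      log_lr = log_lr,
      probability_pct = ifelse(is.na(log_lr), NA_real_,
                               probability_of_paternity_log10(log_lr, prior)),
      excluded = k > 0)
  }
  t_stats <- proc.time()[["elapsed"]]
  say(sprintf("scenario statistics in %.1fs", t_stats - t_sim))

  res <- structure(list(
    tables = tables, lr = lr,
    mismatch = do.call(rbind, c(mismatch, list(make.row.names = FALSE))),
    pair_log_lr = do.call(rbind, c(pair_lr, list(make.row.names = FALSE))),
    freqs = freqs, seed = seed, n_families = n_families, L = L,
    alpha = alpha, prior = prior,
    population = if (keep_population) pop,
    timings = c(simulate = t_sim - t0, statistics = t_stats - t_sim)
  ), class = "parentage_study")
  if (!is.null(out_dir)) render_tables(res, out_dir)
  res
}

#' @export
print.parentage_study <- function(x, ...) {
  cat(sprintf("In-silico parentage study: %d families, %d STR loci (seed %s)\n",
              x$n_families, x$L, format(x$seed)))
  cat(sprintf("Non-exclusion rate at zero non-matching loci (%% ± %d%% interval half-width):\n",
              round(100 * (1 - x$alpha))))
  rels <- unique(vapply(x$tables, `[[`, character(1), "relationship"))
  rows <- t(vapply(rels, function(r) {
    vapply(c("duo", "trio"), function(m) {
      tb <- x$tables[[paste(r, m, sep = ".")]]
      format(tb$rate)[1]
    }, character(1))
  }, character(2)))
  print(data.frame(duo = rows[, 1], trio = rows[, 2], row.names = rels))
  invisible(x)
}

#' @export
summary.parentage_study <- function(object, ...) {
  k0 <- do.call(rbind, lapply(object$tables, function(tb) {
    data.frame(relationship = tb$relationship, mode = tb$mode, n = tb$n,
               k0_count = tb$counts[1],
               rate_pct = tb$rate$center[1], half_width = tb$rate$half_width[1])
  }))
  rownames(k0) <- NULL
  lr <- do.call(rbind, lapply(object$lr, function(s) {
    data.frame(relationship = s$relationship, mode = s$mode,
               n_nonexcluded = s$n_nonexcluded,
               min_log_lr = s$min_log_lr, max_log_lr = s$max_log_lr,
               mean_log_lr = s$mean_log_lr, ci_half_width = s$ci_half_width,
               prob_mean_pct = s$prob$mean)
  }))
  rownames(lr) <- NULL
  out <- list(nonexclusion_k0 = k0, log_lr = lr,
              n_families = object$n_families, L = object$L, seed = object$seed)
  class(out) <- "summary.parentage_study"
  out
}

#' @export
print.summary.parentage_study <- function(x, ...) {
  cat(sprintf("Parentage study summary (%d families, %d loci, seed %s)\n\n",
              x$n_families, x$L, format(x$seed)))
  cat("Zero-mismatch (non-exclusion) rates:\n")
  print(x$nonexclusion_k0, digits = 4)
  cat("\nLog10 LR over non-excluded pairs:\n")
  print(x$log_lr, digits = 5)
  invisible(x)
}

#' Plot non-conformity distributions
#'
#' Bar plots of the number of non-matching loci per relationship, one
#' panel per relationship, for the chosen mode.
#'
#' @param x a `parentage_study`.
#' @param mode `"duo"` or `"trio"`.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.parentage_study <- function(x, mode = c("duo", "trio"), ...) {
  mode <- match.arg(mode)
  keys <- names(x$tables)[endsWith(names(x$tables), paste0(".", mode))]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(keys)),
                       mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (key in keys) {
    tb <- x$tables[[key]]
    graphics::barplot(tb$counts, names.arg = 0:tb$L,
                      main = paste(tb$relationship, mode), ...)
  }
  invisible(x)
}

fmt_num <- function(v, d = 4) ifelse(is.na(v), "-", sprintf(paste0("%.", d, "f"), v))

#' Write the study report tables to files
#'
#' Produces, in `dir`: human-readable non-conformity tables for duo and
#' trio mode (`duo_nonconformity.csv`, `trio_nonconformity.csv`; rows
#' count / cumulative / rate per relationship, rate cells formatted
#' `"19.03 ± 0.77"`), machine-readable variants
#' (`nonconformity_machine.csv`: `relationship,mode,row,k0..kL` with rows
#' count / cumulative / rate_center / rate_halfwidth, unrounded), LR
#' summary tables (`duo_lr_summary.csv`, `trio_lr_summary.csv`), the
#' per-pair LR dump (`pair_log_lr.csv`), a JSON-lines dump of every table
#' cell (`report.jsonl`) and a run log (`run_log.txt`). Re-rendering an
#' unchanged study is idempotent.
#'
#' @param report a `parentage_study`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "parentage_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  kcols <- paste0("k", 0:report$L)

  for (mode in c("duo", "trio")) {
    keys <- names(report$tables)[endsWith(names(report$tables), paste0(".", mode))]
    human <- do.call(rbind, lapply(keys, function(key) {
      tb <- report$tables[[key]]
      m <- rbind(format(tb$counts), format(tb$cumulative), format(tb$rate))
      df <- data.frame(relationship = tb$relationship,
                       row = c("count", "cumulative", "rate"), m)
      names(df) <- c("relationship", "row", kcols)
      df
    }))
    p <- file.path(dir, paste0(mode, "_nonconformity.csv"))
    utils::write.csv(human, p, row.names = FALSE)
    paths <- c(paths, p)

    lr <- do.call(rbind, lapply(keys, function(key) {
      s <- report$lr[[key]]
      data.frame(relationship = s$relationship,
                 n_nonexclusion = s$n_nonexcluded,
                 min = fmt_num(s$min_log_lr), min_prob_pct = fmt_num(s$prob$min),
                 max = fmt_num(s$max_log_lr), max_prob_pct = fmt_num(s$prob$max),
                 mean = fmt_num(s$mean_log_lr),
                 ci_half_width = fmt_num(s$ci_half_width),
                 mean_prob_pct = fmt_num(s$prob$mean))
    }))
    p <- file.path(dir, paste0(mode, "_lr_summary.csv"))
    utils::write.csv(lr, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  machine <- do.call(rbind, lapply(report$tables, function(tb) {
    m <- rbind(tb$counts, tb$cumulative, tb$rate$center, tb$rate$half_width)
    df <- data.frame(relationship = tb$relationship, mode = tb$mode,
                     row = c("count", "cumulative", "rate_center", "rate_halfwidth"), m)
    names(df) <- c("relationship", "mode", "row", kcols)
    df
  }))
  p <- file.path(dir, "nonconformity_machine.csv")
  utils::write.csv(machine, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "pair_log_lr.csv")
  utils::write.csv(report$pair_log_lr, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "report.jsonl")
  con <- file(p, "w")
  for (key in names(report$tables)) {
    tb <- report$tables[[key]]
    s <- report$lr[[key]]
    json_num <- function(v) ifelse(is.na(v), "null", format(v, digits = 15))
    writeLines(sprintf(
      paste0('{"relationship":"%s","mode":"%s","n":%d,',
             '"counts":[%s],"cumulative":[%s],"rate_center":[%s],',
             '"rate_halfwidth":[%s],"n_nonexcluded":%d,"min_log_lr":%s,',
             '"max_log_lr":%s,"mean_log_lr":%s,"ci_half_width":%s}'),
      tb$relationship, tb$mode, tb$n,
      paste(tb$counts, collapse = ","), paste(tb$cumulative, collapse = ","),
      paste(json_num(tb$rate$center), collapse = ","),
      paste(json_num(tb$rate$half_width), collapse = ","),
      s$n_nonexcluded, json_num(s$min_log_lr), json_num(s$max_log_lr),
      json_num(s$mean_log_lr), json_num(s$ci_half_width)), con)
  }
  close(con)
  paths <- c(paths, p)

  p <- file.path(dir, "run_log.txt")
  writeLines(c(
    sprintf("parentage study run: %d families, %d loci", report$n_families, report$L),
    sprintf("seed: %s  alpha: %g  prior: %g", format(report$seed), report$alpha, report$prior),
    sprintf("panel expected heterozygosity: %s",
            paste(sprintf("%.3f", expected_heterozygosity(report$freqs)), collapse = " ")),
    sprintf("timings (s): simulate %.2f, statistics %.2f",
            report$timings[["simulate"]], report$timings[["statistics"]])
  ), p)
  paths <- c(paths, p)
  invisible(paths)
}
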