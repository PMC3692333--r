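# Shared expensive simulations, computed once per test run on first use.

.study_cache <- new.env(parent = emptyenv())

# the full-scale default study (10000 families, 15 synthetic loci)
get_full_study <- function() {
  if (is.null(.study_cache$full)) {
    t0 <- proc.time()[["elapsed"]]
    .study_cache$full <- run_study(n_families = 10000, seed = 1)
    .study_cache$elapsed <- proc.time()[["elapsed"]] - t0
  }
  .study_cache$full
}

get_full_study_elapsed <- function() {
  get_full_study()
  .study_cache$elapsed
}

# a 10000-family population on a single small locus, keyed by frequencies
get_one_locus_population <- function(p, seed = 42) {
  key <- paste0("pop_", paste(p, collapse = "_"), "_", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- simulate_population(one_locus_set(p), 10000, seed = seed)
  }
  .study_cache[[key]]
}

# published report tables bundled as fixtures
load_published_nonconformity <- function(mode) {
  path <- system.file("extdata", sprintf("published_%s_nonconformity.csv", mode),
                      package = "parentsim")
  read.csv(path, check.names = FALSE)
}

load_published_lr <- function(mode) {
  path <- system.file("extdata", sprintf("published_%s_lr_summary.csv", mode),
                      package = "parentsim")
  read.csv(path)
}

# rebuild a nonconformity table from a published per-k count row
table_from_counts <- function(counts, relationship, mode, alpha = 0.05) {
  k <- rep(seq_along(counts) - 1L, counts)
  build_nonconformity_table(
    data.frame(relationship = relationship, mode = mode, k = k),
    L = length(counts) - 1L, alpha = alpha)
}
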