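# Three-generation pedigree simulation.
#
# Founders are drawn under Hardy-Weinberg equilibrium from the frequency
# set; every non-founder receives one uniformly chosen allele from each
# parent, independently across loci (no mutation, no linkage). The pedigree
# is the minimal one realizing the seven alleged-father relationships:
#
#   founders: I, J (paternal grandparents), N (husband of the father's
#             sister D), S (second partner of the father), F (mother),
#             J2 (mother of the half-sibling's reference child), X (random man)
#   I x J  -> E (father), D (paternal aunt), K (paternal uncle)
#   E x F  -> B (child), C (sibling of B)
#   N x D  -> R (cousin: son of the father's sister)
#   E x J2 -> M (reference child for the half-sibling scenario)
#   E x S  -> W (half brother of M through E)
#
# Genotypes are stored as L x 2 integer matrices of allele indices into
# each locus's allele vector; labels are recovered via the frequency set.

# role -> c(father, mother); absent = founder
PEDIGREE_PARENTS <- list(
  E = c("I", "J"), D = c("I", "J"), K = c("I", "J"),
  B = c("E", "F"), C = c("E", "F"),
  R = c("N", "D"),
  M = c("E", "J2"),
  W = c("E", "S")
)
FOUNDER_ROLES <- c("I", "J", "N", "S", "F", "J2", "X")

#' Alleged-father scenario pairings
#'
#' The seven relationships evaluated by the study, each in duo (motherless)
#' and trio mode. The alleged father replaces the true father E against
#' child B (mother F), except the half-sibling scenario, where half brother
#' W is tested against his paternal half sibling M (M's mother J2 supplies
#' the trio mother).
#'
#' @return a data.frame with columns `relationship` (one of `parent`,
#'   `sibling`, `grandparent`, `uncle`, `half_sibling`, `cousin`,
#'   `random_man`), `mode` (`duo`/`trio`), `father_role`, `mother_role`
#'   (`NA` in duo mode) and `child_role`.
#' @examples
#' scenario_pairings()
#' @export
scenario_pairings <- function() {
  base <- data.frame(
    relationship = c("parent", "sibling", "grandparent", "uncle",
                     "half_sibling", "cousin", "random_man"),
    father_role = c("E", "C", "I", "K", "W", "R", "X"),
    mother_role = c("F", "F", "F", "F", "J2", "F", "F"),
    child_role  = c("B", "B", "B", "B", "M", "B", "B"),
    stringsAsFactors = FALSE
  )
  duo <- base
  duo$mode <- "duo"
  duo$mother_role <- NA_character_
  trio <- base
  trio$mode <- "trio"
  out <- rbind(duo, trio)
  out[c("relationship", "mode", "father_role", "mother_role", "child_role")]
}

new_individual <- function(role, genotypes) {
  structure(list(role = role, genotypes = genotypes), class = "str_individual")
}

#' Draw a founder under Hardy-Weinberg equilibrium
#'
#' At each locus, two alleles are drawn independently from the locus's
#' population frequencies. Uses the current RNG state.
#'
#' @param freqs a [freq_set].
#' @param role role code to record on the individual (default `"founder"`).
#' @return an object of class `str_individual` with components `role` and
#'   `genotypes`, an `n_loci x 2` integer matrix of allele indices (row
#'   names are locus names).
#' @examples
#' fs <- generate_synthetic_frequencies(n_loci = 3, seed = 1)
#' set.seed(42)
#' draw_founder(fs)
#' @export
draw_founder <- function(freqs, role = "founder") {
  stopifnot(inherits(freqs, "freq_set"))
  L <- length(freqs)
  g <- matrix(0L, L, 2, dimnames = list(names(freqs), c("a", "b")))
  u <- matrix(stats::runif(2L * L), L, 2)
  for (l in seq_len(L)) {
    cp <- cumsum(freqs[[l]]$freqs)
    cp[length(cp)] <- 1  # guard against cumulative rounding
    g[l, ] <- findInterval(u[l, ], cp, left.open = TRUE) + 1L
  }
  new_individual(role, g)
}

#' Produce a child by Mendelian transmission
#'
#' At each locus the child receives one uniformly chosen allele from each
#' parent, independently across loci; no mutation. Uses the current RNG
#' state.
#'
#' @param parent1,parent2 `str_individual` objects typed on the same panel.
#' @param role role code for the child.
#' @return an `str_individual`.
#' @examples
#' fs <- generate_synthetic_frequencies(n_loci = 2, seed = 1)
#' set.seed(1)
#' p1 <- draw_founder(fs); p2 <- draw_founder(fs)
#' mate(p1, p2, role = "child")
#' @export
mate <- function(parent1, parent2, role = "child") {
  stopifnot(inherits(parent1, "str_individual"), inherits(parent2, "str_individual"))
  g1 <- parent1$genotypes
  g2 <- parent2$genotypes
  if (!identical(dim(g1), dim(g2)) || !identical(rownames(g1), rownames(g2))) {
    stop_param("parents are typed on different panels")
  }
  L <- nrow(g1)
  pick1 <- stats::runif(L) < 0.5
  pick2 <- stats::runif(L) < 0.5
  g <- cbind(a = ifelse(pick1, g1[, 1], g1[, 2]),
             b = ifelse(pick2, g2[, 1], g2[, 2]))
  rownames(g) <- rownames(g1)
  new_individual(role, g)
}

#' Simulate one three-generation family
#'
#' Builds the full pedigree (see [scenario_pairings()] for the roles it
#' feeds): founders I, J, N, S, F, J2 and random man X drawn under
#' Hardy-Weinberg; father E, aunt D and uncle K as children of I x J;
#' children B and C of E x F; cousin R of N x D; M of E x J2; half brother
#' W of E x S. Uses the current RNG state; seed it (or use
#' [simulate_population()]) for reproducibility.
#'
#' @param freqs a [freq_set].
#' @param family_id integer identifier stored on the family.
#' @return an object of class `str_family`: list with `family_id` and
#'   `members`, a named list of `str_individual` objects.
#' @examples
#' fs <- generate_synthetic_frequencies(n_loci = 4, seed = 1)
#' set.seed(7)
#' fam <- simulate_family(fs)
#' names(fam$members)
#' @export
simulate_family <- function(freqs, family_id = 1L) {
  stopifnot(inherits(freqs, "freq_set"))
  members <- list()
  for (r in FOUNDER_ROLES) members[[r]] <- draw_founder(freqs, role = r)
  for (r in names(PEDIGREE_PARENTS)) {
    par <- PEDIGREE_PARENTS[[r]]
    members[[r]] <- mate(members[[par[1]]], members[[par[2]]], role = r)
  }
  structure(list(family_id = as.integer(family_id), members = members),
            class = "str_family")
}

#' @export
print.str_family <- function(x, ...) {
  L <- nrow(x$members[[1]]$genotypes)
  cat("Simulated family", x$family_id, "-", length(x$members),
      "members typed at", L, "loci\n")
  cat("  founders:", paste(FOUNDER_ROLES, collapse = " "), "\n")
  cat("  offspring:", paste(names(PEDIGREE_PARENTS), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a population of independent families
#'
#' The master seed spawns one RNG substream (a derived seed) per family, so
#' the genotypes of family *i* do not depend on how many other families are
#' simulated or in which order they are evaluated.
#'
#' @param freqs a [freq_set].
#' @param n_families number of independent families (>= 1).
#' @param seed integer master seed; `NULL` derives substream seeds from the
#'   current RNG state.
#' @return an object of class `str_population`: a list of `str_family`
#'   objects with attributes `seed` and `family_seeds`.
#' @examples
#' fs <- generate_synthetic_frequencies(n_loci = 3, seed = 1)
#' pop <- simulate_population(fs, n_families = 5, seed = 99)
#' length(pop)
#' @export
simulate_population <- function(freqs, n_families, seed = NULL) {
  stopifnot(inherits(freqs, "freq_set"))
  if (length(n_families) != 1 || is.na(n_families) || n_families < 1) {
    stop_param("'n_families' must be a single integer >= 1")
  }
  n_families <- as.integer(n_families)
  fam_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_families))
  fams <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    fams[[i]] <- with_seed(fam_seeds[i], simulate_family(freqs, family_id = i))
  }
  structure(fams, class = "str_population", seed = seed, family_seeds = fam_seeds)
}

#' @export
print.str_population <- function(x, ...) {
  cat("Simulated population:", length(x), "families",
      if (!is.null(attr(x, "seed"))) paste0("(seed ", attr(x, "seed"), ")"), "\n")
  invisible(x)
}

#' @export
`[.str_population` <- function(x, i) {
  structure(NextMethod(), class = "str_population",
            seed = attr(x, "seed"), family_seeds = attr(x, "family_seeds")[i])
}

#' Audit Mendelian consistency of a family
#'
#' Checks, for every non-founder at every locus, that the genotype can be
#' partitioned into one allele carried by each recorded parent — the
#' no-mutation invariant of the simulator.
#'
#' @param family an `str_family`.
#' @return `TRUE` invisibly if consistent; otherwise throws an error naming
#'   the offending role and locus.
#' @export
audit_mendelian <- function(family) {
  stopifnot(inherits(family, "str_family"))
  for (r in names(PEDIGREE_PARENTS)) {
    par <- PEDIGREE_PARENTS[[r]]
    gc <- family$members[[r]]$genotypes
    gf <- family$members[[par[1]]]$genotypes
    gm <- family$members[[par[2]]]$genotypes
    for (l in seq_len(nrow(gc))) {
      a <- gc[l, 1]; b <- gc[l, 2]
      ok <- (a %in% gf[l, ] && b %in% gm[l, ]) || (b %in% gf[l, ] && a %in% gm[l, ])
      if (!ok) {
        stop("Mendelian violation: role ", r, ", locus ", rownames(gc)[l],
             " in family ", family$family_id, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Dump population genotypes to CSV
#'
#' Writes one row per (family, role, locus) with allele labels, in the
#' dialect `family_id,role,locus,allele_a,allele_b`.
#'
#' @param pop an `str_population` (or a single `str_family`).
#' @param freqs the [freq_set] the population was simulated from (supplies
#'   allele labels).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(pop, freqs, path) {
  stopifnot(inherits(freqs, "freq_set"))
  if (inherits(pop, "str_family")) pop <- list(pop)
  labels <- lapply(freqs, `[[`, "alleles")
  lnames <- names(freqs)
  rows <- lapply(pop, function(fam) {
    do.call(rbind, lapply(fam$members, function(ind) {
      g <- ind$genotypes
      data.frame(family_id = fam$family_id, role = ind$role, locus = lnames,
                 allele_a = vapply(seq_along(lnames), function(l) labels[[l]][g[l, 1]], ""),
                 allele_b = vapply(seq_along(lnames), function(l) labels[[l]][g[l, 2]], ""))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
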