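test_that("founder sampling follows the locus frequencies", {
  # 2-allele locus with p = 0.3: empirical allele frequency over 10000
  # founders (20000 allele draws) must sit within 3 binomial standard errors
  fs <- one_locus_set(c(0.3, 0.7))
  set.seed(11)
  draws <- vapply(seq_len(10000), function(i) draw_founder(fs)$genotypes[1, ],
                  numeric(2))
  p_hat <- mean(draws == 1)
  se <- sqrt(0.3 * 0.7 / 20000)
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("founder draws are deterministic under a fixed RNG state", {
  fs <- generate_synthetic_frequencies(n_loci = 5, seed = 2)
  set.seed(99); a <- draw_founder(fs)
  set.seed(99); b <- draw_founder(fs)
  expect_identical(a, b)
})

test_that("a near-fixed locus yields homozygotes at the expected rate", {
  fs <- one_locus_set(c(0.9999, 0.0001))
  set.seed(5)
  g <- vapply(seq_len(2000), function(i) draw_founder(fs)$genotypes[1, ], numeric(2))
  hom_rate <- mean(g[1, ] == 1 & g[2, ] == 1)
  expect_gt(hom_rate, 0.995)  # theoretical 0.9999^2 = 0.9998
})

test_that("Mendelian transmission is forced for opposite homozygotes", {
  fs <- one_locus_set(c(0.5, 0.5))
  p1 <- parentsim:::new_individual("p1", matrix(c(1L, 1L), 1, dimnames = list("L1", c("a", "b"))))
  p2 <- parentsim:::new_individual("p2", matrix(c(2L, 2L), 1, dimnames = list("L1", c("a", "b"))))
  for (i in 1:20) {
    ch <- mate(p1, p2)
    expect_setequal(as.vector(ch$genotypes), c(1L, 2L))
  }
})

test_that("het x het crosses segregate 1:2:1 within 3 standard errors", {
  g_ab <- matrix(c(1L, 2L), 1, dimnames = list("L1", c("a", "b")))
  p1 <- parentsim:::new_individual("p1", g_ab)
  p2 <- parentsim:::new_individual("p2", g_ab)
  set.seed(21)
  kids <- vapply(seq_len(10000), function(i) sort(mate(p1, p2)$genotypes[1, ]), numeric(2))
  aa <- mean(kids[1, ] == 1 & kids[2, ] == 1)
  bb <- mean(kids[1, ] == 2 & kids[2, ] == 2)
  ab <- 1 - aa - bb
  se25 <- sqrt(0.25 * 0.75 / 10000)
  se50 <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(aa - 0.25), 3 * se25)
  expect_lt(abs(bb - 0.25), 3 * se25)
  expect_lt(abs(ab - 0.50), 3 * se50)
})

test_that("children always share an allele with each parent at every locus", {
  fs <- generate_synthetic_frequencies(n_loci = 8, seed = 4)
  set.seed(31)
  p1 <- draw_founder(fs); p2 <- draw_founder(fs)
  ch <- mate(p1, p2)
  for (l in seq_len(8)) {
    expect_true(any(ch$genotypes[l, ] %in% p1$genotypes[l, ]))
    expect_true(any(ch$genotypes[l, ] %in% p2$genotypes[l, ]))
  }
})

test_that("mating rejects parents typed on different panels", {
  fs3 <- generate_synthetic_frequencies(n_loci = 3, seed = 1)
  fs4 <- generate_synthetic_frequencies(n_loci = 4, seed = 1)
  set.seed(1)
  expect_error(mate(draw_founder(fs3), draw_founder(fs4)), "panel")
})

test_that("the simulated pedigree realizes the seven relationships structurally", {
  fs <- generate_synthetic_frequencies(n_loci = 5, seed = 6)
  set.seed(61)
  fam <- simulate_family(fs, family_id = 1)
  expect_s3_class(fam, "str_family")
  ped <- parentsim:::PEDIGREE_PARENTS
  # E and K are full siblings (same parent pair); D likewise
  expect_identical(ped$E, ped$K)
  expect_identical(ped$E, ped$D)
  # R's parent D shares a parent pair with E (R = son of the father's sister)
  expect_true("D" %in% ped$R)
  # W and M share exactly one parent, the father E
  expect_identical(intersect(ped$W, ped$M), "E")
  # every role referenced by a scenario pairing exists in the family
  sc <- scenario_pairings()
  roles <- unique(na.omit(unlist(sc[c("father_role", "mother_role", "child_role")])))
  expect_true(all(roles %in% names(fam$members)))
  audit_mendelian(fam)
})

test_that("scenario pairings request a mother exactly in trio mode", {
  sc <- scenario_pairings()
  expect_equal(nrow(sc), 14)
  expect_setequal(unique(sc$relationship),
                  c("parent", "sibling", "grandparent", "uncle",
                    "half_sibling", "cousin", "random_man"))
  expect_true(all(is.na(sc$mother_role[sc$mode == "duo"])))
  expect_true(all(!is.na(sc$mother_role[sc$mode == "trio"])))
})

test_that("populations are reproducible, seed-sensitive and order-invariant", {
  fs <- generate_synthetic_frequencies(n_loci = 3, seed = 8)
  a <- simulate_population(fs, 6, seed = 77)
  b <- simulate_population(fs, 6, seed = 77)
  expect_identical(unclass(a)[1:6], unclass(b)[1:6])
  d <- simulate_population(fs, 6, seed = 78)
  expect_false(identical(unclass(a)[1:6], unclass(d)[1:6]))
  # family i does not depend on how many families are simulated after it
  big <- simulate_population(fs, 12, seed = 77)
  expect_identical(unclass(big)[1:6], unclass(a)[1:6])
  # degenerate size is usable
  one <- simulate_population(fs, 1, seed = 1)
  expect_length(one, 1)
  audit_mendelian(one[[1]])
})

test_that("every family in a population passes the Mendelian audit", {
  fs <- generate_synthetic_frequencies(n_loci = 6, seed = 9)
  pop <- simulate_population(fs, 200, seed = 5)
  for (fam in pop) audit_mendelian(fam)
  succeed()
})

test_that("full siblings share no allele at no more than a quarter of loci", {
  # IBD argument: siblings share >= 1 allele identical by descent with
  # probability 3/4, so the no-share proportion is bounded by 1/4
  pop <- get_one_locus_population(c(0.5, 0.3, 0.2))
  none <- vapply(pop, function(fam) {
    duo_locus_excluded(fam$members$C$genotypes[1, ], fam$members$B$genotypes[1, ])
  }, logical(1))
  expect_lte(mean(none), 0.25)
})

test_that("per-locus allele sharing matches the pedigree enumeration oracle", {
  # simulated duo non-exclusion (share >= 1 allele) per relationship vs
  # exhaustive enumeration over founder genotypes and transmissions,
  # within 3 binomial standard errors at n = 10000
  for (rel in names(ORACLE_PEDIGREES)) {
    p <- if (rel == "cousin") c(0.6, 0.4) else c(0.5, 0.3, 0.2)
    ped <- ORACLE_PEDIGREES[[rel]]
    expected <- oracle_share_prob(p, ped$founders, ped$children, ped$pair)
    pop <- get_one_locus_population(p)
    sc <- scenario_pairings()
    row <- sc[sc$relationship == rel & sc$mode == "duo", ]
    shared <- vapply(pop, function(fam) {
      !duo_locus_excluded(fam$members[[row$father_role]]$genotypes[1, ],
                          fam$members[[row$child_role]]$genotypes[1, ])
    }, logical(1))
    se <- sqrt(expected * (1 - expected) / length(pop))
    expect_lt(abs(mean(shared) - expected), 3 * se + 1e-12,
              label = sprintf("sharing rate for %s (obs %.4f, exp %.4f)",
                              rel, mean(shared), expected))
  }
})

test_that("genotype dumps are written in the documented dialect", {
  fs <- generate_synthetic_frequencies(n_loci = 2, seed = 10)
  pop <- simulate_population(fs, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_csv(pop, fs, path)
  df <- read.csv(path, colClasses = "character")
  expect_identical(names(df), c("family_id", "role", "locus", "allele_a", "allele_b"))
  expect_equal(nrow(df), 2 * length(pop[[1]]$members) * 2)
  expect_true(all(df$allele_a %in% unlist(lapply(fs, `[[`, "alleles"))))
})
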