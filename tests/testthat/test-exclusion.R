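test_that("duo exclusion is the no-shared-allele rule and is symmetric", {
  expect_false(duo_locus_excluded(c("a", "b"), c("a", "c")))
  expect_true(duo_locus_excluded(c("a", "b"), c("c", "d")))
  expect_false(duo_locus_excluded(c("a", "a"), c("a", "a")))
  # symmetry over all genotype pairs at a 3-allele locus
  gts <- ordered_genotypes(3)
  for (i in seq_len(nrow(gts))) for (j in seq_len(nrow(gts))) {
    expect_identical(duo_locus_excluded(gts[i, ], gts[j, ]),
                     duo_locus_excluded(gts[j, ], gts[i, ]))
  }
})

test_that("obligate paternal alleles follow the mother-child deduction", {
  expect_identical(obligate_paternal_alleles(c("a", "a"), c("a", "b")), "b")
  expect_setequal(obligate_paternal_alleles(c("a", "b"), c("a", "b")), c("a", "b"))
  expect_identical(obligate_paternal_alleles(c("a", "c"), c("a", "a")), "a")
  expect_identical(obligate_paternal_alleles(c("a", "c"), c("a", "b")), "b")
  expect_error(obligate_paternal_alleles(c("c", "c"), c("a", "b")), "incompatible")
  expect_error(obligate_paternal_alleles(c("b", "c"), c("a", "a")), "incompatible")
})

test_that("trio exclusion matches the obligate-allele rule", {
  expect_false(trio_locus_excluded(c("b", "c"), c("a", "a"), c("a", "b")))
  expect_true(trio_locus_excluded(c("c", "d"), c("a", "b"), c("a", "b")))
  expect_false(trio_locus_excluded(c("a", "c"), c("a", "b"), c("a", "b")))
})

test_that("duo exclusion implies trio exclusion over all genotype triples", {
  # exhaustive enumeration at a 4-allele locus; obligate set is a subset of
  # the child's alleles, so motherless exclusion is always at least as strict
  gts <- ordered_genotypes(4)
  for (i in seq_len(nrow(gts))) for (j in seq_len(nrow(gts))) for (m in seq_len(nrow(gts))) {
    fa <- gts[i, ]; ch <- gts[j, ]; mo <- gts[m, ]
    compatible <- !inherits(try(obligate_paternal_alleles(mo, ch), silent = TRUE),
                            "try-error")
    if (!compatible) next
    if (duo_locus_excluded(fa, ch)) {
      expect_true(trio_locus_excluded(fa, mo, ch))
    }
  }
})

test_that("non-conformity counting applies the pairing's mode across the panel", {
  fs <- one_locus_set(c(0.4, 0.3, 0.2, 0.1))
  g <- function(a, b) matrix(c(a, b), 1, dimnames = list("L1", c("a", "b")))
  fam <- structure(list(family_id = 1L, members = list(
    AF = parentsim:::new_individual("AF", g(3L, 4L)),
    MO = parentsim:::new_individual("MO", g(1L, 2L)),
    CH = parentsim:::new_individual("CH", g(1L, 2L))
  )), class = "str_family")
  duo <- list(relationship = "test", mode = "duo",
              father_role = "AF", mother_role = NA, child_role = "CH")
  trio <- list(relationship = "test", mode = "trio",
               father_role = "AF", mother_role = "MO", child_role = "CH")
  expect_equal(count_nonconformities(duo, fam)$k, 1L)
  expect_equal(count_nonconformities(trio, fam)$k, 1L)
  expect_error(count_nonconformities(
    list(relationship = "x", mode = "duo", father_role = "ZZ", child_role = "CH"),
    fam), "lacks role")
})

test_that("Agresti-Coull estimates reproduce published report cells", {
  expect_equal(round(agresti_coull(1902, 10000)$center, 2), 19.03)
  expect_equal(round(agresti_coull(1902, 10000)$half_width, 2), 0.77)
  expect_equal(round(agresti_coull(0, 10000)$center, 2), 0.02)
  expect_equal(round(agresti_coull(0, 10000)$half_width, 2), 0.03)
  expect_equal(round(agresti_coull(10000, 10000)$center, 2), 99.98)
  expect_equal(round(agresti_coull(10000, 10000)$half_width, 2), 0.03)
  # adjusted center is strictly positive at x = 0
  expect_gt(agresti_coull(0, 10)$center, 0)
})

test_that("Agresti-Coull centers are complementary and inputs validated", {
  for (x in c(0, 1, 17, 5000, 9999)) {
    est <- agresti_coull(c(x, 10000 - x), 10000)
    expect_equal(sum(est$center), 100, tolerance = 1e-12)
  }
  expect_error(agresti_coull(-1, 10), "x")
  expect_error(agresti_coull(11, 10), "x")
  expect_error(agresti_coull(1, 0), "n")
  expect_error(agresti_coull(1, 10, alpha = 0), "alpha")
  expect_error(agresti_coull(1, 10, alpha = 1), "alpha")
})

test_that("non-conformity tables cumulate correctly", {
  recs <- data.frame(relationship = "sibling", mode = "duo",
                     k = c(0, 0, 1, 2, 2, 3))
  tb <- build_nonconformity_table(recs, L = 3)
  expect_equal(unname(tb$counts), c(2, 1, 2, 1))
  expect_equal(unname(tb$cumulative), c(2, 3, 5, 6))
  expect_true(all(diff(tb$cumulative) >= 0))
  expect_equal(unname(tb$cumulative[4]), tb$n)
  # the k = L rate uses x = n
  expect_equal(tb$rate$center[4], agresti_coull(6, 6)$center)
  expect_error(build_nonconformity_table(recs[0, ], L = 3), "no mismatch records")
  expect_error(build_nonconformity_table(
    rbind(recs, data.frame(relationship = "cousin", mode = "duo", k = 1)), L = 3),
    "one relationship")
})

test_that("all-conforming records give a constant table", {
  recs <- data.frame(relationship = "parent", mode = "trio", k = rep(0, 50))
  tb <- build_nonconformity_table(recs, L = 4)
  expect_equal(unname(tb$counts), c(50, 0, 0, 0, 0))
  expect_true(all(tb$cumulative == 50))
  expect_equal(tb$rate$center, rep(agresti_coull(50, 50)$center, 5))
})

test_that("published accumulative rates rebuild from published counts", {
  # sibling duo: counts 1902, 3268 cumulate to 5170 and rate 51.70
  duo <- load_published_nonconformity("duo")
  counts <- as.numeric(duo[duo$relationship == "sibling" & duo$row == "count", -(1:2)])
  tb <- table_from_counts(counts, "sibling", "duo")
  expect_equal(unname(tb$cumulative[2]), 5170)
  expect_equal(round(tb$rate$center[2], 2), 51.70)
  expect_equal(round(tb$rate$half_width[2], 2), 0.98)
  # trio sibling: 49 + 377 -> 4.28 +/- 0.40
  trio <- load_published_nonconformity("trio")
  counts <- as.numeric(trio[trio$relationship == "sibling" & trio$row == "count", -(1:2)])
  tb <- table_from_counts(counts, "sibling", "trio")
  expect_equal(unname(tb$cumulative[2]), 426)
  expect_equal(round(tb$rate$center[2], 2), 4.28)
  expect_equal(round(tb$rate$half_width[2], 2), 0.40)
})
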