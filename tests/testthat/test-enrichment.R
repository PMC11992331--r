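test_that("interval merging unions overlaps and adjacencies", {
  expect_equal(merge_intervals(c(10, 15), c(20, 30)),
               data.frame(start = 10, end = 30))
  expect_equal(merge_intervals(c(10, 20), c(20, 30)),
               data.frame(start = 10, end = 30))
  expect_equal(merge_intervals(c(10, 40), c(20, 50)),
               data.frame(start = c(10, 40), end = c(20, 50)))
  # idempotence and monotone covered bases
  m1 <- merge_intervals(c(10, 15, 40), c(20, 30, 50))
  m2 <- merge_intervals(m1$start, m1$end)
  expect_equal(m1, m2)
  more <- merge_intervals(c(m1$start, 25), c(m1$end, 45))
  expect_gte(sum(more$end - more$start), sum(m1$end - m1$start))
  expect_error(merge_intervals(10, 10), "invalid interval")
})

test_that("coverage fractions match hand examples and prefix semantics", {
  tr <- make_track("c1", c(10, 15), c(20, 30),
                   c("LTR/Gypsy", "LTR/Gypsy/Athila"))
  expect_equal(coverage_fraction(tr, "LTR", "c1:0-100"), 0.20)
  expect_equal(coverage_fraction(tr, "LTR/Gypsy", "c1:0-100"), 0.20)
  expect_equal(coverage_fraction(tr, "LTR/Gypsy/Athila", "c1:0-100"), 0.15)
  expect_equal(coverage_fraction(tr, "DNA", "c1:0-100"), 0)
  # prefix match is per '/'-component, not per character
  trx <- make_track("c1", 0, 50, "LTRX")
  expect_equal(coverage_fraction(trx, "LTR", "c1:0-100"), 0)
  full <- make_track("c1", 0, 100, "LTR/Copia")
  expect_equal(coverage_fraction(full, "LTR", "c1:0-100"), 1.0)
  expect_error(coverage_fraction(tr, "LTR", genomic_interval("c1", 5, 6))
               , NA)
})

test_that("coverage agrees exactly with the per-base oracle", {
  withr::local_seed(21)
  for (rep in 1:300) {
    n <- sample(1:15, 1)
    s <- sample(0:9000, n, replace = TRUE)
    e <- s + sample(1:2000, n, replace = TRUE)
    rs <- sample(0:5000, 1)
    re <- rs + sample(1:5000, 1)
    tr <- make_track("c1", s, e, rep("LTR/Gypsy", n))
    expect_identical(coverage_fraction(tr, "LTR", genomic_interval("c1", rs, re)),
                     coverage_brute_force(s, e, rs, re))
  }
})

test_that("enrichment tables report region, background and ratio", {
  # fractions engineered to the printed contrast: 59% vs 18% -> ratio 3.2778
  tr <- rbind(make_track("c1", 0, 5900, "LTR/Gypsy"),
              make_track("c2", 0, 82100, "LTR/Gypsy"))
  sizes <- c(c1 = 10000, c2 = 480000)
  tab <- enrichment_table(tr, "c1:0-10000", sizes, classes = "LTR/Gypsy")
  expect_equal(tab$region_fraction, 0.59)
  expect_equal(tab$background_fraction, 0.1796, tolerance = 1e-3)
  expect_equal(tab$ratio, 0.59 / tab$background_fraction)
  expect_equal(0.59 / 0.18, 3.2778, tolerance = 1e-4)

  # region == background: every ratio is 1
  tab2 <- enrichment_table(tr, "c1:0-10000",
                           list(genomic_interval("c1", 0, 10000)))
  expect_true(all(tab2$ratio == 1))

  # default class list: top-level prefixes plus full labels
  tr3 <- make_track("c1", c(0, 100), c(50, 150),
                    c("LTR/Gypsy", "DNA/Mutator"))
  tab3 <- enrichment_table(tr3, "c1:0-200", c(c1 = 200))
  expect_setequal(tab3$class, c("LTR", "DNA", "LTR/Gypsy", "DNA/Mutator"))
})

test_that("simulated TE coverage closes the loop with the enrichment module", {
  truth <- synthetic_truth(seed = 5)
  ann <- simulate_genome_annotations(truth)
  sizes <- unlist(truth$chrom_sizes)
  tab <- enrichment_table(ann$te, truth$array_region, sizes, classes = "LTR")
  expect_lt(abs(tab$region_fraction - 0.78), 0.03)
  expect_lt(abs(tab$background_fraction - 0.60), 0.03)
})

test_that("permutation test behaves at the extremes and is seeded", {
  sizes <- c(c1 = 100000, c2 = 100000)
  everywhere <- make_track(c("c1", "c2"), c(0, 0), c(100000, 100000),
                           c("LTR/Gypsy", "LTR/Gypsy"))
  expect_equal(permutation_test(everywhere, "LTR", "c1:0-10000", sizes,
                                n_perm = 200, seed = 1), 1)

  only_region <- make_track("c1", 20000, 30000, "LTR/Gypsy")
  p <- permutation_test(only_region, "LTR", "c1:20000-30000", sizes,
                        n_perm = 200, seed = 1)
  expect_lte(p, 1 / 201 + 0.05)

  p1 <- permutation_test(only_region, "LTR", "c1:20000-30000", sizes,
                         n_perm = 150, seed = 7)
  p2 <- permutation_test(only_region, "LTR", "c1:20000-30000", sizes,
                         n_perm = 150, seed = 7)
  expect_identical(p1, p2)
  expect_error(permutation_test(only_region, "LTR", "c1:20000-30000",
                                c(c1 = 30000), n_perm = 100, seed = 1),
               NA)
  expect_error(permutation_test(only_region, "LTR", "c1:20000-30000",
                                sizes, n_perm = 10), ">= 100")
})
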