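test_that("viewpoint profile is the mean over viewpoint bins", {
  sizes <- c(chrV = 100000, chrT = 150000)
  m <- make_map(sizes, 50000,
                list("chrV", 0, "chrT", 0, 4), list("chrV", 1, "chrT", 0, 2),
                list("chrV", 0, "chrT", 2, 1), list("chrV", 1, "chrT", 2, 3))
  prof <- extract_viewpoint_profile(m, "chrV:0-100000", "chrT")
  expect_equal(prof$values, c(3, 0, 2))

  # single-bin viewpoint equals that bin's contact row
  p1 <- extract_viewpoint_profile(m, "chrV:0-50000", "chrT")
  expect_equal(p1$values, c(4, 0, 1))

  # intrachromosomal: viewpoint bins reported but flagged
  mi <- make_map(c(chrV = 200000), 50000, list("chrV", 0, "chrV", 3, 5))
  pi <- extract_viewpoint_profile(mi, "chrV:0-100000", "chrV")
  expect_identical(pi$in_viewpoint, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("normalization drops zeros, logs, and z-scores with sample sd", {
  n <- normalize_profile(make_profile(c(4, 0, 16)))
  expect_identical(n$kept, c(TRUE, FALSE, TRUE))
  expect_equal(n$log2[n$kept], c(2, 4), tolerance = 1e-12)
  expect_equal(n$z[n$kept], c(-1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(n$z[n$kept], c(-0.70711, 0.70711), tolerance = 1e-5)

  n2 <- normalize_profile(make_profile(c(1, 2, 4, 8)))
  expect_equal(n2$log2, c(0, 1, 2, 3))
  expect_equal(n2$z, c(-1.16190, -0.38730, 0.38730, 1.16190),
               tolerance = 1e-5)

  expect_error(normalize_profile(make_profile(c(5, 0, 0))), "degenerate")
  expect_error(normalize_profile(make_profile(c(3, 3, 3))), "zero variance")
  # viewpoint-flagged bins are removed before the zero filter
  expect_error(normalize_profile(make_profile(c(9, 9, 4),
                                              c(TRUE, TRUE, FALSE))),
               "degenerate")
})

test_that("kept z-scores always standardize to mean 0, sample sd 1", {
  withr::local_seed(11)
  for (rep in 1:50) {
    vals <- rpois(sample(10:200, 1), sample(2:20, 1))
    if (sum(vals > 0) < 2 || length(unique(vals[vals > 0])) < 2) next
    n <- normalize_profile(make_profile(as.numeric(vals)))
    expect_lt(abs(mean(n$z[n$kept])), 1e-9)
    expect_lt(abs(sd(n$z[n$kept]) - 1), 1e-9)
  }
})

test_that("tail p-values match the erfc oracle and are antisymmetric", {
  expect_equal(tail_pvalue(0), 0.5)
  expect_equal(tail_pvalue(1.959964), 0.025, tolerance = 1e-6)
  expect_equal(tail_pvalue(-3), 0.998650, tolerance = 1e-6)
  z <- seq(-6, 6, by = 0.01)
  expect_equal(tail_pvalue(z), normal_tail_oracle(z), tolerance = 1e-9)
  expect_true(all(diff(tail_pvalue(z)) < 0))
  expect_equal(tail_pvalue(z) + tail_pvalue(-z), rep(1, length(z)),
               tolerance = 1e-12)
  expect_error(tail_pvalue(NaN), "non-finite")
})

test_that("BH adjustment matches stated examples and brute force", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  withr::local_seed(5)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute_force(p))
    # adjusted values never fall below the raw p-values
    expect_true(all(q >= p - 1e-12))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("the screen recovers a planted contact and excludes the viewpoint", {
  truth <- synthetic_truth(seed = 1, planted_fold = 8)
  map <- simulate_contact_map(truth)
  sc <- screen_genome(map, truth$bgc_core, alpha = 0.05)
  tb <- region_to_bins(truth$array_region, map$resolution)
  chr2 <- sc$table[sc$table$chrom == "chr2", ]
  expect_equal(chr2$bin[which.max(chr2$z)], tb)
  expect_true(any(chr2$significant[chr2$bin %in% tb]))

  own <- screen_genome(map, truth$bgc_core, scope = truth$bgc_chrom)
  vb <- region_to_bins(truth$bgc_core, map$resolution)
  inside <- own$table$bin %in% vb
  expect_true(all(own$table$in_viewpoint[inside]))
  expect_true(all(is.na(own$table$z[inside])))
  expect_false(any(own$table$significant[inside]))
})

test_that("null screens rarely call anything significant", {
  hits <- vapply(1:20, function(s) {
    truth <- synthetic_truth(seed = s, planted_fold = 1)
    sc <- screen_genome(simulate_contact_map(truth), truth$bgc_core,
                        alpha = 0.05)
    any(sc$table$significant)
  }, TRUE)
  expect_lte(mean(hits), 0.10)
})

test_that("targeted test matches hand computation and the screen", {
  # chromosome log2 values {1,2,3,4,5}: raw 2^x so the log2s come out exact
  sizes <- c(chrV = 50000, chrT = 250000)
  raw <- 2^(1:5)
  m <- make_map(sizes, 50000,
                list("chrV", 0, "chrT", 0, raw[1]),
                list("chrV", 0, "chrT", 1, raw[2]),
                list("chrV", 0, "chrT", 2, raw[3]),
                list("chrV", 0, "chrT", 3, raw[4]),
                list("chrV", 0, "chrT", 4, raw[5]))
  tt <- targeted_test(m, "chrV:0-50000", "chrT:200000-250000")
  expect_equal(tt$z, 2 / sqrt(2.5), tolerance = 1e-12)
  expect_lt(abs(tt$z - 1.26491), 1e-5)
  expect_lt(abs(tt$p - 0.10295), 1e-5)

  # candidate at the chromosome mean
  tmid <- targeted_test(m, "chrV:0-50000", "chrT:100000-150000")
  expect_equal(tmid$z, 0)
  expect_equal(tmid$p, 0.5)

  # single-bin candidate reproduces the screen's z and p exactly
  sc <- screen_genome(m, "chrV:0-50000", scope = "chrT")
  row <- sc$table[sc$table$bin == 4, ]
  expect_identical(tt$z, row$z)
  expect_identical(tt$p, row$p)

  expect_error(targeted_test(m, "chrV:0-50000", "chrT:0-1"),
               NA) # bin 0 is non-zero
  m0 <- make_map(sizes, 50000,
                 list("chrV", 0, "chrT", 0, 4), list("chrV", 0, "chrT", 1, 2),
                 list("chrV", 0, "chrT", 2, 1))
  expect_error(targeted_test(m0, "chrV:0-50000", "chrT:150000-250000"),
               "zero filter")
})

test_that("a planted fold-6 contact is individually significant at seed 1", {
  truth <- synthetic_truth(seed = 1)
  map <- simulate_contact_map(truth)
  tt <- targeted_test(map, truth$bgc_core, truth$array_region)
  expect_lt(tt$p, 0.01)
})
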