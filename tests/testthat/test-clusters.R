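fams <- c("LS", "IPR", "L3OH", "ISPD", "PR")

test_that("BGC chaining follows the gap rule and the 3-family floor", {
  genes <- rbind(gene_row("ls", "c1", 10000, 12000, "LS"),
                 gene_row("ipr", "c1", 100000, 102000, "IPR"),
                 gene_row("l3oh", "c1", 300000, 302000, "L3OH"))
  calls <- call_bgcs(genes, c("LS", "IPR", "L3OH"), max_gap = 400000)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_families, 3L)
  expect_equal(calls$start, 10000)
  expect_equal(calls$end, 302000)

  # ISPD 346 kb downstream: chained at 400 kb, split off at 300 kb
  genes2 <- rbind(genes, gene_row("ispd", "c1", 648000, 650000, "ISPD"))
  in400 <- call_bgcs(genes2, c("LS", "IPR", "L3OH", "ISPD"), max_gap = 400000)
  expect_equal(in400$n_members, 4L)
  expect_match(in400$member_ids, "ispd")
  out300 <- call_bgcs(genes2, c("LS", "IPR", "L3OH", "ISPD"), max_gap = 300000)
  expect_equal(nrow(out300), 1L)
  expect_equal(out300$n_members, 3L)
  expect_no_match(out300$member_ids, "ispd")

  # two families never make a BGC
  two <- rbind(gene_row("a", "c1", 0, 1000, "LS"),
               gene_row("b", "c1", 2000, 3000, "LS"),
               gene_row("c", "c1", 4000, 5000, "IPR"))
  expect_equal(nrow(call_bgcs(two, c("LS", "IPR"))), 0L)

  # intervening non-pathway genes do not break the chain
  genes3 <- rbind(genes, gene_row("x", "c1", 150000, 152000, "other"))
  expect_equal(nrow(call_bgcs(genes3, c("LS", "IPR", "L3OH"))), 1L)

  expect_warning(call_bgcs(genes, c(fams, "NOPE")), "NOPE")
})

test_that("chaining is monotone in max_gap", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    genes <- do.call(rbind, lapply(seq_len(n), function(k)
      gene_row(paste0("g", k), "c1", k * 50000 + sample(0:40000, 1), 0,
               sample(fams, 1))))
    genes$end <- genes$start + 2000
    gaps <- c(50000, 150000, 400000)
    members <- vapply(gaps, function(mg) {
      calls <- suppressWarnings(call_bgcs(genes, fams, max_gap = mg))
      if (nrow(calls)) sum(calls$n_members) else 0L
    }, 1L)
    expect_true(all(diff(members) >= 0))
  }
})

test_that("tandem arrays are maximal same-family runs", {
  pr3 <- rbind(gene_row("p1", "c1", 10000, 12000, "PR"),
               gene_row("p2", "c1", 30000, 32000, "PR"),
               gene_row("p3", "c1", 50000, 52000, "PR"))
  calls <- call_tandem_arrays(pr3)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_members, 3L)
  expect_equal(calls$n_families, 1L)

  expect_equal(nrow(call_tandem_arrays(pr3[1, ])), 0L)

  # an intervening pathway gene of another family breaks the run...
  broken <- rbind(pr3[1, ], gene_row("ls", "c1", 20000, 22000, "LS"), pr3[2:3, ])
  bcalls <- call_tandem_arrays(broken)
  expect_false(any(grepl("p1", bcalls$member_ids) &
                     grepl("p2", bcalls$member_ids)))
  # ...but a filler gene of family "other" does not
  filler <- rbind(pr3[1, ], gene_row("f", "c1", 20000, 22000, "other"),
                  pr3[2:3, ])
  expect_equal(call_tandem_arrays(filler)$n_members, 3L)

  # a gap beyond the threshold splits the run
  far <- pr3; far$start[3] <- 500000; far$end[3] <- 502000
  expect_equal(call_tandem_arrays(far)$n_members, 2L)
})

test_that("default synthetic truth yields one BGC and one PR array", {
  for (s in 1:5) {
    truth <- synthetic_truth(seed = s)
    ann <- simulate_genome_annotations(truth)
    bgc <- call_bgcs(ann$genes, fams, max_gap = 400000)
    expect_equal(nrow(bgc), 1L)
    expect_identical(bgc$families, "IPR,ISPD,L3OH,LS")
    bgc300 <- call_bgcs(ann$genes, fams, max_gap = 300000)
    expect_equal(nrow(bgc300), 1L)
    expect_no_match(bgc300$member_ids, "ISPD")

    arrays <- call_tandem_arrays(ann$genes)
    expect_equal(nrow(arrays), 1L)
    expect_equal(arrays$n_members, 3L)
    expect_identical(arrays$families, "PR")
    expect_identical(arrays$chrom, truth$array_region$chrom)
  }
})

test_that("call annotation delegates to coverage_fraction", {
  truth <- synthetic_truth(seed = 1)
  ann <- simulate_genome_annotations(truth)
  arrays <- annotate_calls(call_tandem_arrays(ann$genes), ann$te)
  direct <- coverage_fraction(ann$te, "LTR",
                              genomic_interval(arrays$chrom, arrays$start,
                                               arrays$end))
  expect_identical(arrays$ltr_fraction, direct)
  expect_lt(abs(arrays$ltr_fraction - truth$te_targets$array), 0.05)

  no_te <- annotate_calls(call_tandem_arrays(ann$genes),
                          make_track("c9", 0, 10, "LTR/Gypsy"))
  expect_equal(no_te$ltr_fraction, 0)
})
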