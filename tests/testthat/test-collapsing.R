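test_that("window tiling follows the step arithmetic", {
  v <- data.frame(variant_id = sprintf("V%02d", 1:24), chrom = "1",
                  pos = seq(0, 11500, by = 500))
  w <- make_windows(v, size = 5000, step = 2500)
  expect_equal(w$start, c(0, 2500, 5000, 7500, 10000))
  expect_equal(w$end, c(5000, 7500, 10000, 11501, 11501))  # truncated at span end
  # every variant in >= 1 window; interior variants in >= 2 (step = size/2)
  counts <- table(unlist(w$member_variants))
  expect_setequal(names(counts), v$variant_id)
  interior <- v$variant_id[v$pos >= 2500 & v$pos < 10000]
  expect_true(all(counts[interior] >= 2))
  expect_error(make_windows(v, size = 1000, step = 2000), "step")
  expect_error(make_windows(v, size = 0), "size")
})

test_that("a span shorter than the window gives a single covering window", {
  v <- data.frame(variant_id = c("A", "B"), chrom = "1", pos = c(10, 290))
  w <- make_windows(v, size = 5000, step = 2500)
  expect_equal(nrow(w), 1)
  expect_setequal(w$member_variants[[1]], c("A", "B"))
})

test_that("window membership respects half-open bounds on simulated positions", {
  co <- simulate_cohort(small_config())
  w <- make_windows(co$variants, size = 5000, step = 2500, genes = co$genes)
  pos <- setNames(co$variants$pos, co$variants$variant_id)
  for (i in sample(nrow(w), 25)) {
    m <- w$member_variants[[i]]
    expect_true(all(pos[m] >= w$start[i] & pos[m] < w$start[i] + 5000))
  }
  expect_setequal(unique(unlist(w$member_variants)), co$variants$variant_id)
})

test_that("carrier indicator applies the strict MAF threshold per subject", {
  g <- rbind(
    s1 = c(0L, 0L, 2L),
    s2 = c(1L, 0L, 2L),
    s3 = c(0L, 1L, 2L),
    s4 = c(0L, 0L, 1L)
  )
  g <- g[rep(1:4, times = c(1, 1, 1, 27)), ]  # V3 frequent, V1/V2 rare
  rownames(g) <- sprintf("s%02d", 1:30)
  colnames(g) <- c("V1", "V2", "V3")
  st <- carrier_status(g, c("V1", "V2", "V3"), maf_max = 0.05)
  expect_equal(unname(st[1:3]), c(0L, 1L, 1L))
  # V3 (common) does not make its carriers count
  expect_setequal(attr(st, "rare_variants"), c("V1", "V2"))
  expect_equal(unname(st[4]), 0L)
  # strict threshold: a variant at exactly the cutoff frequency is excluded
  g2 <- cbind(V1 = c(rep(1L, 5), rep(0L, 45)))  # MAF 0.05
  rownames(g2) <- sprintf("t%02d", 1:50)
  expect_null(carrier_status(g2, "V1", maf_max = 0.05))
  expect_error(carrier_status(g, character(0)), "non-empty")
  # missing dosages count as non-carrying
  g3 <- cbind(V1 = c(NA, 1L, rep(0L, 48)))
  rownames(g3) <- sprintf("u%02d", 1:50)
  st3 <- carrier_status(g3, "V1", maf_max = 0.05)
  expect_equal(unname(st3[1:2]), c(0L, 1L))
})

test_that("the minor allele is defined by the sample frequency", {
  # dosage column coded toward the major allele: frequency 0.96, so the
  # minor allele is the reference; its carriers are subjects with dosage <= 1
  g <- cbind(V1 = c(1L, rep(2L, 24)))
  rownames(g) <- sprintf("s%02d", 1:25)
  st <- carrier_status(g, "V1", maf_max = 0.05)
  expect_equal(as.vector(st), c(1L, rep(0L, 24)))
})

test_that("carrier_test picks the right test and p-value", {
  # equal carrier proportions: statistic 0, p = 1
  carr <- c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 180))
  aff <- c(rep(1, 100), rep(0, 200))
  r <- carrier_test(carr, aff)
  expect_equal(r$test_used, "chisq")
  expect_equal(r$p_value, 1.0)
  # sparse table: Fisher, against the exhaustive enumeration oracle
  carr2 <- c(rep(1, 5), rep(0, 95), rep(1, 1), rep(0, 199))
  aff2 <- c(rep(1, 100), rep(0, 200))
  r2 <- carrier_test(carr2, aff2)
  expect_equal(r2$test_used, "fisher")
  expect_equal(r2$p_value, fisher_enum_oracle(5, 95, 1, 199), tolerance = 1e-9)
  expect_equal(round(r2$p_value, 4), 0.0169)
  # degenerate margins are untestable
  r3 <- carrier_test(rep(1, 300), aff)
  expect_equal(r3$test_used, "none")
  expect_true(is.na(r3$p_value))
  expect_error(carrier_test(carr, rep(1, 300)), "classes")
})

test_that("single-SNP allelic test matches the textbook chi-square", {
  # proportional allele counts: p = 1
  dos <- c(rep(2, 5), rep(0, 45), rep(2, 10), rep(0, 90))
  aff <- c(rep(1, 50), rep(0, 100))
  r <- single_snp_test(dos, aff)
  expect_equal(r$p_value, 1.0)
  # cases 30/170 vs controls 20/380 minor/major alleles
  dos2 <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 180))
  aff2 <- c(rep(1, 100), rep(0, 200))
  r2 <- single_snp_test(dos2, aff2)
  expect_equal(r2$table[["case_minor"]], 30)
  expect_equal(r2$table[["control_minor"]], 20)
  expect_equal(r2$p_value, chisq_enum_oracle(30, 170, 20, 380), tolerance = 1e-12)
  # monomorphic: untestable
  r3 <- single_snp_test(rep(0, 300), aff2)
  expect_equal(r3$test_used, "none")
  expect_true(is.na(r3$p_value))
})

test_that("chi-square and Fisher converge on well-filled tables", {
  # asymptotic equivalence: the discrepancy shrinks as counts grow, and is
  # below 0.02 once cells are in the hundreds
  worst_at <- function(lo, hi, n_draws) {
    worst <- 0
    for (i in seq_len(n_draws)) {
      a <- sample(lo:hi, 1); b <- sample(lo:hi, 1)
      c <- sample(lo:hi, 1); d <- sample(lo:hi, 1)
      worst <- max(worst, abs(chisq_enum_oracle(a, b, c, d) -
                                rarepath:::fisher_p_2x2(a, b, c, d)))
    }
    worst
  }
  set.seed(77)
  w_small <- worst_at(40, 120, 60)
  w_large <- worst_at(2000, 6000, 60)
  expect_lt(w_large, w_small)
  expect_lt(w_large, 0.02)
})

test_that("collapsing power increases with the carrier effect", {
  pow <- vapply(c(0.3, 0.9, 1.5), function(eff) {
    hits <- 0
    for (s in 1:5) {
      co <- simulate_cohort(small_config(carrier_effect = eff, seed = 300 + s,
                                         n_subjects = 500))
      sc <- collapsing_scan(co, window_sizes = numeric(0), include_snp = FALSE)
      gw <- sc[sc$unit_kind == "gene" & sc$gene %in% co$truth$causal_genes, ]
      hits <- hits + sum(gw$p_value < 0.01, na.rm = TRUE)
    }
    hits
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], pow[1])
})

test_that("a strongly differential causal gene is detected gene-wise", {
  # aggregate carrier frequency ~0.15 in cases vs ~0.05 in controls at
  # n = 209/488; analytic power at alpha = 0.001 is ~0.85
  detected <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    n_case <- 209; n_ctrl <- 488
    carr <- c(rbinom(n_case, 1, 0.15), rbinom(n_ctrl, 1, 0.05))
    aff <- c(rep(1, n_case), rep(0, n_ctrl))
    r <- carrier_test(carr, aff)
    if (!is.na(r$p_value) && r$p_value < 0.001) detected <- detected + 1
  }
  expect_gte(detected / 50, 0.70)
})

test_that("scan output is consistent across unit kinds", {
  co <- simulate_cohort(small_config())
  sc <- collapsing_scan(co, window_sizes = c(5000), maf_max = 0.05)
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1, na.rm = TRUE))
  expect_true(all(sc$test_used %in% c("chisq", "fisher", "none")))
  # untestable iff flagged
  expect_identical(is.na(sc$p_value), sc$test_used == "none")
  # window unit count matches the tiling arithmetic
  w <- make_windows(co$variants, 5000, 2500)
  expect_equal(sum(sc$unit_kind == "window"), nrow(w))
  # no rare variants at a tiny threshold: every collapsing unit untestable
  sc0 <- collapsing_scan(co, window_sizes = c(5000), maf_max = 1e-6,
                         include_snp = FALSE)
  expect_true(all(sc0$test_used == "none"))
  # Manhattan coordinates drop untestable units and transform p
  mh <- manhattan_data(sc[sc$unit_kind == "window" & sc$size == 5000, ])
  expect_equal(nrow(mh), sum(sc$unit_kind == "window" & !is.na(sc$p_value)))
  expect_true(all(mh$neg_log10_p >= 0))
})
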