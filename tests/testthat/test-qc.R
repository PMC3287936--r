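test_that("HWE chi-square test matches hand-computed expectations", {
  # counts exactly at HWE expectation: statistic 0
  expect_equal(hwe_test(25, 50, 25), 1.0)
  # monomorphic convention
  expect_equal(hwe_test(100, 0, 0), 1.0)
  expect_equal(hwe_test(0, 0, 80), 1.0)
  # (10,10,10): allele freq 0.5, expected (7.5, 15, 7.5), statistic 10/3
  oracle <- pchisq(2.5^2 / 7.5 + 5^2 / 15 + 2.5^2 / 7.5, df = 1,
                   lower.tail = FALSE)
  expect_equal(hwe_test(10, 10, 10), oracle, tolerance = 1e-12)
  expect_equal(round(hwe_test(10, 10, 10), 3), 0.068)
  expect_error(hwe_test(0, 0, 0), "positive")
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  # vectorized
  expect_equal(hwe_test(c(25, 100), c(50, 0), c(25, 0)), c(1, 1))
})

test_that("HWE p-values are calibrated under binomial sampling", {
  set.seed(31)
  n <- 300
  maf <- runif(10000, 0.05, 0.5)
  g <- matrix(rbinom(n * 10000, 2, rep(maf, each = n)), n, 10000)
  cc <- rarepath:::genotype_counts(g)
  p <- hwe_test(cc[, 1], cc[, 2], cc[, 3])
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("hwe_filter removes deviating variants in controls only", {
  co <- simulate_cohort(small_config(n_subjects = 300))
  # inject a grossly deviating variant among controls (all heterozygous)
  bad <- co$genotypes
  ctrl <- co$phenotypes$subject_id[co$phenotypes$affected == 0]
  bad[rownames(bad) %in% ctrl, 1] <- 1L
  res <- hwe_filter(bad, co$phenotypes, alpha = 1e-4)
  expect_true(colnames(bad)[1] %in% res$removed$variant_id)
  expect_false(colnames(bad)[1] %in% colnames(res$genotypes))
  # alpha = 0: empty rejection region
  res0 <- hwe_filter(bad, co$phenotypes, alpha = 0)
  expect_equal(nrow(res0$removed), 0)
  # a variant with control counts (10,10,10) is removed at alpha = 0.1
  g2 <- bad
  g2[rownames(g2) %in% ctrl, 2] <- rep_len(c(0L, 1L, 2L), sum(rownames(g2) %in% ctrl))
  counts <- table(factor(g2[rownames(g2) %in% ctrl, 2], levels = 0:2))
  stopifnot(max(counts) - min(counts) <= 1)  # ~equal thirds
  res1 <- hwe_filter(g2, co$phenotypes, alpha = 0.1)
  expect_true(colnames(g2)[2] %in% res1$removed$variant_id)
  expect_error(hwe_filter(bad, transform(co$phenotypes, affected = 1)),
               "control")
})

test_that("under a panmictic null the HWE filter removes almost nothing", {
  # common-variant panel: the chi-square approximation needs expected
  # homozygote counts away from zero, which very rare variants cannot give
  co <- simulate_cohort(sim_config(n_genes = 1000, variants_per_gene = 10,
                                   n_sets = 10, n_populations = 1,
                                   divergence = 0, n_subjects = 400,
                                   rare_fraction = 0, very_rare_fraction = 0,
                                   carrier_effect = 0, seed = 17))
  res <- hwe_filter(co$genotypes, co$phenotypes, alpha = 1e-4)
  expect_lte(nrow(res$removed) / ncol(co$genotypes), 0.001)
})

test_that("correlated-marker pruning drops duplicates and keeps independents", {
  set.seed(5)
  g <- matrix(rbinom(200 * 20, 2, 0.3), 200, 20)
  colnames(g) <- sprintf("V%02d", 1:20)
  # duplicated column pair: exactly one survives
  g_dup <- cbind(g, V21 = g[, 1])
  kept <- prune_correlated(g_dup, r2_max = 0.2)
  expect_length(intersect(c("V01", "V21"), kept), 1)
  # r2_max = 1: nothing exceeds the threshold
  expect_setequal(prune_correlated(g_dup, r2_max = 1.0), colnames(g_dup))
  # independent variants all kept
  expect_setequal(prune_correlated(g, r2_max = 0.2), colnames(g))
  # deterministic given input order
  expect_identical(prune_correlated(g_dup), prune_correlated(g_dup))
  # single variant passes through
  expect_equal(prune_correlated(g[, 1, drop = FALSE]), "V01")
})

test_that("the 1-IBS distance is a metric-like dissimilarity", {
  set.seed(9)
  g <- matrix(rbinom(30 * 50, 2, 0.3), 30, 50)
  rownames(g) <- sprintf("S%02d", 1:30)
  d <- as.matrix(ibs_distance(g))
  expect_equal(diag(d), setNames(rep(0, 30), rownames(g)))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # identical subjects coincide
  g2 <- rbind(g, S31 = g[1, ])
  d2 <- as.matrix(ibs_distance(g2))
  expect_equal(d2["S01", "S31"], 0)
  mds <- mds_components(g2, k = 2)
  expect_equal(mds$coordinates["S01", ], mds$coordinates["S31", ],
               tolerance = 1e-8)
})

test_that("missing dosages are excluded pairwise in the IBS distance", {
  g <- rbind(A = c(0L, 2L, 2L), B = c(0L, 0L, NA))
  # complete pair: |0-0| and |2-0| -> mean over 3 variants rescaled from 2
  expect_equal(as.numeric(ibs_distance(g)), mean(c(0, 2) / 2))
})

test_that("MDS separates simulated populations", {
  co <- simulate_cohort(sim_config(n_subjects = 300, n_genes = 150,
                                   variants_per_gene = 8, n_sets = 15,
                                   divergence = 0.1, seed = 23))
  hw <- hwe_filter(co$genotypes, co$phenotypes)
  kept <- prune_correlated(hw$genotypes)
  mds <- mds_components(hw$genotypes[, kept, drop = FALSE], k = 2)
  set.seed(1)
  km <- kmeans(mds$coordinates, centers = 3, nstart = 10)
  agree <- best_label_agreement(km$cluster, co$phenotypes$population)
  expect_gte(agree, 0.9)
  expect_error(mds_components(co$genotypes, k = 300), "smaller")
})

test_that("MDS coordinates are invariant to subject order up to sign", {
  set.seed(13)
  g <- matrix(rbinom(40 * 200, 2, runif(200, 0.1, 0.5)[rep(1:200, each = 40)]),
              40, 200)
  rownames(g) <- sprintf("S%02d", 1:40)
  m1 <- mds_components(g, k = 2)
  perm <- sample(nrow(g))
  m2 <- mds_components(g[perm, ], k = 2)
  back <- m2$coordinates[rownames(g), ]
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(back[, j], m1$coordinates[, j], tolerance = 1e-6)) ||
                isTRUE(all.equal(-back[, j], m1$coordinates[, j], tolerance = 1e-6)))
  }
})
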