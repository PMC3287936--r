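make_panel <- function(seed = 1, n = 400, n_null = 30) {
  simulate_snp_panel(n_subjects = n, n_null = n_null, n_causal = 3,
                     effect = 1.0, seed = seed)
}

test_that("parameter invariants are enforced", {
  expect_error(sgb_params(max_terminal_nodes = 1), "max_terminal_nodes")
  expect_error(sgb_params(max_terminal_nodes = 13), "max_terminal_nodes")
  expect_error(sgb_params(shrinkage = 0), "shrinkage")
  expect_error(sgb_params(subsample_fraction = 1.5), "subsample_fraction")
})

test_that("an intercept-only model predicts the case fraction", {
  p <- make_panel()
  m <- fit_sgb(p$genotypes, p$affected, sgb_params(n_trees = 0, seed = 1))
  pred <- predict_sgb(m, p$genotypes)
  expect_equal(unique(round(pred, 12)), round(mean(p$affected), 12))
})

test_that("fits are deterministic under a fixed seed", {
  p <- make_panel()
  pars <- sgb_params(n_trees = 60, shrinkage = 0.1, seed = 5)
  m1 <- fit_sgb(p$genotypes, p$affected, pars)
  m2 <- fit_sgb(p$genotypes, p$affected, pars)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$train_score, m2$train_score)
  # subsample_fraction = 1: refit bit-identical too
  pars1 <- sgb_params(n_trees = 40, shrinkage = 0.1, subsample_fraction = 1,
                      seed = 2)
  expect_identical(fit_sgb(p$genotypes, p$affected, pars1)$train_score,
                   fit_sgb(p$genotypes, p$affected, pars1)$train_score)
})

test_that("a perfectly separating feature is learned to near-certainty", {
  set.seed(6)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  x <- cbind(sep = y, noise = matrix(rbinom(n * 5, 2, 0.3), n, 5))
  colnames(x) <- c("sep", paste0("n", 1:5))
  m <- fit_sgb(x, y, sgb_params(n_trees = 800, shrinkage = 0.05,
                                min_node = 5, seed = 3))
  pred <- predict_sgb(m, x)
  # training AUC
  auc <- mean(outer(pred[y == 1], pred[y == 0], ">") +
                0.5 * outer(pred[y == 1], pred[y == 0], "=="))
  expect_gte(auc, 0.99)
  imp <- variable_importance(m)
  expect_equal(imp$variable[1], "sep")
})

test_that("training deviance is non-increasing over iterations", {
  p <- make_panel(seed = 2)
  m <- fit_sgb(p$genotypes, p$affected,
               sgb_params(n_trees = 300, shrinkage = 0.01, seed = 7))
  score <- rep(m$base_score, nrow(p$genotypes))
  dev <- numeric(301)
  dev[1] <- binomial_deviance(p$affected, plogis(score))
  for (t in seq_along(m$trees)) {
    contrib <- rarepath:::sgb_predict_cpp(m$trees[t], p$genotypes, 0,
                                          m$params$shrinkage)
    score <- score + contrib
    dev[t + 1] <- binomial_deviance(p$affected, plogis(score))
  }
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("variable importance flags split variables only", {
  p <- make_panel(seed = 4)
  m <- fit_sgb(p$genotypes, p$affected,
               sgb_params(n_trees = 150, shrinkage = 0.05, seed = 9))
  imp <- variable_importance(m)
  expect_true(all(imp$raw_importance >= 0))
  expect_equal(max(imp$scaled_importance), 100)
  # never-split variables: zero importance, never selected
  zero <- imp$variable[imp$raw_importance == 0]
  expect_true(all(!imp$selected[imp$raw_importance == 0]))
  # cutoff 0 selects every split variable
  m0 <- m; m0$params$importance_cutoff <- 0
  imp0 <- variable_importance(m0)
  expect_setequal(imp0$variable[imp0$selected],
                  imp0$variable[imp0$raw_importance > 0])
  # permuting a never-split feature leaves predictions unchanged
  if (length(zero)) {
    x2 <- p$genotypes
    set.seed(11)
    x2[, zero[1]] <- sample(x2[, zero[1]])
    expect_equal(predict_sgb(m, x2), predict_sgb(m, p$genotypes))
  }
  # no-splits model: all zero, none selected
  mnone <- fit_sgb(p$genotypes, p$affected, sgb_params(n_trees = 0, seed = 1))
  impn <- variable_importance(mnone)
  expect_true(all(impn$raw_importance == 0))
  expect_false(any(impn$selected))
})

test_that("predictions are monotone in the additive score and in (0,1)", {
  p <- make_panel(seed = 8)
  m <- fit_sgb(p$genotypes, p$affected,
               sgb_params(n_trees = 100, shrinkage = 0.05, seed = 2))
  pred <- predict_sgb(m, p$genotypes)
  expect_true(all(pred > 0 & pred < 1))
  score <- rarepath:::sgb_predict_cpp(m$trees, p$genotypes, m$base_score,
                                      m$params$shrinkage)
  expect_identical(order(pred), order(score))
  expect_error(predict_sgb(m, p$genotypes[, -1]), "columns")
})

test_that("degenerate inputs are rejected", {
  p <- make_panel()
  expect_error(fit_sgb(p$genotypes, rep(1, nrow(p$genotypes))), "constant")
  bad <- p$genotypes; bad[1, 1] <- NA
  expect_error(fit_sgb(bad, p$affected), "missing")
})

test_that("predictions agree with a reference gradient-boosting oracle", {
  p <- make_panel(seed = 12, n = 500, n_null = 25)
  pars <- sgb_params(n_trees = 400, max_terminal_nodes = 8, shrinkage = 0.05,
                     subsample_fraction = 1, min_node = 5, seed = 3)
  mine <- fit_sgb(p$genotypes, p$affected, pars)
  pred_mine <- predict_sgb(mine, p$genotypes)
  ref <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.05, max_depth = 0,
                  grow_policy = "lossguide", max_leaves = 8, tree_method = "hist",
                  lambda = 0, gamma = 0, min_child_weight = 1, subsample = 1,
                  base_score = mean(p$affected), nthread = 1),
    data = xgboost::xgb.DMatrix(p$genotypes, label = p$affected),
    nrounds = 400, verbose = 0)
  pred_ref <- predict(ref, xgboost::xgb.DMatrix(p$genotypes))
  expect_lt(mean(abs(pred_mine - pred_ref)), 0.05)
})

test_that("models round-trip through the JSON schema", {
  p <- make_panel()
  m <- fit_sgb(p$genotypes, p$affected,
               sgb_params(n_trees = 30, shrinkage = 0.1, seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_sgb_model(m, f)
  back <- read_sgb_model(f)
  expect_equal(predict_sgb(back, p$genotypes), predict_sgb(m, p$genotypes))
})
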