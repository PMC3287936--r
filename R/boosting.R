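## boosting module: stochastic gradient boosting of affection status on SNP
## dosages, stratification components and environmental covariates, with
## split-gain variable importance and cutoff-based predictor selection.

#' Stochastic gradient boosting parameters
#'
#' Defaults follow common practice for case-control SNP screens: 5000 small
#' trees of at most 8 terminal nodes, shrinkage 0.01, 50% row subsampling,
#' and a scaled-importance selection cutoff of 7.00 (importance is rescaled
#' so the top predictor scores 100).
#'
#' @param n_trees Number of boosting iterations.
#' @param max_terminal_nodes Terminal nodes per tree (2 to 12).
#' @param shrinkage Learning rate in (0, 1].
#' @param subsample_fraction Row-sampling fraction in (0, 1], drawn without
#'   replacement each iteration.
#' @param importance_cutoff Scaled-importance selection threshold.
#' @param min_node Minimum observations per terminal node.
#' @param seed Integer seed.
#' @return Object of class `sgb_params`.
#' @export
sgb_params <- function(n_trees = 5000, max_terminal_nodes = 8, shrinkage = 0.01,
                       subsample_fraction = 0.5, importance_cutoff = 7.00,
                       min_node = 10, seed = 1) {
  if (max_terminal_nodes < 2 || max_terminal_nodes > 12)
    stopf("max_terminal_nodes must lie in [2, 12]")
  if (shrinkage <= 0 || shrinkage > 1) stopf("shrinkage must lie in (0, 1]")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stopf("subsample_fraction must lie in (0, 1]")
  if (n_trees < 0) stopf("n_trees must be non-negative")
  structure(list(n_trees = as.integer(n_trees),
                 max_terminal_nodes = as.integer(max_terminal_nodes),
                 shrinkage = shrinkage,
                 subsample_fraction = subsample_fraction,
                 importance_cutoff = importance_cutoff,
                 min_node = as.integer(min_node),
                 seed = as.integer(seed)),
            class = "sgb_params")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    if (!all(vapply(features, is.numeric, logical(1))))
      stopf("all feature columns must be numeric")
    features <- as.matrix(features)
  }
  if (is.null(colnames(features)))
    colnames(features) <- paste0("X", seq_len(ncol(features)))
  storage.mode(features) <- "double"
  features
}

#' Fit a stochastic gradient boosting model
#'
#' Binomial-deviance boosting: the intercept is the log-odds of the case
#' fraction; each iteration draws a row subsample without replacement, grows
#' a least-squares regression tree best-first (splits maximizing
#' squared-error reduction, up to `max_terminal_nodes` leaves) on the
#' negative gradient (affected minus fitted probability), sets leaf values by
#' the one-step Newton estimate, and adds the tree with weight `shrinkage`.
#' Split-gain contributions are accumulated per feature as raw variable
#' importance.
#'
#' @param features Subjects x variables numeric matrix or data frame; no
#'   missing values.
#' @param affected Binary outcome vector with both classes present.
#' @param params An [sgb_params()].
#' @return Object of class `sgb_model`: `base_score`, `trees` (per-tree node
#'   matrices: feature index (0-based, -1 = leaf), threshold, left, right,
#'   leaf value), `raw_importance`, `feature_names`, `params`,
#'   `train_score` (additive score on the training rows).
#' @export
fit_sgb <- function(features, affected, params = sgb_params()) {
  stopifnot(inherits(params, "sgb_params"))
  x <- as_feature_matrix(features)
  if (anyNA(x)) stopf("features must not contain missing values")
  y <- as.numeric(affected)
  if (length(y) != nrow(x)) stopf("features and outcome are misaligned")
  if (length(unique(y)) < 2) stopf("outcome is constant")
  fit <- with_seed(params$seed,
    sgb_fit_cpp(x, y, params$n_trees, params$max_terminal_nodes,
                params$shrinkage, params$subsample_fraction, params$min_node))
  structure(list(base_score = fit$base_score, trees = fit$trees,
                 raw_importance = setNames(fit$importance, colnames(x)),
                 feature_names = colnames(x), params = params,
                 train_score = as.numeric(fit$train_score)),
            class = "sgb_model")
}

#' Variable importance of a fitted boosting model
#'
#' Raw importance is the sum over all trees of the squared-error improvement
#' attributed to splits on each variable; scaled importance rescales so the
#' maximum is 100 (all zero when no split occurred). A variable is selected
#' when its scaled importance reaches the model's `importance_cutoff`.
#'
#' @param model An `sgb_model`.
#' @return Data frame sorted by descending importance: `variable`,
#'   `raw_importance`, `scaled_importance`, `selected`.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "sgb_model"))
  raw <- model$raw_importance
  scaled <- if (max(raw) > 0) 100 * raw / max(raw) else raw * 0
  out <- data.frame(variable = names(raw), raw_importance = unname(raw),
                    scaled_importance = unname(scaled),
                    selected = unname(scaled) >= model$params$importance_cutoff &
                      max(raw) > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$scaled_importance, out$variable), ]
  rownames(out) <- NULL
  out
}

#' Predict case probabilities from a boosting model
#'
#' Inverse-logit of the additive score (intercept plus shrinkage-weighted
#' tree contributions).
#'
#' @param model An `sgb_model`.
#' @param features Matrix or data frame with the training columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_sgb <- function(model, features) {
  stopifnot(inherits(model, "sgb_model"))
  x <- as_feature_matrix(features)
  if (!identical(colnames(x), model$feature_names))
    stopf("feature columns do not match the training columns")
  score <- sgb_predict_cpp(model$trees, x, model$base_score,
                           model$params$shrinkage)
  plogis(score)
}

#' Serialize / restore a boosting model as JSON
#'
#' The schema stores the intercept, hyperparameters, feature names and one
#' node table per tree (columns: feature, threshold, left, right, value).
#'
#' @param model An `sgb_model`.
#' @param path Output path.
#' @return Invisibly, `path` (for write) or the restored `sgb_model` (read).
#' @export
write_sgb_model <- function(model, path) {
  stopifnot(inherits(model, "sgb_model"))
  obj <- list(
    format = "rarepath-sgb-1",
    base_score = model$base_score,
    params = unclass(model$params),
    feature_names = model$feature_names,
    trees = lapply(model$trees, function(t) {
      colnames(t) <- c("feature", "threshold", "left", "right", "value")
      as.data.frame(t)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sgb_model
#' @export
read_sgb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rarepath-sgb-1"))
    stopf("not a serialized boosting model: %s", path)
  trees <- lapply(obj$trees, function(t) unname(as.matrix(t)))
  params <- do.call(sgb_params, obj$params[setdiff(names(obj$params), NULL)])
  structure(list(base_score = obj$base_score, trees = trees,
                 raw_importance = NULL, feature_names = obj$feature_names,
                 params = params, train_score = NULL),
            class = "sgb_model")
}
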