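#' The 13-member base-estimator roster
#'
#' The ensemble draws on thirteen regressor families spanning simple linear
#' models through boosted tree ensembles: ridge, lasso, k-neighbors,
#' support-vector, decision-tree, random-forest, extra-trees,
#' adaptive-boosting (AdaBoost.R2), bootstrap-aggregating (bagged trees),
#' gradient-boosting (exact greedy tree boosting), extreme-gradient-boosting
#' (histogram depth-wise), light-gradient-boosting (histogram leaf-wise), and
#' categorical-gradient-boosting (least-squares boosting over trees fitted
#' directly on the promoter factors rather than their one-hot expansion).
#' Hyperparameters are pinned defaults treated as part of the experiment
#' definition; per-estimator seeds are derived deterministically from
#' `master_seed`.
#'
#' @param master_seed Integer; seeds each stochastic estimator reproducibly.
#' @return A tibble with columns `name`, `family`, `seed`, and a `hyperparams`
#'   list-column, in fixed roster order.
#' @examples
#' default_roster(1)$family
#' @export
default_roster <- function(master_seed = 1L) {
  families <- estimator_families()
  tibble::tibble(
    name = families,
    family = families,
    seed = as.integer((master_seed * 1009L + 97L * seq_along(families)) %% .Machine$integer.max),
    hyperparams = purrr::map(families, default_hyperparams)
  )
}

#' @rdname default_roster
#' @export
estimator_families <- function() {
  c("ridge", "lasso", "k-neighbors", "support-vector", "decision-tree",
    "random-forest", "extra-trees", "adaptive-boosting",
    "bootstrap-aggregating", "gradient-boosting", "extreme-gradient-boosting",
    "light-gradient-boosting", "categorical-gradient-boosting")
}

default_hyperparams <- function(family) {
  switch(family,
    "ridge" = list(lambda = 1),
    "lasso" = list(lambda = 1),
    "k-neighbors" = list(k = 5),
    "support-vector" = list(kernel = "radial", cost = 10, epsilon = 0.1),
    "decision-tree" = list(maxdepth = 8, minsplit = 5, cp = 0.001),
    "random-forest" = list(ntree = 200),
    "extra-trees" = list(num.trees = 200, mtry_frac = 1 / 3),
    "adaptive-boosting" = list(n_rounds = 40, maxdepth = 3),
    "bootstrap-aggregating" = list(n_bags = 40, maxdepth = 8, minsplit = 5, cp = 0.001),
    "gradient-boosting" = list(nrounds = 150, eta = 0.1, max_depth = 3,
                               subsample = 1, tree_method = "exact"),
    "extreme-gradient-boosting" = list(nrounds = 150, eta = 0.1, max_depth = 4,
                                       subsample = 0.9, colsample_bytree = 0.9,
                                       tree_method = "hist"),
    "light-gradient-boosting" = list(nrounds = 150, eta = 0.1, max_leaves = 15,
                                     subsample = 0.9, tree_method = "hist",
                                     grow_policy = "lossguide"),
    "categorical-gradient-boosting" = list(n_rounds = 400, shrinkage = 0.08,
                                           maxdepth = 5),
    abort(paste0("unknown estimator family: ", family))
  )
}

#' Fit one base estimator
#'
#' Dispatches on the roster `family`, fitting to a one-hot feature matrix `x`
#' and titer vector `y`. The categorical-gradient-boosting family instead
#' decodes the one-hot blocks back to promoter factors (via `spec`) and boosts
#' trees on those factors directly.
#'
#' @param est One roster row (list or one-row tibble with `family`,
#'   `hyperparams`, `seed`).
#' @param x Numeric feature matrix.
#' @param y Numeric response (titer, mg/L).
#' @param spec The `library_spec` defining the one-hot block layout (needed by
#'   the categorical family; optional otherwise).
#' @return A `base_fit` object with a `predict` method.
#' @export
fit_estimator <- function(est, x, y, spec = NULL) {
  if (is.data.frame(est)) {
    stopifnot(nrow(est) == 1)
    est <- list(name = est$name, family = est$family,
                hyperparams = est$hyperparams[[1]], seed = est$seed)
  }
  hp <- est$hyperparams
  family <- est$family
  if (sd(y) == 0) { # degenerate target: every family reduces to the constant fit
    return(structure(list(name = est$name, family = "constant", fit = y[1],
                          n_features = ncol(x), spec = spec),
                     class = "base_fit"))
  }
  fit <- with_seed(est$seed, switch(family,
    "ridge" = glmnet::glmnet(x, y, alpha = 0, lambda = hp$lambda),
    "lasso" = glmnet::glmnet(x, y, alpha = 1, lambda = hp$lambda),
    "k-neighbors" = caret::knnreg(x, y, k = hp$k),
    # binary features need no scaling (and constant columns would warn)
    "support-vector" = e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                                  epsilon = hp$epsilon, scale = FALSE),
    "decision-tree" = fit_rpart(x, y, hp),
    "random-forest" = randomForest::randomForest(x, y, ntree = hp$ntree),
    "extra-trees" = ranger::ranger(
      y = y, x = as.data.frame(x), num.trees = hp$num.trees,
      mtry = max(1, floor(ncol(x) * hp$mtry_frac)),
      splitrule = "extratrees", seed = est$seed, num.threads = 1),
    "adaptive-boosting" = fit_adaboost_r2(x, y, hp),
    "bootstrap-aggregating" = fit_bagged_trees(x, y, hp),
    "gradient-boosting" = fit_xgb(x, y, hp, est$seed),
    "extreme-gradient-boosting" = fit_xgb(x, y, hp, est$seed),
    "light-gradient-boosting" = fit_xgb(x, y, hp, est$seed),
    "categorical-gradient-boosting" = fit_cat_boost(x, y, hp, spec),
    abort(paste0("unknown estimator family: ", family))
  ))
  structure(list(name = est$name, family = family, fit = fit,
                 n_features = ncol(x), spec = spec),
            class = "base_fit")
}

#' Predict from a fitted base estimator
#' @param object A `base_fit`.
#' @param x New one-hot feature matrix (same width as training).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.base_fit <- function(object, x, ...) {
  if (ncol(x) != object$n_features) {
    abort(sprintf("feature width %d does not match training width %d",
                  ncol(x), object$n_features))
  }
  fit <- object$fit
  out <- switch(object$family,
    "constant" = rep(fit, nrow(x)),
    "ridge" = ,
    "lasso" = as.numeric(predict(fit, x)),
    "k-neighbors" = predict(fit, x),
    "support-vector" = as.numeric(predict(fit, x)),
    "decision-tree" = predict_rpart(fit, x),
    "random-forest" = as.numeric(predict(fit, x)),
    "extra-trees" = predict(fit, data = as.data.frame(x), num.threads = 1)$predictions,
    "adaptive-boosting" = predict_adaboost_r2(fit, x),
    "bootstrap-aggregating" = predict_bagged_trees(fit, x),
    "gradient-boosting" = ,
    "extreme-gradient-boosting" = ,
    "light-gradient-boosting" = predict(fit, xgboost::xgb.DMatrix(x)),
    "categorical-gradient-boosting" = predict_cat_boost(fit, x, object$spec),
    abort(paste0("unknown estimator family: ", object$family))
  )
  as.numeric(out)
}

# ---- family helpers ---------------------------------------------------------

fit_rpart <- function(x, y, hp) {
  d <- data.frame(y = y, x)
  rpart::rpart(y ~ ., data = d, method = "anova",
               control = rpart::rpart.control(maxdepth = hp$maxdepth,
                                              minsplit = hp$minsplit,
                                              cp = hp$cp, xval = 0))
}

predict_rpart <- function(fit, x) {
  unname(predict(fit, data.frame(x)))
}

fit_xgb <- function(x, y, hp, seed) {
  params <- list(objective = "reg:squarederror", eta = hp$eta,
                 subsample = hp$subsample %||% 1,
                 tree_method = hp$tree_method %||% "hist",
                 nthread = 1, seed = seed)
  if (!is.null(hp$max_depth)) params$max_depth <- hp$max_depth
  if (!is.null(hp$colsample_bytree)) params$colsample_bytree <- hp$colsample_bytree
  if (!is.null(hp$grow_policy)) {
    params$grow_policy <- hp$grow_policy
    params$max_depth <- 0
    params$max_leaves <- hp$max_leaves
  }
  xgboost::xgb.train(params = params, data = xgboost::xgb.DMatrix(x, label = y),
                     nrounds = hp$nrounds, verbose = 0)
}

# AdaBoost.R2 (Drucker 1997) with shallow regression trees: reweighted
# bootstrap rounds, linear loss, weighted-median prediction
fit_adaboost_r2 <- function(x, y, hp) {
  n <- length(y)
  w <- rep(1 / n, n)
  members <- list()
  betas <- numeric(0)
  for (r in seq_len(hp$n_rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tree <- fit_rpart(x[idx, , drop = FALSE], y[idx],
                      list(maxdepth = hp$maxdepth, minsplit = 5, cp = 0.001))
    pred <- predict_rpart(tree, x)
    err <- abs(pred - y)
    denom <- max(err)
    if (denom <= 0) { # perfect member: keep it and stop
      members[[length(members) + 1]] <- tree
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / denom
    ebar <- sum(w * loss)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    members[[length(members) + 1]] <- tree
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (!length(members)) { # degenerate data: fall back to a single tree
    members <- list(fit_rpart(x, y, list(maxdepth = hp$maxdepth, minsplit = 5, cp = 0.001)))
    betas <- 0.5
  }
  list(members = members, log_inv_beta = log(1 / betas))
}

predict_adaboost_r2 <- function(fit, x) {
  preds <- vapply(fit$members, predict_rpart, numeric(nrow(x)), x = x)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(x))
  wts <- fit$log_inv_beta
  apply(preds, 1, function(p) weighted_median(p, wts))
}

weighted_median <- function(v, w) {
  o <- order(v)
  cw <- cumsum(w[o])
  v[o][which(cw >= sum(w) / 2)[1]]
}

fit_bagged_trees <- function(x, y, hp) {
  n <- length(y)
  lapply(seq_len(hp$n_bags), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_rpart(x[idx, , drop = FALSE], y[idx], hp)
  })
}

predict_bagged_trees <- function(fit, x) {
  preds <- vapply(fit, predict_rpart, numeric(nrow(x)), x = x)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(x))
  rowMeans(preds)
}

# least-squares gradient boosting with trees grown on the promoter factors
# themselves (categorical splits), not the one-hot expansion
fit_cat_boost <- function(x, y, hp, spec) {
  if (is.null(spec)) {
    abort("categorical-gradient-boosting needs the library_spec block layout")
  }
  d <- one_hot_to_factors(x, spec)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", hp$n_rounds)
  for (r in seq_len(hp$n_rounds)) {
    dd <- cbind(data.frame(.r = resid), d)
    tree <- rpart::rpart(.r ~ ., data = dd, method = "anova",
                         control = rpart::rpart.control(maxdepth = hp$maxdepth,
                                                        minsplit = 5, cp = 0,
                                                        xval = 0))
    step <- predict(tree, dd)
    trees[[r]] <- tree
    resid <- resid - hp$shrinkage * step
  }
  list(f0 = f0, trees = trees, shrinkage = hp$shrinkage)
}

predict_cat_boost <- function(fit, x, spec) {
  d <- one_hot_to_factors(x, spec)
  out <- rep(fit$f0, nrow(d))
  for (tree in fit$trees) out <- out + fit$shrinkage * predict(tree, d)
  unname(out)
}

one_hot_to_factors <- function(x, spec) {
  a <- decode_one_hot(x, spec)
  d <- as.data.frame(lapply(seq_along(spec$positions), function(i) {
    factor(a[[i]], levels = spec$alphabet[[i]]$id)
  }))
  names(d) <- make.names(spec$positions)
  d
}
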