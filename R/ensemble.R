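#' Root mean square error
#'
#' `sqrt(mean((measured - predicted)^2))` between measured and predicted
#' titers.
#'
#' @param measured,predicted Equal-length numeric vectors (mg/L).
#' @return A non-negative scalar; 0 iff the vectors are identical.
#' @examples
#' rmse(c(0, 1, 2), c(0, 2, 2)) # sqrt(1/3)
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    abort("`measured` and `predicted` lengths differ")
  }
  if (!length(measured)) abort("need at least one observation")
  sqrt(mean((measured - predicted)^2))
}

#' Pearson correlation coefficient
#'
#' Pearson correlation between measured and predicted titers. A constant
#' vector has no defined correlation and raises an error rather than
#' silently returning 0 — a constant screen readout is a degenerate dataset
#' worth surfacing.
#'
#' @inheritParams rmse
#' @return A value in \[-1, 1\].
#' @examples
#' pcc(c(0, 1, 2), c(0, 2, 2))
#' @export
pcc <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    abort("`measured` and `predicted` lengths differ")
  }
  if (length(measured) < 2) abort("correlation needs at least two observations")
  if (sd(measured) == 0 || sd(predicted) == 0) {
    abort("correlation is undefined for a constant vector")
  }
  cor(measured, predicted)
}

#' Cross-validation configuration
#'
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 10, seed = 1L) {
  stopifnot(folds >= 2)
  structure(list(folds = as.integer(folds), seed = as.integer(seed)),
            class = "cv_config")
}

# deterministic shuffled fold assignment: 1..folds recycled then permuted
cv_fold_ids <- function(n, cv) {
  if (cv$folds > n) abort("more folds than observations")
  with_seed(cv$seed, sample(rep_len(seq_len(cv$folds), n)))
}

#' Rank base estimators by cross-validated RMSE
#'
#' Fits every roster estimator per fold, pools the out-of-fold predictions
#' over all samples, and sorts the roster ascending by CV RMSE (ties keep
#' roster order). An estimator that fails to fit is recorded with infinite
#' RMSE and a warning instead of aborting the run.
#'
#' @param data A data frame with one promoter column per library position and
#'   a `titer` column (mg/L).
#' @param spec The `library_spec` describing the promoter columns.
#' @param roster A [default_roster()]-shaped tibble.
#' @param cv A [cv_config()].
#' @param target `"log"` (default) fits every base estimator to log-titer and
#'   back-transforms its predictions; `"identity"` fits the raw titer. Titers
#'   are strictly positive with multiplicative assay error, so the log scale
#'   is the natural regression scale; all RMSE/PCC metrics remain on the raw
#'   mg/L scale either way.
#' @return A tibble sorted by `cv_rmse` with columns `name`, `family`,
#'   `cv_rmse`, and list-columns `oof` (pooled out-of-fold predictions in data
#'   order) and `spec_row` (the roster row), plus attributes `measured` and
#'   `fold_id`.
#' @export
cv_rank <- function(data, spec, roster = default_roster(), cv = cv_config(),
                    target = c("log", "identity")) {
  stopifnot(is.data.frame(data), "titer" %in% names(data))
  target <- match.arg(target)
  x <- encode_one_hot(data, spec)
  y <- data$titer
  if (target == "log" && any(y <= 0)) {
    abort("log-target fitting requires strictly positive titers")
  }
  y_fit <- if (target == "log") log(y) else y
  back <- if (target == "log") exp else identity
  fold_id <- cv_fold_ids(length(y), cv)
  rows <- purrr::map(seq_len(nrow(roster)), function(i) {
    est <- roster[i, ]
    oof <- rep(NA_real_, length(y))
    ok <- TRUE
    for (f in seq_len(cv$folds)) {
      test <- fold_id == f
      pred <- tryCatch({
        fit <- fit_estimator(est, x[!test, , drop = FALSE], y_fit[!test],
                             spec = spec)
        back(predict(fit, x[test, , drop = FALSE]))
      }, error = function(e) {
        warning(sprintf("estimator '%s' failed in fold %d: %s",
                        est$name, f, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(pred)) { ok <- FALSE; break }
      oof[test] <- pred
    }
    tibble::tibble(
      name = est$name, family = est$family,
      cv_rmse = if (ok) rmse(y, oof) else Inf,
      oof = list(if (ok) oof else rep(NA_real_, length(y))),
      spec_row = list(est)
    )
  })
  ranked <- dplyr::bind_rows(rows)
  ranked <- ranked[order(ranked$cv_rmse), , drop = FALSE] # stable: ties keep roster order
  attr(ranked, "measured") <- y
  attr(ranked, "fold_id") <- fold_id
  attr(ranked, "target") <- target
  ranked
}

#' Greedy forward ensemble selection
#'
#' Starting from the top-ranked estimator, scans the remaining candidates in
#' rank order; a candidate joins the ensemble iff the uniform average of the
#' members' pooled out-of-fold predictions plus the candidate's strictly
#' lowers the ensemble RMSE. Rejected candidates are skipped and the scan
#' continues to the end of the roster, so the accepted-state RMSE trace is
#' strictly decreasing.
#'
#' @param ranked Output of [cv_rank()].
#' @param measured Measured titers; defaults to the vector carried by
#'   `ranked`.
#' @return An `ensemble_model` (unfitted members) with fields `members`
#'   (roster rows of accepted estimators, in acceptance order), `trace`
#'   (per-candidate tibble: `candidate`, `rmse_if_added`, `accepted`,
#'   `ensemble_rmse`), `oof` (ensemble out-of-fold predictions), `cv_rmse`,
#'   `cv_pcc`.
#' @export
greedy_select <- function(ranked, measured = attr(ranked, "measured")) {
  if (!nrow(ranked)) abort("`ranked` must contain at least one estimator")
  if (is.null(measured)) abort("`measured` titers are required")
  usable <- is.finite(ranked$cv_rmse)
  if (!any(usable)) abort("no estimator produced finite cross-validated RMSE")
  ranked <- ranked[usable, , drop = FALSE]
  sum_pred <- ranked$oof[[1]]
  k <- 1L
  current_rmse <- rmse(measured, sum_pred)
  members <- ranked$spec_row[1]
  trace <- list(tibble::tibble(candidate = ranked$name[1],
                               rmse_if_added = current_rmse, accepted = TRUE,
                               ensemble_rmse = current_rmse))
  for (i in seq_len(nrow(ranked))[-1]) {
    cand_rmse <- rmse(measured, (sum_pred + ranked$oof[[i]]) / (k + 1))
    accept <- cand_rmse < current_rmse
    if (accept) {
      sum_pred <- sum_pred + ranked$oof[[i]]
      k <- k + 1L
      current_rmse <- cand_rmse
      members <- c(members, ranked$spec_row[i])
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      candidate = ranked$name[i], rmse_if_added = cand_rmse,
      accepted = accept, ensemble_rmse = current_rmse)
  }
  oof <- sum_pred / k
  structure(list(
    members = members,
    trace = dplyr::bind_rows(trace),
    oof = oof,
    measured = measured,
    cv_rmse = current_rmse,
    cv_pcc = tryCatch(pcc(measured, oof), error = function(e) NA_real_),
    fits = NULL, spec = NULL
  ), class = "ensemble_model")
}

#' Fit the full greedy ensemble pipeline
#'
#' Runs [cv_rank()] and [greedy_select()] on a training set, then refits each
#' accepted member on the full data so the model can score new designs. The
#' returned model carries both the cross-validated selection metrics and the
#' fitted members.
#'
#' @inheritParams cv_rank
#' @return A fitted `ensemble_model`; see [greedy_select()] for the
#'   selection fields, plus `fits` (fitted members), `ranking` (the cv_rank
#'   table without prediction columns), and `spec`.
#' @examples
#' \donttest{
#' spec <- default_library_spec()
#' d <- simulate_screen(spec, n = 120, seed = 7)
#' m <- fit_ensemble(d, spec, roster = default_roster(1)[c(1, 2, 5), ],
#'                   cv = cv_config(5, 1))
#' glance(m)
#' }
#' @export
fit_ensemble <- function(data, spec, roster = default_roster(), cv = cv_config(),
                         target = c("log", "identity")) {
  target <- match.arg(target)
  ranked <- cv_rank(data, spec, roster, cv, target = target)
  model <- greedy_select(ranked)
  x <- encode_one_hot(data, spec)
  y_fit <- if (target == "log") log(data$titer) else data$titer
  model$fits <- purrr::map(model$members, fit_estimator, x = x,
                           y = y_fit, spec = spec)
  model$target <- target
  model$ranking <- dplyr::select(ranked, "name", "family", "cv_rmse")
  model$spec <- spec
  model$cv <- cv
  model
}

#' Predict titers with a fitted ensemble
#'
#' The ensemble prediction is the unweighted mean of the member predictions.
#'
#' @param object A fitted `ensemble_model` (from [fit_ensemble()]).
#' @param newdata A data frame of promoter assignments, or a one-hot matrix.
#' @param ... Unused.
#' @return Numeric predicted titers (mg/L).
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  if (is.null(object$fits)) {
    abort("this ensemble has no fitted members; use fit_ensemble()")
  }
  x <- if (is.matrix(newdata)) newdata else encode_one_hot(newdata, object$spec)
  back <- if (identical(object$target, "log")) exp else identity
  preds <- vapply(object$fits, function(f) back(predict(f, x)), numeric(nrow(x)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(x))
  rowMeans(preds)
}

#' @export
print.ensemble_model <- function(x, ...) {
  nm <- vapply(x$members, function(m) m$name, character(1))
  cat("<ensemble_model> ", length(nm), " member(s): ",
      paste(nm, collapse = ", "), "\n", sep = "")
  cat(sprintf("  CV RMSE %.4g mg/L, CV PCC %.4g  (%s)\n",
              x$cv_rmse, x$cv_pcc,
              if (is.null(x$fits)) "selection only" else "fitted"))
  invisible(x)
}

#' @export
tidy.ensemble_model <- function(x, ...) {
  x$trace
}

#' @export
glance.ensemble_model <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    cv_rmse = x$cv_rmse,
    cv_pcc = x$cv_pcc,
    n_train = length(x$measured)
  )
}

#' @export
autoplot.ensemble_model <- function(object, ...) {
  d <- tibble::tibble(measured = object$measured, predicted = object$oof)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "measured titer (mg/L)",
                  y = "out-of-fold predicted titer (mg/L)",
                  title = sprintf("CV RMSE %.0f mg/L, PCC %.2f",
                                  object$cv_rmse, object$cv_pcc))
}

#' Selection-trace plot
#'
#' Ensemble RMSE after each accepted candidate during greedy forward
#' selection.
#'
#' @param model An `ensemble_model`.
#' @return A ggplot.
#' @export
plot_selection_trace <- function(model) {
  tr <- dplyr::mutate(model$trace, step = dplyr::row_number())
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$ensemble_rmse)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted)) +
    ggplot2::labs(x = "candidate (rank order)", y = "ensemble CV RMSE (mg/L)",
                  colour = "accepted")
}

#' Evaluate a roster + greedy selection by cross-validation
#'
#' Convenience wrapper: runs the selection pipeline and returns the pooled
#' out-of-fold ensemble metrics as a one-row tibble.
#'
#' @inheritParams cv_rank
#' @return A tibble with `cv_rmse`, `cv_pcc`, `n_members`, `n_train`.
#' @export
evaluate_ensemble <- function(data, spec, roster = default_roster(), cv = cv_config(),
                              target = c("log", "identity")) {
  ranked <- cv_rank(data, spec, roster, cv, target = match.arg(target))
  glance(greedy_select(ranked))[, c("cv_rmse", "cv_pcc", "n_members", "n_train")]
}
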