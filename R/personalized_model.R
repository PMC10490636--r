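#' Model configuration for personalized training
#'
#' @param learner Learner name. Only `"extra_trees"` (the study's
#'   best-performing regressor) is available offline; `"lightgbm"` and
#'   `"catboost"` are recognized names that raise an informative error.
#' @param train_fraction Fraction of training-iteration rows used to fit
#'   (remainder is the validation split), default 0.8.
#' @param cv_folds Cross-validation folds on the training split (default
#'   5); `0` skips CV for speed.
#' @param n_trees Trees in the forest (default 100).
#' @param seed Integer seed controlling the split, the folds and the fit.
#' @return A `model_config` list.
#' @export
model_config <- function(learner = "extra_trees", train_fraction = 0.8,
                         cv_folds = 5L, n_trees = 100L, seed = 1L) {
  learner <- match.arg(learner, c("extra_trees", "lightgbm", "catboost"))
  if (learner != "extra_trees") {
    stop("learner ", sQuote(learner), " is not available in this ",
         "installation; use \"extra_trees\"", call. = FALSE)
  }
  stopifnot(train_fraction > 0, train_fraction < 1,
            cv_folds == 0L || cv_folds >= 2L, n_trees >= 1L)
  structure(list(learner = learner, train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "model_config")
}

# deterministic stratified assignment: returns logical "in training part"
.stratified_split <- function(strata, fraction, seed) {
  set.seed(seed)
  keep <- logical(length(strata))
  for (g in split(seq_along(strata), strata)) {
    n_tr <- max(1L, round(length(g) * fraction))
    keep[sample(g, n_tr)] <- TRUE
  }
  keep
}

# deterministic stratified fold ids 1..k
.stratified_folds <- function(strata, k, seed) {
  set.seed(seed + 1L)
  fold <- integer(length(strata))
  for (g in split(seq_along(strata), strata)) {
    fold[sample(g)] <- rep_len(seq_len(k), length(g))
  }
  fold
}

#' Train one participant's personalized model
#'
#' Fits the configured learner on a stratified 80/20 train/validation
#' split of the participant's training-iteration feature matrix
#' (stratified by carried weight, so every weight class is represented in
#' training), reports stratified k-fold cross-validated MAE on the
#' training split, and extracts feature importances. One model is trained
#' per participant: load distributions are individual enough that models
#' do not transfer.
#'
#' @param features_train A [build_feature_matrix()] result for a single
#'   participant.
#' @param config A [model_config()].
#' @return A `participant_model`: list with `fit`, `features`,
#'   `importance` (40 values), `cv_mae` (per-fold), `validation` (an
#'   `eval_report` on the held-out 20%), `participant_id` and `config`.
#' @export
train_participant <- function(features_train, config = model_config()) {
  stopifnot(inherits(features_train, "feature_matrix") ||
            is.data.frame(features_train))
  feats <- model_feature_names()
  miss <- setdiff(c(feats, "label"), names(features_train))
  if (length(miss)) {
    stop("feature matrix is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pid <- unique(stats::na.omit(features_train$participant_id))
  if (length(pid) > 1L) {
    stop("personalized models are per participant; got rows from: ",
         paste(pid, collapse = ", "), call. = FALSE)
  }
  y <- features_train$label
  if (length(unique(y)) < 2L) {
    stop("cannot learn a weight mapping from a single label value",
         call. = FALSE)
  }
  if (config$cv_folds > 0L && nrow(features_train) < 2L * config$cv_folds) {
    stop("need at least ", 2L * config$cv_folds, " rows for ",
         config$cv_folds, "-fold cross-validation", call. = FALSE)
  }
  x <- as.matrix(features_train[feats])
  strata <- features_train$carried_weight %||% y
  in_train <- .stratified_split(strata, config$train_fraction, config$seed)

  fit <- extra_trees(x[in_train, , drop = FALSE], y[in_train],
                     n_trees = config$n_trees, seed = config$seed)
  validation <- if (any(!in_train)) {
    evaluate_predictions(y[!in_train],
                         predict(fit, x[!in_train, , drop = FALSE]))
  } else NULL

  cv_mae <- if (config$cv_folds > 0L) {
    xi <- x[in_train, , drop = FALSE]
    yi <- y[in_train]
    fold <- .stratified_folds(strata[in_train], config$cv_folds, config$seed)
    vapply(seq_len(config$cv_folds), function(f) {
      ftr <- extra_trees(xi[fold != f, , drop = FALSE], yi[fold != f],
                         n_trees = config$n_trees, seed = config$seed + f)
      mean(abs(yi[fold == f] - predict(ftr, xi[fold == f, , drop = FALSE])))
    }, numeric(1L))
  } else numeric(0L)

  structure(list(participant_id = if (length(pid)) pid else NA_character_,
                 fit = fit, features = feats,
                 importance = setNames(fit$importance, feats),
                 cv_mae = cv_mae, validation = validation, config = config),
            class = "participant_model")
}

#' @param object A `participant_model`.
#' @param newdata A feature matrix (data.frame or matrix) containing the
#'   40 training feature columns; extra columns are ignored, missing ones
#'   are an error.
#' @param ... Unused.
#' @rdname train_participant
#' @export
predict.participant_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("prediction input is missing feature columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  predict(object$fit, as.matrix(as.data.frame(newdata)[object$features]))
}

#' @export
print.participant_model <- function(x, ...) {
  cat(sprintf("<participant_model> %s: %s, CV MAE %s\n",
              x$participant_id, x$config$learner,
              if (length(x$cv_mae)) sprintf("%.3f lbs", mean(x$cv_mae))
              else "not computed"))
  invisible(x)
}

#' Five-metric evaluation report
#'
#' Computes, from prediction errors `e_i = y_i - yhat_i`: MAE (lbs), MSE
#' (lbs^2), RMSE (lbs), the coefficient of determination R^2 (with the
#' total sum of squares taken about the mean of the supplied ground
#' truths) and MAPE, reported as a fraction (multiply by 100 for
#' percent).
#'
#' @param y_true Ground-truth total weights (lbs), all non-zero.
#' @param y_pred Predicted weights, same length.
#' @param carried_weight Optional per-row carried weight; when given, the
#'   report includes a per-weight-class MAE breakdown.
#' @return An `eval_report`: list with `mae`, `mse`, `rmse`, `r2`,
#'   `mape`, `n` and optionally `per_weight_mae` (data.frame).
#' @examples
#' evaluate_predictions(c(100, 110), c(101, 108))
#' @export
evaluate_predictions <- function(y_true, y_pred, carried_weight = NULL) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  if (any(y_true == 0)) {
    stop("MAPE is undefined for zero ground-truth weights", call. = FALSE)
  }
  e <- y_true - y_pred
  mse <- mean(e^2)
  sst <- sum((y_true - mean(y_true))^2)
  r2 <- if (sst == 0) {
    warning("zero-variance ground truth: R^2 undefined", call. = FALSE)
    NaN
  } else 1 - sum(e^2) / sst
  rep <- list(mae = mean(abs(e)), mse = mse, rmse = sqrt(mse), r2 = r2,
              mape = mean(abs(e / y_true)), n = length(e))
  if (!is.null(carried_weight)) {
    stopifnot(length(carried_weight) == length(e))
    by_w <- vapply(split(abs(e), carried_weight), mean, numeric(1L))
    rep$per_weight_mae <- data.frame(carried_weight = as.numeric(names(by_w)),
                                     mae = unname(by_w))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d: MAE %.3f lbs, MSE %.3f, RMSE %.3f lbs, R2 %.3f, MAPE %.2f%%\n",
    x$n, x$mae, x$mse, x$rmse, x$r2, 100 * x$mape))
  invisible(x)
}

#' Average evaluation reports across participants
#'
#' Unweighted arithmetic mean of each metric over the supplied reports
#' (the convention used for cohort summary rows).
#'
#' @param reports Non-empty list of `eval_report` objects.
#' @return An `eval_report` with the averaged metrics; `n` is the number
#'   of reports averaged.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1L), "eval_report")))
  avg <- function(f) mean(vapply(reports, `[[`, numeric(1L), f))
  structure(list(mae = avg("mae"), mse = avg("mse"), rmse = avg("rmse"),
                 r2 = avg("r2"), mape = avg("mape"), n = length(reports)),
            class = "eval_report")
}
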