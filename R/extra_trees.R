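#' Extremely randomized trees regression
#'
#' Minimal deterministic ExtraTrees regressor: every tree is grown on the
#' full sample, candidate splits use one uniform random cut point per
#' candidate feature, and nodes are grown until pure (so an unconstrained
#' forest reproduces its training labels exactly). This is the learner the
#' personalized models default to; see [train_participant()].
#'
#' @param x Numeric feature matrix (rows = instances).
#' @param y Numeric response vector.
#' @param n_trees Number of trees (default 100).
#' @param mtry Candidate features per split; default all columns, the
#'   conventional ExtraTrees regression setting.
#' @param min_split Minimum node size eligible for splitting (default 2,
#'   i.e. fully grown).
#' @param seed Integer seed; fits are bit-reproducible given the seed.
#' @return An `extra_trees` object (predict with [predict.extra_trees()]);
#'   component `importance` holds normalized impurity-decrease feature
#'   importances.
#' @export
extra_trees <- function(x, y, n_trees = 100L, mtry = NULL, min_split = 2L,
                        seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (is.null(mtry)) mtry <- ncol(x)
  fit <- .et_fit(x, y, as.integer(n_trees), as.integer(mtry),
                 as.integer(min_split), as.integer(seed))
  structure(list(forest = fit, importance = setNames(fit$importance,
                                                     colnames(x)),
                 features = colnames(x), n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), min_split = as.integer(min_split),
                 seed = as.integer(seed)),
            class = "extra_trees")
}

#' @param object An `extra_trees` fit.
#' @param newdata Matrix or data.frame with the training feature columns.
#' @param ... Unused.
#' @rdname extra_trees
#' @export
predict.extra_trees <- function(object, newdata, ...) {
  newdata <- as.matrix(if (!is.null(object$features) &&
                           !is.null(colnames(newdata)))
                         newdata[, object$features, drop = FALSE]
                       else newdata)
  storage.mode(newdata) <- "double"
  .et_predict(object$forest, newdata)
}

#' @export
print.extra_trees <- function(x, ...) {
  cat(sprintf("<extra_trees> %d trees, mtry %d, min_split %d\n",
              x$n_trees, x$mtry, x$min_split))
  invisible(x)
}
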