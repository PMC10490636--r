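#' Run the full per-participant experiment protocol
#'
#' End to end, for every eligible participant in the inventory: pool the
#' training iterations' raw channels and fit the adaptive bias table;
#' build bias-corrected, windowed, trimmed-mean feature matrices for the
#' training and test iterations (the bias stays frozen on test data);
#' train the personalized model on the training matrix; predict the test
#' iteration and compute the five-metric report together with a
#' per-weight-class MAE breakdown and the feature importances.
#'
#' The default protocol mirrors the controlled-setting design: iterations
#' 1 and 3 train (80/20 train/validation within them), iteration 2 tests.
#' For a two-iteration design use `protocol = list(train = 1, test = 2)`.
#'
#' @param inventory An [scan_dataset()] inventory with a ground-truth
#'   table.
#' @param protocol List with integer vectors `train` and scalar `test`.
#' @param bias_mode `"fab"`, `"zrab"` or `"none"`.
#' @param l_samples,olap_init,alpha Windowing and trimming parameters
#'   (defaults 100, 0.2, 15 — the ablation-selected operating point).
#' @param activities Activities used (default `"standing"`).
#' @param config A [model_config()].
#' @param on_all_zero Passed to [compute_bias()].
#' @param participants Optional subset of participant ids; default: all
#'   eligible per [select_participants()].
#' @return An `experiment_result`: list with `reports` (named list of
#'   `eval_report`s), `cohort` (their [aggregate_reports()] average),
#'   `importance` (participants x 40 matrix), `per_weight_mae`
#'   (long data.frame), `models`, `n_train_rows`, and `params`.
#' @export
run_experiment <- function(inventory,
                           protocol = list(train = c(1L, 3L), test = 2L),
                           bias_mode = "fab", l_samples = 100,
                           olap_init = 0.2, alpha = 15,
                           activities = "standing",
                           config = model_config(),
                           on_all_zero = "error",
                           participants = NULL) {
  stopifnot(inherits(inventory, "insole_inventory"))
  if (is.null(inventory$ground_truth)) {
    stop("inventory has no ground-truth weight table", call. = FALSE)
  }
  if (is.null(participants)) {
    participants <- select_participants(inventory, activities = activities)
  }
  if (!length(participants)) {
    stop("no eligible participants in the inventory", call. = FALSE)
  }
  manifest <- inventory$manifest
  manifest <- manifest[manifest$activity %in% activities, , drop = FALSE]
  need_iters <- c(protocol$train, protocol$test)
  raw <- raw_feature_names()

  reports <- list()
  models <- list()
  importance <- NULL
  pw <- list()
  n_train_rows <- integer(0)
  for (pid in participants) {
    m <- manifest[manifest$participant_id == pid, , drop = FALSE]
    wc_weights <- sort(unique(m$carried_weight))
    complete <- vapply(need_iters, function(it) {
      setequal(m$carried_weight[m$iteration == it], wc_weights)
    }, logical(1L))
    if (!all(complete)) {
      warning("participant ", pid, " is missing iteration(s) ",
              paste(need_iters[!complete], collapse = ", "),
              "; skipped", call. = FALSE)
      next
    }
    gt <- inventory$ground_truth
    bw <- gt$body_weight_lbs[match(pid, gt$participant_id)]
    if (is.na(bw)) {
      warning("participant ", pid, " has no ground-truth weight; skipped",
              call. = FALSE)
      next
    }
    wc <- weight_class(wc_weights)
    load_rows <- function(iters) {
      rows <- m[m$iteration %in% iters, , drop = FALSE]
      lapply(seq_len(nrow(rows)), function(r) {
        load_recording(rows$path[r], participant_id = pid)
      })
    }
    train_recs <- load_rows(protocol$train)
    test_recs <- load_rows(protocol$test)

    # bias is fit on the pooled raw channels of the training iterations only
    samples_by_weight <- lapply(setNames(wc$weights, wc$weights), function(w) {
      do.call(rbind, lapply(
        Filter(function(r) attr(r, "key")$carried_weight == w, train_recs),
        function(r) as.matrix(r[raw])))
    })
    bias <- compute_bias(samples_by_weight, wc, on_all_zero = on_all_zero)

    fm_train <- build_feature_matrix(train_recs, bias, bw, mode = bias_mode,
                                     l_samples = l_samples,
                                     olap_init = olap_init, alpha = alpha)
    fm_test <- build_feature_matrix(test_recs, bias, bw, mode = bias_mode,
                                    l_samples = l_samples,
                                    olap_init = olap_init, alpha = alpha)
    model <- train_participant(fm_train, config)
    pred <- predict(model, fm_test)
    rep <- evaluate_predictions(fm_test$label, pred,
                                carried_weight = fm_test$carried_weight)
    reports[[pid]] <- rep
    models[[pid]] <- model
    importance <- rbind(importance, model$importance)
    rownames(importance)[nrow(importance)] <- pid
    pw[[pid]] <- cbind(participant_id = pid, rep$per_weight_mae)
    n_train_rows[pid] <- nrow(fm_train)
  }
  if (!length(reports)) {
    stop("no participant completed the protocol", call. = FALSE)
  }
  structure(list(
    reports = reports, cohort = aggregate_reports(reports),
    importance = importance,
    per_weight_mae = do.call(rbind, c(pw, list(make.row.names = FALSE))),
    models = models, n_train_rows = n_train_rows,
    params = list(protocol = protocol, bias_mode = bias_mode,
                  l_samples = l_samples, olap_init = olap_init,
                  alpha = alpha, activities = activities, config = config)),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d participants, bias %s, l_samples %g, alpha %g\n",
              length(x$reports), x$params$bias_mode, x$params$l_samples,
              x$params$alpha))
  print(x$cohort)
  invisible(x)
}
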