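#' Plan dynamic windows over a recording
#'
#' Recordings differ in length, which would otherwise bias the model
#' toward the longer ones. Dynamic windowing derives the window geometry
#' from the sequence length itself: with user parameters `l_samples` (the
#' initial window-length parameter) and `olap_init` (initial overlap
#' rate),
#'
#' \deqn{Win_{init} = L / l_{samples}, \quad
#'       Olap_{new} = olap_{init} \cdot Win_{init}, \quad
#'       Win_{new} = (L + Olap_{new} \cdot Win_{init}) / l_{samples}}
#'
#' so every recording yields on the order of `l_samples` windows
#' regardless of its duration. Window boundaries are materialized with
#' length `round(Win_new)` (floored at 1), stride
#' `length - round(Olap_new)` (floored at 1), and the trailing partial
#' window dropped.
#'
#' @param l_data Sequence length in samples (`L`).
#' @param l_samples Initial window-length parameter (default 100). Larger
#'   values give smaller windows and more training instances.
#' @param olap_init Initial overlap rate in `[0, 1)` (default 0.2).
#' @return A `window_plan`: list with `win_init`, `olap_new`, `win_new`,
#'   `length`, `stride`, `n_windows` and integer matrix `bounds`
#'   (`start`, `end`, 1-based inclusive).
#' @examples
#' p <- plan_windows(1000, 100, 0.2)
#' c(p$win_new, p$length, p$stride)  # 10.2, 10, 8
#' @export
plan_windows <- function(l_data, l_samples = 100, olap_init = 0.2) {
  stopifnot(l_data >= 1, l_samples >= 1, olap_init >= 0, olap_init < 1)
  if (l_data < l_samples) {
    warning("sequence shorter than l_samples (", l_data, " < ", l_samples,
            "): using a single full-sequence window", call. = FALSE)
    bounds <- cbind(start = 1L, end = as.integer(l_data))
    return(structure(list(l_data = l_data, l_samples = l_samples,
                          olap_init = olap_init, win_init = l_data / l_samples,
                          olap_new = 0, win_new = l_data,
                          length = as.integer(l_data), stride = as.integer(l_data),
                          n_windows = 1L, bounds = bounds),
                     class = "window_plan"))
  }
  win_init <- l_data / l_samples
  olap_new <- olap_init * win_init
  win_new <- (l_data + olap_new * win_init) / l_samples
  len <- max(1L, as.integer(round(win_new)))
  stride <- max(1L, len - as.integer(round(olap_new)))
  starts <- seq.int(1L, by = stride, length.out = (l_data - len) %/% stride + 1L)
  bounds <- cbind(start = starts, end = starts + len - 1L)
  structure(list(l_data = l_data, l_samples = l_samples,
                 olap_init = olap_init, win_init = win_init,
                 olap_new = olap_new, win_new = win_new,
                 length = len, stride = stride,
                 n_windows = nrow(bounds), bounds = bounds),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf(
    "<window_plan> L=%d, l_samples=%g, olap_init=%g -> win_new=%.3f; %d windows of %d samples, stride %d\n",
    x$l_data, x$l_samples, x$olap_init, x$win_new, x$n_windows, x$length,
    x$stride))
  invisible(x)
}

#' Alpha-trimmed mean
#'
#' Sorts the values, removes `k = floor(alpha * n / 100)` from each end
#' and returns the arithmetic mean of the remainder, discarding the
#' extreme points where outliers and noise concentrate. `alpha = 0`
#' reduces to the arithmetic mean and `alpha = 50` to the median.
#'
#' @param x Non-empty numeric vector.
#' @param alpha Trim percentage in `[0, 50]`.
#' @return The trimmed mean (scalar).
#' @examples
#' trimmed_mean(c(1, 2, 3, 4, 100), 20)  # 3: trims 1 and 100
#' @export
trimmed_mean <- function(x, alpha) {
  n <- length(x)
  stopifnot(n >= 1L, is.numeric(x), alpha >= 0, alpha <= 50)
  k <- floor(alpha * n / 100)
  if (2 * k >= n) {
    k_adj <- floor((n - 1) / 2)
    warning("trim k = ", k, " would remove all ", n,
            " values; reduced to k = ", k_adj, call. = FALSE)
    k <- k_adj
  }
  s <- sort.int(x)
  mean(s[(k + 1L):(n - k)])
}

#' Synthesize the six derived features
#'
#' Appends to the 34 raw features (32 pressures + 2 per-foot total
#' forces) the per-foot pressure sums, the combined pressure sum, the
#' combined pressure average (over all 32 cells), the combined force sum
#' (left + right total force) and the combined force average.
#'
#' @param x Numeric matrix (or single row) with the 34
#'   [raw_feature_names()] columns.
#' @return Matrix with the 40 [model_feature_names()] columns.
#' @export
synthesize_features <- function(x) {
  x <- if (is.null(dim(x))) matrix(x, 1L, dimnames = list(NULL, names(x)))
       else as.matrix(x)
  raw <- raw_feature_names()
  if (is.null(colnames(x))) {
    stopifnot(ncol(x) == length(raw))
    colnames(x) <- raw
  }
  stopifnot(identical(colnames(x), raw))
  lp <- x[, sprintf("pressure_l_%02d", 1:16), drop = FALSE]
  rp <- x[, sprintf("pressure_r_%02d", 1:16), drop = FALSE]
  ps_l <- rowSums(lp)
  ps_r <- rowSums(rp)
  fs <- x[, "total_force_l"] + x[, "total_force_r"]
  cbind(x,
        pressure_sum_l = ps_l, pressure_sum_r = ps_r,
        pressure_sum = ps_l + ps_r, pressure_avg = (ps_l + ps_r) / 32,
        force_sum = fs, force_avg = fs / 2)
}

# aggregate one corrected raw-feature matrix into windowed trimmed means
# (compiled hot path; contract-equivalent to trimmed_mean() per cell)
.window_aggregate <- function(mat, plan, alpha) {
  out <- .window_trimmed_means(mat, plan$bounds[, "start"], plan$length,
                               alpha)
  colnames(out) <- colnames(mat)
  out
}

#' Build the windowed 40-feature matrix for one participant
#'
#' For each recording: correct the 34 raw channels with the participant's
#' bias table (indexed by the recording's position in the weight class),
#' segment with [plan_windows()], aggregate every window and channel with
#' [trimmed_mean()], then recompute the six synthesized features from the
#' corrected values. One row per window; the label is
#' `body_weight + carried_weight` (lbs).
#'
#' @param recordings List of `insole_recording` objects (one participant).
#' @param bias A [compute_bias()] table for that participant (fit on
#'   training iterations only).
#' @param body_weight The participant's ground-truth body weight (lbs).
#' @param mode Bias mode passed to [apply_bias()].
#' @param l_samples,olap_init Dynamic-windowing parameters.
#' @param alpha Trim percentage.
#' @return A `feature_matrix`: data.frame with the 40
#'   [model_feature_names()] columns, `label`, and provenance columns
#'   `participant_id`, `carried_weight`, `iteration`, `window`.
#' @export
build_feature_matrix <- function(recordings, bias, body_weight,
                                 mode = "fab", l_samples = 100,
                                 olap_init = 0.2, alpha = 15) {
  stopifnot(inherits(bias, "bias_table"), body_weight > 0)
  raw <- raw_feature_names()
  chunks <- list()
  for (rec in recordings) {
    key <- attr(rec, "key")
    stopifnot(inherits(key, "recording_key"))
    if (nrow(rec) == 0L) {
      warning("skipping empty recording ", format_filename(key), call. = FALSE)
      next
    }
    i <- weight_index(bias$weight_class, key$carried_weight)
    corrected <- apply_bias(as.matrix(rec[raw]), bias, i, mode)
    plan <- plan_windows(nrow(corrected), l_samples, olap_init)
    agg <- .window_aggregate(corrected, plan, alpha)
    full <- synthesize_features(agg)
    chunk <- data.frame(full, check.names = FALSE)
    chunk$label <- body_weight + key$carried_weight
    chunk$participant_id <- attr(rec, "participant_id") %||% NA_character_
    chunk$carried_weight <- key$carried_weight
    chunk$iteration <- key$iteration
    chunk$window <- seq_len(nrow(chunk))
    chunks[[length(chunks) + 1L]] <- chunk
  }
  if (!length(chunks)) stop("no non-empty recordings supplied", call. = FALSE)
  fm <- do.call(rbind, chunks)
  rownames(fm) <- NULL
  if (anyNA(fm[model_feature_names()])) {
    stop("feature matrix contains missing values", call. = FALSE)
  }
  structure(fm, class = c("feature_matrix", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
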