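#' Construct a weight class
#'
#' The weight class `Wc` is the ordered set of carried dumbbell weights a
#' participant performed recordings with, always starting at 0 (no weight).
#' Its length `L_Wc` and the 1-based index `i` of each weight drive the
#' adaptive bias: heavier readings receive proportionally larger
#' corrections.
#'
#' @param weights Strictly increasing numeric vector of carried weights
#'   (lbs) with `weights[1] == 0`.
#' @return A `weight_class`: list with `weights` and `length`.
#' @examples
#' wc <- weight_class(c(0, 2, 3, 5, 7, 9, 11, 13))
#' wc$length            # 8
#' weight_index(wc, 13) # 8
#' @export
weight_class <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) < 1L || weights[1L] != 0) {
    stop("a weight class must start at 0 lbs (no carried weight)", call. = FALSE)
  }
  if (is.unsorted(weights, strictly = TRUE)) {
    stop("weight-class weights must be strictly increasing", call. = FALSE)
  }
  structure(list(weights = weights, length = length(weights)),
            class = "weight_class")
}

#' @rdname weight_class
#' @param wc A `weight_class`.
#' @param w A carried weight belonging to the class.
#' @return `weight_index()`: the 1-based index of `w` within the class.
#' @export
weight_index <- function(wc, w) {
  stopifnot(inherits(wc, "weight_class"))
  i <- match(w, wc$weights)
  if (is.na(i)) {
    stop("carried weight ", w, " lbs is not in the weight class (",
         paste(wc$weights, collapse = ", "), ")", call. = FALSE)
  }
  i
}

#' Compute the automated adaptive bias table
#'
#' For each feature `j`, the bias anchor `m_j` is the minimum
#' strictly-positive value of that feature among the samples recorded at
#' the *maximum* weight of the class; if the feature is zero throughout
#' those recordings, the search falls back to the next-highest weight,
#' repeating until a non-zero minimum is found. The correction for
#' weight-class index `i` is then
#' `B[j, i] = m_j * i / L_Wc` — linear and strictly increasing in `i`, so
#' adding it restores a positive correlation between carried weight and
#' the corrected feature even for channels that read 0.
#'
#' The bias adapts per feature (each channel has its own scale) and per
#' participant (each person has their own load distribution). It should be
#' computed from training iterations only and reused frozen on held-out
#' data.
#'
#' @param samples_by_weight Named list, one element per carried weight in
#'   the class (names are the weights), each a numeric matrix or
#'   data.frame of per-sample feature values (columns = features, shared
#'   across weights).
#' @param wc The participant's [weight_class()].
#' @param on_all_zero What to do when a feature is zero across every
#'   weight: `"error"` (default) or `"zero"` (bias 0 with a warning).
#' @return A `bias_table`: list with matrix `B` (features x `L_Wc`),
#'   vector `m`, `source_weight` (weight that supplied each `m_j`),
#'   `weight_class` and `features` (column names).
#' @examples
#' wc <- weight_class(c(0, 2, 3, 5, 7, 9, 11, 13))
#' s <- lapply(setNames(wc$weights, wc$weights),
#'             function(w) matrix(8, 2, 1, dimnames = list(NULL, "f")))
#' compute_bias(s, wc)$B["f", ]  # 1, 2, ..., 8
#' @export
compute_bias <- function(samples_by_weight, wc,
                         on_all_zero = c("error", "zero")) {
  on_all_zero <- match.arg(on_all_zero)
  stopifnot(inherits(wc, "weight_class"))
  ws <- as.numeric(names(samples_by_weight))
  if (anyNA(ws) || !setequal(ws, wc$weights)) {
    stop("samples_by_weight must have one element per weight in the class",
         call. = FALSE)
  }
  mats <- lapply(samples_by_weight[order(ws)], function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  feats <- colnames(mats[[1L]])
  if (is.null(feats)) feats <- sprintf("f%02d", seq_len(ncol(mats[[1L]])))
  for (m in mats) stopifnot(ncol(m) == length(feats))
  nf <- length(feats)
  m_j <- rep(NA_real_, nf)
  src <- rep(NA_real_, nf)
  for (j in seq_len(nf)) {
    for (k in rev(seq_along(mats))) {       # max weight first, then fall back
      v <- mats[[k]][, j]
      v <- v[v > 0]
      if (length(v)) {
        m_j[j] <- min(v)
        src[j] <- sort(wc$weights)[k]
        break
      }
    }
  }
  if (anyNA(m_j)) {
    dead <- feats[is.na(m_j)]
    if (on_all_zero == "error") {
      stop("feature(s) zero across all weight classes: ",
           paste(dead, collapse = ", "),
           " (set on_all_zero = \"zero\" to bias them by 0)", call. = FALSE)
    }
    warning("feature(s) zero across all weight classes, bias set to 0: ",
            paste(dead, collapse = ", "), call. = FALSE)
    m_j[is.na(m_j)] <- 0
  }
  B <- outer(m_j, seq_len(wc$length) / wc$length)
  dimnames(B) <- list(feats, as.character(wc$weights))
  structure(list(B = B, m = setNames(m_j, feats),
                 source_weight = setNames(src, feats),
                 weight_class = wc, features = feats),
            class = "bias_table")
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("<bias_table> %d features x %d weight classes (weights: %s)\n",
              nrow(x$B), ncol(x$B),
              paste(x$weight_class$weights, collapse = ", ")))
  invisible(x)
}

#' Apply an adaptive bias to per-sample feature values
#'
#' Updates sensor features as `S' = S + B[j, i]`. In full-adaptive-bias
#' mode (`"fab"`) the correction is added to every sample of every
#' feature; in zero-reading mode (`"zrab"`) only samples reading exactly 0
#' are updated (no epsilon band — near-zero readings pass through, which
#' is precisely ZRAB's documented weakness); `"none"` returns the input
#' unchanged.
#'
#' A corrected matrix carries attribute `bias_applied = TRUE`; applying a
#' bias twice is an error, since the correction is defined exactly once
#' per sample.
#'
#' @param x Numeric matrix or data.frame of per-sample raw feature values;
#'   column names must match the bias table's features.
#' @param bias A [compute_bias()] table.
#' @param i Weight-class index of the recording being corrected (see
#'   [weight_index()]).
#' @param mode `"fab"`, `"zrab"` or `"none"` (default `"fab"`, the mode
#'   that ablation selects).
#' @return Corrected numeric matrix with attribute `bias_applied`.
#' @export
apply_bias <- function(x, bias, i, mode = c("fab", "zrab", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bias, "bias_table"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (isTRUE(attr(x, "bias_applied"))) {
    stop("bias has already been applied to this matrix", call. = FALSE)
  }
  if (!is.null(colnames(x))) {
    if (!identical(colnames(x), bias$features)) {
      stop("feature columns do not match the bias table", call. = FALSE)
    }
  } else if (ncol(x) != nrow(bias$B)) {
    stop("feature count does not match the bias table", call. = FALSE)
  }
  if (!(is.numeric(i) && length(i) == 1L && i >= 1 && i <= ncol(bias$B))) {
    stop("weight-class index i must be in 1..", ncol(bias$B), call. = FALSE)
  }
  b <- bias$B[, i]
  out <- switch(mode,
    none = x,
    fab  = sweep(x, 2L, b, `+`),
    zrab = x + (x == 0) * rep(b, each = nrow(x)))
  attr(out, "bias_applied") <- mode != "none"
  out
}
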