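#' Canonical insole channel schema
#'
#' Column names of a recording exported from a pair of instrumented insoles:
#' a timestamp plus, per foot, 16 pressure channels (N/cm^2), the total
#' ground-reaction force (N), 3-axis acceleration (g), 3-axis angular rate
#' (dps) and the center of pressure as fractions of insole length/width —
#' 51 columns in all.
#'
#' The vendor text export does not document a column order, so this manifest
#' is the package's canonical convention; [load_recording()] accepts any
#' column order when a header is present, and a user-supplied `col_map` can
#' rename foreign headers onto this schema.
#'
#' @return Character vector of the 51 canonical column names, starting with
#'   `"time"`.
#' @examples
#' length(insole_channels())  # 51
#' @export
insole_channels <- function() {
  side <- function(s) {
    c(sprintf("pressure_%s_%02d", s, 1:16),
      paste0("total_force_", s),
      paste0("acc_", s, "_", c("x", "y", "z")),
      paste0("gyro_", s, "_", c("x", "y", "z")),
      paste0("cop_", s, "_", c("x", "y")))
  }
  c("time", side("l"), side("r"))
}

#' Model feature names
#'
#' `raw_feature_names()` gives the 34 channels the regression model starts
#' from (16 pressures per foot plus each foot's total force).
#' `model_feature_names()` appends the 6 synthesized features (per-foot
#' pressure sums, combined pressure sum and average, combined force sum and
#' average) for the full 40-feature schema.
#'
#' @return Character vector of length 34 (`raw_feature_names`) or 40
#'   (`model_feature_names`).
#' @seealso [synthesize_features()]
#' @export
raw_feature_names <- function() {
  c(sprintf("pressure_l_%02d", 1:16),
    sprintf("pressure_r_%02d", 1:16),
    "total_force_l", "total_force_r")
}

#' @rdname raw_feature_names
#' @export
model_feature_names <- function() {
  c(raw_feature_names(),
    "pressure_sum_l", "pressure_sum_r", "pressure_sum", "pressure_avg",
    "force_sum", "force_avg")
}

# channels that must be non-negative in a valid recording
.nonneg_channels <- function() {
  ch <- insole_channels()
  ch[grepl("^pressure_|^total_force_", ch)]
}

.activities <- c("sitting", "standing", "walking")
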