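#' Variance inflation of a window mean under AR(1) noise
#'
#' For a stationary AR(1) process with unit marginal variance and
#' coefficient `rho`, the variance of the mean of `n` consecutive samples
#' is `(1/n) * (1 + 2 * sum_{k=1}^{n-1} (1 - k/n) rho^k)`. With `rho = 0`
#' this reduces to the i.i.d. `1/n`.
#'
#' @param rho AR(1) coefficient in `[0, 1)`.
#' @param n Window length in samples.
#' @return Variance of the window mean (unit-marginal-variance scale).
#' @export
ar1_mean_var <- function(rho, n) {
  stopifnot(rho >= 0, rho < 1, n >= 1)
  if (n == 1L) return(1)
  k <- seq_len(n - 1L)
  (1 + 2 * sum((1 - k / n) * rho^k)) / n
}

#' Analytic MAE noise floor of the generation model
#'
#' Under the synthetic generation model, the window-aggregated combined
#' total force at carried weight `w` is `F(w) * (1 + eps)` with
#' `Var(eps) = (sd_tot^2 + sum(shares^2) * sd_sensor^2) * v(rho, len) +
#' sum(shares^2) * calib_sd^2`, where `v` is [ar1_mean_var()] and `len`
#' the window length; the calibration term does not shrink with the
#' window because iteration gains are constant within a recording.
#' Inverting the noise-free weight/force map, the error of an ideal
#' estimator that reads weight off the combined-force feature is
#' Gaussian with sd `(body_weight + w) * sd(eps)`, whose absolute mean
#' is `sqrt(2/pi)` times that. The floor reported is this MAE averaged
#' over the weight class — a lower bound for single-feature estimation
#' and a useful yard stick for the multi-feature model (trimming,
#' outliers, dropout and flicker are ignored; the first two are what the
#' trim removes, the last two are what the bias corrects).
#'
#' @param spec A [synthetic_participant_spec()].
#' @param l_samples,olap_init Windowing parameters used by the pipeline.
#' @return Expected MAE (lbs) of the ideal combined-force estimator.
#' @export
noise_floor_mae <- function(spec, l_samples = 100, olap_init = 0.2) {
  stopifnot(inherits(spec, "synthetic_participant_spec"))
  n <- as.integer(round(spec$duration * spec$sampling_rate))
  len <- plan_windows(n, l_samples, olap_init)$length
  v <- ar1_mean_var(spec$ar_coef, len)
  var_rel <- (spec$total_noise_sd^2 +
                sum(spec$load_shares^2) * spec$noise_sd^2) * v +
    sum(spec$load_shares^2) * spec$calib_sd^2
  w <- spec$weight_class$weights
  mean(sqrt(2 / pi) * (spec$body_weight + w) * sqrt(var_rel))
}
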