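LBS_TO_N <- 4.448                 # newtons per pound
SENSOR_AREA_CM2 <- 10             # nominal contact area per pressure cell

#' Specify one synthetic participant
#'
#' Describes the stated world the generator samples from: total
#' ground-reaction force proportional to body weight plus carried dumbbell
#' weight, split across 32 pressure cells by participant-specific load
#' shares (their "gait pattern"), perturbed by temporally correlated
#' multiplicative noise, transient outlier rows, and per-(recording,
#' channel) dropout in which a sensor reads exactly 0 for a whole
#' recording.
#'
#' Noise has two components: a common-mode total-load fluctuation
#' (`total_noise_sd`, postural sway / breathing, moving all sensors
#' together) and independent per-sensor redistribution noise (`noise_sd`,
#' load shifting between cells). Both are AR(1) with coefficient
#' `ar_coef`, because consecutive 50 Hz samples of a standing person are
#' strongly dependent.
#'
#' @param participant_id Identifier string.
#' @param body_weight Ground-truth body weight in lbs.
#' @param weight_class Strictly increasing carried weights (lbs), starting
#'   at 0. Default: the controlled-protocol dumbbell series
#'   0, 2, 3, 5, 7, 9, 11, 13 lbs.
#' @param n_iterations Experimental iterations (>= 2; default 3).
#' @param sampling_rate Hz, 25 or 50 (default 50).
#' @param duration Seconds recorded per weight (default 20).
#' @param load_shares 32 non-negative per-sensor load shares summing to 1
#'   (first 16 left foot, last 16 right); default near-uniform.
#' @param dropout_prob Per-(recording, pressure-channel) probability of an
#'   all-zero dropout; 0 defines a "balanced" participant.
#' @param noise_sd Relative per-sensor noise sd (default 0.05).
#' @param total_noise_sd Relative common-mode noise sd (default
#'   `noise_sd / 5`).
#' @param ar_coef AR(1) coefficient of both noise processes (default 0.9).
#' @param outlier_prob Probability a sample row is an outlier (default
#'   0.01).
#' @param outlier_scale Multiplier applied to outlier rows (default 3).
#' @param calib_sd Between-iteration calibration variability: every
#'   experimental iteration starts with a fresh sensor calibration, so
#'   each (iteration, sensor) pair draws a persistent gain
#'   `N(1, calib_sd)`. Default `0.6 * noise_sd` (0.03 at the default
#'   noise scale; 0 in the noise-free limit). This is what keeps
#'   held-out iterations from being trivially interpolable.
#' @param flicker_prob Per-(recording, channel) probability that a sensor
#'   is barely loaded and emits near-zero ("infinitesimal") readings
#'   instead of its nominal share; defaults to `dropout_prob`. Such
#'   readings are not exactly 0, which is precisely the case a
#'   zero-reading-only bias correction misses.
#' @param flicker_max Upper bound of the uniform share attenuation of a
#'   flickering channel (default 0.02, i.e. 0.1-2% of nominal).
#' @param episode_rate Rate (per second) of transient stance-adjustment
#'   episodes during which the participant partially unloads the insoles
#'   and load redistributes erratically (default 0.1, one per ~10 s).
#'   Episodes last 0.2-1 s, scale total load by a uniform 0.05-0.6 dip
#'   and add uncorrelated per-sensor scatter; they are what fills the
#'   low-range/near-zero part of each channel's sample distribution and
#'   what makes large aggregation windows include noisy, uncorrelated
#'   samples. Set 0 to disable.
#' @param activity Activity recorded (default `"standing"`).
#' @param seed Integer seed making the participant's files reproducible.
#' @return A `synthetic_participant_spec` list.
#' @export
synthetic_participant_spec <- function(participant_id, body_weight,
                                       weight_class = c(0, 2, 3, 5, 7, 9, 11, 13),
                                       n_iterations = 3L,
                                       sampling_rate = 50,
                                       duration = 20,
                                       load_shares = NULL,
                                       dropout_prob = 0,
                                       noise_sd = 0.05,
                                       total_noise_sd = noise_sd / 5,
                                       ar_coef = 0.9,
                                       outlier_prob = 0.01,
                                       outlier_scale = 3,
                                       calib_sd = 0.6 * noise_sd,
                                       flicker_prob = NULL,
                                       flicker_max = 0.02,
                                       episode_rate = 0.1,
                                       activity = "standing",
                                       seed = 1L) {
  if (is.null(load_shares)) {
    load_shares <- rep(1 / 32, 32)
  }
  if (is.null(flicker_prob)) flicker_prob <- dropout_prob
  stopifnot(body_weight > 0, n_iterations >= 2L,
    sampling_rate %in% c(25, 50), duration > 0,
    length(load_shares) == 32L, all(load_shares >= 0),
    abs(sum(load_shares) - 1) < 1e-9,
    dropout_prob >= 0, dropout_prob <= 1, noise_sd >= 0,
    total_noise_sd >= 0, ar_coef >= 0, ar_coef < 1,
    outlier_prob >= 0, outlier_prob <= 1, outlier_scale > 0,
    calib_sd >= 0, flicker_prob >= 0, flicker_prob <= 1,
    flicker_max > 0, flicker_max < 1, episode_rate >= 0)
  wc <- weight_class(weight_class)
  structure(list(participant_id = as.character(participant_id),
                 body_weight = body_weight, weight_class = wc,
                 n_iterations = as.integer(n_iterations),
                 sampling_rate = sampling_rate, duration = duration,
                 load_shares = load_shares, dropout_prob = dropout_prob,
                 noise_sd = noise_sd, total_noise_sd = total_noise_sd,
                 ar_coef = ar_coef, outlier_prob = outlier_prob,
                 outlier_scale = outlier_scale, calib_sd = calib_sd,
                 flicker_prob = flicker_prob, flicker_max = flicker_max,
                 episode_rate = episode_rate,
                 activity = match.arg(activity, .activities),
                 seed = as.integer(seed)),
            class = "synthetic_participant_spec")
}

#' Deterministic total ground-reaction force of the generation model
#'
#' @param spec A `synthetic_participant_spec`.
#' @param carried_weight Carried weight in lbs.
#' @return Expected two-foot total force in newtons,
#'   `4.448 * (body_weight + carried_weight)`.
#' @export
expected_total_force <- function(spec, carried_weight) {
  LBS_TO_N * (spec$body_weight + carried_weight)
}

# stationary AR(1) series with marginal sd `sd` (n x k matrix)
.ar1_noise <- function(n, k, sd, rho) {
  if (sd == 0 || n == 0L) return(matrix(0, n, k))
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- matrix(rnorm(n * k, 0, innov_sd), n, k)
  x <- matrix(0, n, k)
  x[1L, ] <- rnorm(k, 0, sd)
  if (n > 1L) {
    x <- apply(rbind(x[1L, , drop = FALSE], e[-1L, , drop = FALSE]), 2L,
               function(col) as.numeric(stats::filter(col, rho, method = "recursive")))
    if (is.null(dim(x))) x <- matrix(x, n, k)
  }
  x
}

# simulate one recording (data.frame in canonical schema); `gains` is the
# iteration's per-sensor calibration gain vector
.simulate_recording <- function(spec, carried_weight, posture, gains) {
  n <- as.integer(round(spec$duration * spec$sampling_rate))
  if (n < 1L) stop("duration x sampling_rate must yield at least 1 sample",
                   call. = FALSE)
  f_total <- expected_total_force(spec, carried_weight)
  # per-recording channel states: dropped (exact 0 throughout), flickering
  # (barely loaded: near-zero but non-zero readings), or nominal
  dropped <- runif(32) < spec$dropout_prob
  flicker <- !dropped & runif(32) < spec$flicker_prob
  share_mult <- ifelse(flicker, runif(32, 0.001, spec$flicker_max), 1)
  eps_tot <- .ar1_noise(n, 1L, spec$total_noise_sd, spec$ar_coef)[, 1L]
  eps_s <- .ar1_noise(n, 32L, spec$noise_sd, spec$ar_coef)
  row_mult <- ifelse(runif(n) < spec$outlier_prob, spec$outlier_scale, 1)
  # transient stance-adjustment episodes: partial unloading plus erratic
  # redistribution, giving every loaded channel a low-range tail
  ep_mult <- matrix(1, n, 32)
  n_ep <- stats::rpois(1L, spec$episode_rate * spec$duration)
  for (e in seq_len(n_ep)) {
    t0 <- runif(1, 0, spec$duration)
    idx <- which(abs((seq_len(n) - 1L) / spec$sampling_rate - t0) <
                   runif(1, 0.2, 1.0) / 2)
    if (!length(idx)) next
    dip <- runif(1, 0.05, 0.6)
    scatter <- exp(rnorm(32, 0, 0.3))
    ep_mult[idx, ] <- rep(dip * scatter, each = length(idx))
  }
  # per-cell force: share * gain * F * (1 + common)(1 + sensor) * transients
  f <- sweep((1 + eps_s) * (1 + eps_tot) * row_mult * ep_mult, 2L,
             spec$load_shares * share_mult * gains * f_total, `*`)
  f <- pmax(f, 0)
  f[, dropped] <- 0
  imu <- function(mu, sd) mu + rnorm(n, 0, sd)
  side <- function(idx, pos) {
    p <- f[, idx, drop = FALSE] / SENSOR_AREA_CM2
    colnames(p) <- NULL
    data.frame(p,
               total_force = rowSums(f[, idx, drop = FALSE]),
               acc_x = imu(pos["acc_x"], 0.02), acc_y = imu(pos["acc_y"], 0.02),
               acc_z = imu(1, 0.02),
               gyro_x = imu(0, 1), gyro_y = imu(0, 1), gyro_z = imu(0, 1),
               cop_x = pmin(pmax(imu(pos["cop_x"], 0.02), 0), 1),
               cop_y = pmin(pmax(imu(pos["cop_y"], 0.02), 0), 1))
  }
  df <- cbind(time = (seq_len(n) - 1L) / spec$sampling_rate,
              side(1:16, posture$l), side(17:32, posture$r))
  names(df) <- insole_channels()
  # 6-decimal export precision: realistic for vendor text dumps, and makes
  # the write->read round trip value-exact
  df[] <- lapply(df, round, digits = 6L)
  df
}

#' Generate one synthetic participant's dataset on disk
#'
#' Writes `n_iterations * length(weight_class)` recording files under
#' `out_dir/<participant_id>/<activity>/` using the study filename grammar,
#' and upserts the participant's row in `out_dir/ground_truth.csv`. Fully
#' reproducible from `spec$seed` (same seed, byte-identical files).
#'
#' @param spec A `synthetic_participant_spec`.
#' @param out_dir Dataset root directory (created if needed).
#' @return Invisibly, a data.frame manifest of the files written.
#' @export
generate_participant <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_participant_spec"))
  set.seed(spec$seed)
  # posture constants persist across the participant's recordings
  posture <- list(
    l = c(acc_x = rnorm(1, 0, 0.05), acc_y = rnorm(1, 0, 0.05),
          cop_x = runif(1, 0.4, 0.6), cop_y = runif(1, 0.4, 0.6)),
    r = c(acc_x = rnorm(1, 0, 0.05), acc_y = rnorm(1, 0, 0.05),
          cop_x = runif(1, 0.4, 0.6), cop_y = runif(1, 0.4, 0.6)))
  rows <- list()
  for (iter in seq_len(spec$n_iterations)) {
    # sensors are recalibrated at the start of every iteration
    gains <- pmax(rnorm(32, 1, spec$calib_sd), 0.2)
    for (w in spec$weight_class$weights) {
      key <- recording_key(w, spec$activity, iter)
      df <- .simulate_recording(spec, w, posture, gains)
      path <- file.path(out_dir, spec$participant_id, spec$activity,
                        format_filename(key))
      write_recording(df, path)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = spec$participant_id, activity = spec$activity,
        carried_weight = w, iteration = iter, path = path,
        stringsAsFactors = FALSE)
    }
  }
  .upsert_ground_truth(out_dir, spec$participant_id, spec$body_weight)
  invisible(do.call(rbind, rows))
}

.upsert_ground_truth <- function(out_dir, participant_id, body_weight) {
  gt_path <- file.path(out_dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) load_ground_truth(gt_path) else
    data.frame(participant_id = character(), body_weight_lbs = numeric())
  gt <- gt[gt$participant_id != participant_id, , drop = FALSE]
  gt <- rbind(gt, data.frame(participant_id = participant_id,
                             body_weight_lbs = body_weight))
  gt <- gt[order(gt$participant_id), ]
  data.table::fwrite(gt, gt_path)
  invisible(gt_path)
}

# Dirichlet(alpha) draw of length k
.rdirichlet <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Balanced participants get `dropout_prob = 0` and near-uniform load
#' shares (symmetric Dirichlet, concentration 5); unbalanced participants
#' get skewed shares (Dirichlet 0.5) and `dropout_prob = 0.25`, emulating
#' people who never load some sensors because of posture or shoe type.
#' Body weights are drawn uniformly on 120–220 lbs. Participant seeds are
#' derived from `seed`.
#'
#' @param n_balanced,n_unbalanced Number of participants of each kind
#'   (total >= 1).
#' @param out_dir Dataset root directory.
#' @param seed Master seed.
#' @param base_spec Named list of [synthetic_participant_spec()] arguments
#'   overriding the defaults for every participant (e.g.
#'   `list(noise_sd = 0, duration = 10)`).
#' @return Invisibly, the list of participant specs used.
#' @export
generate_cohort <- function(n_balanced, n_unbalanced, out_dir, seed = 1L,
                            base_spec = list()) {
  n <- n_balanced + n_unbalanced
  stopifnot(n >= 1L)
  set.seed(seed)
  kinds <- c(rep("balanced", n_balanced), rep("unbalanced", n_unbalanced))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    args <- list(
      participant_id = sprintf("P%02d", i),
      body_weight = round(runif(1, 120, 220), 1),
      load_shares = if (kinds[i] == "balanced") .rdirichlet(32, 5)
                    else .rdirichlet(32, 0.5),
      dropout_prob = if (kinds[i] == "balanced") 0 else 0.25,
      seed = as.integer(seed + 1000L * i))
    args <- utils::modifyList(args, base_spec, keep.null = TRUE)
    specs[[i]] <- do.call(synthetic_participant_spec, args)
  }
  for (sp in specs) generate_participant(sp, out_dir)
  invisible(specs)
}
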