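noise_free <- list(noise_sd = 0, outlier_prob = 0, dropout_prob = 0,
                   episode_rate = 0)

test_that("the same seed reproduces byte-identical files", {
  spec <- synthetic_participant_spec("T01", 163.4, weight_class = c(0, 3, 7),
                                     n_iterations = 2, duration = 0.5,
                                     seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_participant(spec, d1)
  m2 <- generate_participant(spec, d2)
  expect_equal(nrow(m1), 2 * 3)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$path[i]), readLines(m2$path[i]))
  }
})

test_that("the noise-free limit is exactly weight-proportional", {
  spec <- do.call(synthetic_participant_spec,
                  c(list(participant_id = "T01", body_weight = 150.3,
                         duration = 0.3, seed = 4), noise_free))
  d <- withr::local_tempdir()
  generate_participant(spec, d)
  for (w in c(0, 7, 13)) {
    key <- recording_key(w, "standing", 2L)
    rec <- load_recording(file.path(d, "T01", "standing",
                                    format_filename(key)))
    total <- rec$total_force_l + rec$total_force_r
    expect_equal(total, rep(expected_total_force(spec, w), nrow(rec)),
                 tolerance = 1e-7)
    # export precision is the only deviation
    expect_lt(max(abs(total - 4.448 * (150.3 + w))), 1e-5)
  }
})

test_that("mean total force matches the model within 3 standard errors", {
  # episodes off: this test checks the stationary AR(1) + calibration model
  spec <- synthetic_participant_spec("T01", 180, duration = 20, seed = 21,
                                     episode_rate = 0)
  d <- withr::local_tempdir()
  generate_participant(spec, d)
  rec <- load_recording(file.path(d, "T01", "standing", "0lbs_standing.txt"))
  total <- rec$total_force_l + rec$total_force_r
  f <- expected_total_force(spec, 0)
  # relative sd of the mean under the AR(1) + calibration noise model
  se_rel <- sqrt((spec$total_noise_sd^2 +
                    sum(spec$load_shares^2) * spec$noise_sd^2) *
                   ar1_mean_var(spec$ar_coef, length(total)) +
                   sum(spec$load_shares^2) * spec$calib_sd^2)
  # allow for the rare outlier rows on top of the Gaussian term
  expect_lt(abs(mean(total) - f),
            3 * f * se_rel + f * spec$outlier_prob * spec$outlier_scale)
})

test_that("expected total force strictly increases with carried weight", {
  # law-of-large-numbers property of the stationary noise core: episodes
  # and outlier rows (weight-independent transients handled downstream by
  # the trim stage) are scoped out, and recordings are long enough that
  # the sd of each pooled mean sits well below the smallest force gap
  spec <- synthetic_participant_spec("T01", 140, duration = 40, seed = 8,
                                     episode_rate = 0, outlier_prob = 0)
  d <- withr::local_tempdir()
  generate_participant(spec, d)
  # pool the iterations so each weight's mean is estimated from 3 x 40 s
  means <- vapply(spec$weight_class$weights, function(w) {
    mean(vapply(1:3, function(it) {
      rec <- load_recording(file.path(
        d, "T01", "standing",
        format_filename(recording_key(w, "standing", it))))
      mean(rec$total_force_l + rec$total_force_r)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("dropped-out channels read exactly zero for whole recordings", {
  spec <- synthetic_participant_spec("T01", 150, dropout_prob = 0.4,
                                     duration = 0.5, seed = 31,
                                     load_shares = insoleweight:::.rdirichlet(32, 0.5))
  d <- withr::local_tempdir()
  generate_participant(spec, d)
  pressure_cols <- grep("^pressure_", insole_channels(), value = TRUE)
  n_dropped <- 0L
  files <- list.files(file.path(d, "T01", "standing"), full.names = TRUE)
  for (f in files) {
    rec <- load_recording(f)
    for (ch in pressure_cols) {
      v <- rec[[ch]]
      if (all(v == 0)) {
        n_dropped <- n_dropped + 1L
      } else {
        # no partial dropouts within a recording (flickering channels stay
        # positive up to export rounding of near-zero episode samples)
        expect_gt(mean(v > 0), 0.9)
      }
    }
  }
  expect_gt(n_dropped, 0L)
})

test_that("cohorts split into balanced and unbalanced participants", {
  fx <- fixture_cohort("tiny", 1, 1,
                       base_spec = list(duration = 0.3, n_iterations = 2,
                                        weight_class = c(0, 5)))
  expect_equal(fx$specs[[1]]$dropout_prob, 0)
  expect_gte(fx$specs[[2]]$dropout_prob, 0.2)
  # skewed shares for the unbalanced participant
  expect_gt(max(fx$specs[[2]]$load_shares), max(fx$specs[[1]]$load_shares))
  gt <- load_ground_truth(file.path(fx$dir, "ground_truth.csv"))
  expect_setequal(gt$participant_id, c("P01", "P02"))
  expect_true(all(gt$body_weight_lbs >= 120 & gt$body_weight_lbs <= 220))
})

test_that("generation fails when duration yields no samples", {
  expect_error(synthetic_participant_spec("T01", 150, duration = 0),
               "duration")
  spec <- synthetic_participant_spec("T01", 150, duration = 0.005, seed = 1)
  expect_error(generate_participant(spec, withr::local_tempdir()),
               "at least 1 sample")
})
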