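# Shared fixtures: synthetic cohorts and pipeline runs are expensive, so
# they are generated once per session into tempdir() and memoized across
# test files. Seeds are fixed constants of the stated world.

.fx <- new.env(parent = emptyenv())

COHORT_SEED <- 20260901L

# build (or reuse) a cohort on disk; returns list(dir, specs)
fixture_cohort <- function(name, n_balanced, n_unbalanced, base_spec = list(),
                           seed = COHORT_SEED) {
  key <- paste0("cohort_", name)
  if (is.null(.fx[[key]])) {
    dir <- file.path(tempdir(), paste0("iw-fixture-", name))
    unlink(dir, recursive = TRUE)
    specs <- generate_cohort(n_balanced, n_unbalanced, out_dir = dir,
                             seed = seed, base_spec = base_spec)
    .fx[[key]] <- list(dir = dir, specs = specs)
  }
  .fx[[key]]
}

# phase-1-style cohort: 1 balanced + 6 unbalanced participants, defaults
phase1_cohort <- function() fixture_cohort("phase1", 1, 6)

# memoized pipeline run on a fixture cohort
fixture_run <- function(cohort, bias_mode = "fab", l_samples = 100,
                        alpha = 15) {
  key <- paste("run", basename(cohort$dir), bias_mode, l_samples, alpha,
               sep = "_")
  if (is.null(.fx[[key]])) {
    inv <- scan_dataset(cohort$dir)
    .fx[[key]] <- run_experiment(
      inv, bias_mode = bias_mode, l_samples = l_samples, alpha = alpha,
      config = model_config(cv_folds = 0L, seed = 1L))
  }
  .fx[[key]]
}

# a small in-memory recording in the canonical schema; per-sensor forces
# are given as an n x 32 matrix (newtons)
make_recording <- function(forces, carried_weight = 0, iteration = 1L,
                           participant_id = "T01", rate = 50) {
  n <- nrow(forces)
  blank <- function(k) matrix(0, n, k)
  side <- function(idx) {
    cbind(forces[, idx, drop = FALSE] / 10,
          rowSums(forces[, idx, drop = FALSE]),
          blank(3), blank(3), matrix(0.5, n, 2))
  }
  df <- data.frame(cbind((seq_len(n) - 1) / rate, side(1:16), side(17:32)))
  names(df) <- insole_channels()
  insoleweight:::new_recording(df, recording_key(carried_weight, "standing",
                                                 iteration),
                               participant_id = participant_id)
}

# brute-force oracle for the adaptive bias: exhaustive scan, scalar loops
oracle_bias <- function(samples_by_weight, weights) {
  L <- length(weights)
  ord <- order(as.numeric(names(samples_by_weight)))
  mats <- lapply(samples_by_weight[ord], as.matrix)
  nf <- ncol(mats[[1]])
  B <- matrix(NA_real_, nf, L)
  for (j in seq_len(nf)) {
    m_j <- NA_real_
    for (k in seq(L, 1)) {
      best <- Inf
      found <- FALSE
      for (v in mats[[k]][, j]) {
        if (v > 0 && v < best) {
          best <- v
          found <- TRUE
        }
      }
      if (found) {
        m_j <- best
        break
      }
    }
    for (i in seq_len(L)) B[j, i] <- m_j * i / L
  }
  B
}

# brute-force oracle for the alpha-trimmed mean
oracle_trimmed_mean <- function(x, alpha) {
  n <- length(x)
  k <- floor(alpha * n / 100)
  if (2 * k >= n) k <- floor((n - 1) / 2)
  s <- x[order(x)]
  kept <- s[seq(k + 1, n - k)]
  sum(kept) / length(kept)
}
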