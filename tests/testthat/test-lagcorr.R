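test_that("linear detrending is exact, idempotent and orthogonal to time", {
  t <- 1:50
  expect_equal(detrend_linear(3 + 0.5 * t), rep(0, 50), tolerance = 1e-10)
  set.seed(1)
  for (i in 1:100) {
    y <- rnorm(40)
    d <- detrend_linear(y)
    expect_lt(abs(sum(d * seq_along(d))), 1e-8)
    expect_lt(max(abs(detrend_linear(d) - d)), 1e-10)
  }
})

test_that("RT resampling matches the closed-form linear interpolant", {
  ev <- data.frame(onset = c(3, 6), duration = 0.5,
                   trial_type = "OG", response = "left",
                   rt_ms = c(800, 900), correct = TRUE)
  g <- rt_to_volume_grid(ev, times = 4)
  expect_equal(g$values, 800 + 100 / 3)
  # constant RT: every valid grid value equals it
  ev$rt_ms <- c(750, 750)
  gc <- rt_to_volume_grid(ev, times = c(3, 4, 5, 6))
  expect_true(all(gc$values[gc$valid] == 750))
  # outside the usable span: invalid
  expect_false(rt_to_volume_grid(ev, times = 10)$valid)
  expect_error(rt_to_volume_grid(ev[1, ], times = 4), "fewer than 2")
})

test_that("RT transforms and the nearest-volume option behave as stated", {
  ev <- data.frame(onset = c(3, 6, 9), duration = 0.5, trial_type = "OG",
                   response = "left", rt_ms = c(800, 900, 1000),
                   correct = TRUE)
  lg <- rt_to_volume_grid(ev, times = 6, transform = "log")
  expect_equal(lg$values, log(900))
  ad <- rt_to_volume_grid(ev, times = 6, transform = "abs_dev")
  expect_equal(ad$values, abs(900 - 900))
  nv <- rt_to_volume_grid(ev, times = c(2, 4, 6, 8, 10),
                          nearest_volume = TRUE)
  expect_equal(nv$values[nv$valid], c(800, 900, 1000))
  expect_equal(nv$times[nv$valid], c(4, 6, 10))
})

test_that("long gaps between usable trials are not bridged", {
  ev <- data.frame(onset = c(3, 6, 30, 33), duration = 0.5,
                   trial_type = "OG", response = "left",
                   rt_ms = c(800, 820, 840, 860), correct = TRUE)
  g <- rt_to_volume_grid(ev, times = c(5, 18, 31), max_gap_s = 15)
  expect_true(g$valid[1]); expect_false(g$valid[2]); expect_true(g$valid[3])
})

test_that("self-correlation is clamped at the Fisher-Z ceiling", {
  # build a voxel whose detrended BOLD equals the behavioral series at
  # every volume: trials at 1-s spacing make volume times interpolation
  # nodes, and a pre-detrended target survives detrending unchanged
  set.seed(2)
  yd <- detrend_linear(rnorm(90))
  rt <- 800 + 100 * approx(2 * (1:90), yd, xout = 1:200, rule = 2)$y
  ev <- data.frame(onset = 1:200, duration = 0.5, trial_type = "OG",
                   response = "left", rt_ms = rt, correct = TRUE)
  Z <- crosscorr_profile(matrix(yd, ncol = 1), ev, lags = 0, tr_s = 2)
  expect_equal(unname(Z[1, "0"]), atanh(1 - 1e-6), tolerance = 1e-9)
})

test_that("a pure delay moves the correlation peak to the matching lag", {
  # BOLD = behavioral series delayed by 10 s, no noise
  run <- tiny_run(seed = 22, n_trials = 204L, n_pm = 0L, n_volumes = 306L)
  grid <- rt_to_volume_grid(run$events, seq(1, 612))
  vol_times <- 2 * (1:306)
  y <- vapply(vol_times, function(t) {
    k <- t - 10
    if (k >= 1 && k <= 612 && grid$valid[k]) grid$values[k] else 0
  }, 0)
  Z <- crosscorr_profile(matrix(y, ncol = 1), run$events, tr_s = 2)
  expect_identical(ncol(Z), 101L)
  expect_equal(as.numeric(colnames(Z))[which.max(abs(Z[1, ]))], 10)
})

test_that("lagged profiles equal a brute-force shift-and-correlate oracle", {
  set.seed(33)
  for (i in 1:10) {
    nt <- 45L; nv <- 3L
    sq <- generate_trial_sequence(n_trials = 30L, n_pm = 3L, seed = i)
    trace <- simulate_vigilance_trace(30L, seed = 100 + i)
    rts <- simulate_rt_series(sq, trace, seed = 200 + i)
    ev <- make_events(sq, rts)
    Y <- matrix(rnorm(nt * nv), nt)
    lags <- -12:12
    got <- crosscorr_profile(Y, ev, lags = lags, tr_s = 2)
    ref <- oracle_lag_profile(Y, ev, lags = lags, tr_s = 2)
    expect_lt(max(abs(got - ref), na.rm = TRUE), 1e-10)
    expect_identical(unname(is.na(got)), is.na(ref))
  }
})

test_that("negating the behavioral series negates every Fisher-Z exactly", {
  run <- tiny_run(seed = 24)
  set.seed(4)
  Y <- matrix(rnorm(90 * 2), 90)
  ev_neg <- run$events
  ev_neg$rt_ms <- 4000 - ev_neg$rt_ms   # reflect: interpolant negates + const
  z1 <- crosscorr_profile(Y, run$events, lags = -10:10, tr_s = 2)
  z2 <- crosscorr_profile(Y, ev_neg, lags = -10:10, tr_s = 2)
  expect_equal(z1, -z2, tolerance = 1e-10)
})

test_that("lag antisymmetry: corr(A, B at +tau) = corr(B, A at -tau)", {
  # on fully valid, equally sampled series the pairing is symmetric
  set.seed(5)
  a <- rnorm(80); b <- rnorm(80)
  for (tau in c(-7, -3, 0, 3, 7)) {
    ia <- seq_along(a); ib <- ia - tau
    ok <- ib >= 1 & ib <= length(b)
    r1 <- cor(a[ok], b[ib[ok]])
    ia2 <- seq_along(b); ib2 <- ia2 + tau
    ok2 <- ib2 >= 1 & ib2 <= length(a)
    r2 <- cor(b[ok2], a[ib2[ok2]])
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("common-timepoint control: 102 coincident samples, controls", {
  run <- tiny_run(seed = 25, n_trials = 204L, n_pm = 0L, n_volumes = 306L,
                  accuracy_og = 1, accuracy_pm = 1)
  # all trials correct OG: every 6 s a trial onset coincides with a volume
  set.seed(6)
  Y <- matrix(rnorm(306), 306)
  Zc <- common_sample_crosscorr(Y, run$events, lags = 0, tr_s = 2)
  n_coincident <- sum((2 * (1:306)) %in% run$events$onset)
  expect_identical(n_coincident, 102L)
  # constant behavioral series: zero variance, lag marked missing
  ev_const <- run$events; ev_const$rt_ms <- 800
  Zna <- common_sample_crosscorr(Y, ev_const, lags = 0, tr_s = 2)
  expect_true(all(is.na(Zna)))
})

test_that("interpolated and common-timepoint profiles are highly similar", {
  sp <- tiny_specs()
  coh <- simulate_cohort(n_subjects = 1L, runs_per_subject = 6L,
                         voxel_specs = sp, n_volumes = 306L, seed = 26)
  runs <- coh$subjects[[1]]
  zi <- average_runs(lapply(runs, function(r)
    crosscorr_profile(r$bold, r$events)))
  zc <- average_runs(lapply(runs, function(r)
    common_sample_crosscorr(r$bold, r$events)))
  for (v in which(sp$modulation != "none"))
    expect_gt(cor(zi[v, ], zc[v, ], use = "complete.obs"), 0.9)
})

test_that("run averaging is the arithmetic mean over available runs", {
  z1 <- matrix(1, 2, 3); z2 <- matrix(3, 2, 3)
  z2[1, 1] <- NA
  avg <- average_runs(list(z1, z2))
  expect_equal(avg[1, 1], 1)       # run with NA ignored at that lag
  expect_equal(avg[2, 2], 2)
  expect_identical(attr(avg, "n_runs"), 2L)
})

test_that("window contrasts: labels, alpha arithmetic, null behavior", {
  # lags 1..5 labeled 3
  set.seed(7)
  profs <- lapply(1:6, function(s) {
    z <- matrix(rnorm(4 * 101, sd = 0.01), 4, 101)
    colnames(z) <- as.character(-50:50)
    z
  })
  z <- stack_profiles(profs)
  gm <- group_window_contrast(z, 1:5, alpha = 0.05, n_pretests = 5L)
  expect_equal(gm$window_label, 3)
  # Bonferroni for 5 pre-stimulus windows at family level 0.05 -> 0.01
  expect_equal(0.05 / 5, 0.01)
  expect_equal(gm$p_corrected, pmin(gm$p * 4 * 5, 1))
  # all-zero profiles: nothing significant
  z0 <- z; z0[] <- 0
  gm0 <- group_window_contrast(z0, 1:5)
  expect_false(any(gm0$pos_mask) || any(gm0$neg_mask))
  expect_error(group_window_contrast(z, 60:64), "outside")
})

test_that("GLM-similarity curve: construction, antisymmetry, argmax", {
  set.seed(8)
  beta <- rnorm(200)
  z <- matrix(rnorm(200 * 101, sd = 1), 200, 101)
  colnames(z) <- as.character(-50:50)
  z[, "5"] <- beta
  sim <- glm_similarity_by_lag(beta, z)
  expect_identical(sim$best_lag, 5)
  expect_equal(max(sim$similarity$r), 1, tolerance = 1e-12)
  flipped <- glm_similarity_by_lag(-beta, z)
  expect_equal(flipped$similarity$r, -sim$similarity$r, tolerance = 1e-12)
})

test_that("ROI threshold arithmetic and onset definition", {
  expect_equal(roi_alpha(0.05, 2, 50), 0.0005)
  # constructed profiles: significant from -8 s through 0
  lags <- -10:10
  z <- array(0, c(12, 3, length(lags)),
             dimnames = list(NULL, NULL, as.character(lags)))
  set.seed(9)
  sig_lags <- lags >= -8 & lags <= 2
  for (s in 1:12)
    z[s, , ] <- rep(ifelse(sig_lags, 0.5, 0), each = 3) +
      rnorm(3 * length(lags), sd = 0.05)
  prof <- roi_profile(z, c(TRUE, TRUE, FALSE), threshold = 0.001)
  expect_equal(attr(prof, "onset_of_significance"), -8)
  # all-noise cohort: onset undefined
  zn <- array(rnorm(12 * 3 * 21, sd = 1), c(12, 3, 21),
              dimnames = list(NULL, NULL, as.character(-10:10)))
  pn <- roi_profile(zn, c(TRUE, TRUE, TRUE), threshold = 1e-6)
  expect_true(is.na(attr(pn, "onset_of_significance")))
  expect_identical(compare_onsets(pn, prof), "undefined")
  expect_error(roi_profile(z, c(FALSE, FALSE, FALSE)), "empty")
})

test_that("window statistics agree in sign with the parametric GLM", {
  # noise-free, lead-0 modulated voxels: lag window [3..7] vs pmod beta
  sp <- tiny_specs(noise_sd = 0, drift_slope = 0)
  coh <- simulate_cohort(n_subjects = 3L, runs_per_subject = 1L,
                         voxel_specs = sp, n_volumes = 306L, seed = 27)
  fits <- lapply(coh$subjects, function(runs)
    lapply(runs, function(r)
      fit_run_glm(r$bold, build_design_matrix(r$events, r$motion))))
  pmod <- t(vapply(fits, subject_contrast, column = "pmod_RT_OG_correct",
                   numeric(nrow(sp))))
  z <- stack_profiles(lapply(coh$subjects, subject_profile))
  gm <- group_window_contrast(z, 3:7, correction = "none")
  expect_identical(sign(gm$t), sign(colMeans(pmod)))
})
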