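test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(dt = 0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)                       # gamma density at the origin
  peak <- t[which.max(h)]
  expect_gte(peak, 4.5); expect_lte(peak, 5.5)
  expect_lt(abs(h[length(h)]), 0.01)          # ~0 at 32 s
  expect_equal(max(h), 1)                     # peak-normalized
  expect_gt(sum(h) * 0.1, 0)                  # integrates to a positive value
})

test_that("high-pass basis has the prescribed size and is orthonormal", {
  hp <- highpass_basis(306L, 2, 128)
  expect_identical(ncol(hp), 10L)   # constant + floor(2*612/128) = 9 cosines
  expect_identical(colnames(hp)[1], "constant")
  g <- crossprod(hp)
  expect_lt(max(abs(g - diag(ncol(hp)))), 1e-10)
  expect_identical(ncol(highpass_basis(306L, 2, Inf)), 1L)
  expect_error(highpass_basis(306L, 2, 3), "exceed")
})

test_that("full design matrix carries 14 task+motion regressors", {
  run <- tiny_run(seed = 2, n_trials = 204L, n_pm = 20L, n_volumes = 306L)
  motion <- simulate_motion(306L, seed = 4)
  dm <- build_design_matrix(run$events, motion)
  expect_identical(length(c(dm$task_cols, dm$pmod_cols, dm$motion_cols)),
                   14L)
  expect_identical(length(dm$task_cols), 4L)
  expect_identical(length(dm$pmod_cols), 4L)
  expect_identical(nrow(dm$X), 306L)
  expect_identical(length(dm$nuisance_cols), 10L)
})

test_that("empty conditions are dropped and recorded", {
  run <- tiny_run(seed = 3, n_trials = 204L, n_pm = 20L, n_volumes = 306L,
                  accuracy_og = 1, accuracy_pm = 1)
  dm <- build_design_matrix(run$events, simulate_motion(306L, seed = 1))
  expect_identical(length(c(dm$task_cols, dm$pmod_cols, dm$motion_cols)),
                   10L)
  expect_setequal(dm$dropped,
                  c("onset_OG_incorrect", "pmod_RT_OG_incorrect",
                    "onset_PM_incorrect", "pmod_RT_PM_incorrect"))
})

test_that("constant-RT conditions lose their degenerate parametric column", {
  run <- tiny_run(seed = 4, n_trials = 60L, n_pm = 6L,
                  rt_scale_ms = 0, noise_sd_ms = 0)
  dm <- build_design_matrix(run$events, motion = NULL, n_volumes = 90L)
  expect_false(any(grepl("^pmod_", colnames(dm$X))))
  expect_true(all(grepl("pmod_", dm$dropped[grepl("pmod", dm$dropped)])))
})

test_that("parametric columns are invariant to a constant RT shift", {
  run <- tiny_run(seed = 5)
  dm1 <- build_design_matrix(run$events, motion = NULL, n_volumes = 90L)
  ev2 <- run$events
  ev2$rt_ms <- ev2$rt_ms + 250   # mean-centering removes any constant
  dm2 <- build_design_matrix(ev2, motion = NULL, n_volumes = 90L)
  for (cn in dm1$pmod_cols)
    expect_equal(dm1$X[, cn], dm2$X[, cn], tolerance = 1e-10)
})

test_that("OLS betas equal an explicit normal-equations solve", {
  set.seed(10)
  for (i in 1:5) {
    n <- 40L; p <- 5L; v <- 3L
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", seq_len(p))
    Y <- matrix(rnorm(n * v), n)
    dm <- structure(list(X = X, task_cols = "c2", pmod_cols = "c3",
                         motion_cols = character(0),
                         nuisance_cols = "c1", dropped = character(0)),
                    class = "design_matrix")
    fit <- fit_run_glm(Y, dm)
    ref <- solve(t(X) %*% X) %*% t(X) %*% Y
    expect_lt(max(abs(fit$betas - ref)), 1e-8)
  }
})

test_that("noise-free simulated voxels are recovered exactly", {
  run <- tiny_run(seed = 6)
  clean <- tiny_specs(noise_sd = 0, drift_slope = 0)
  b <- simulate_bold_run(run$sequence, run$rts, clean, n_volumes = 90L,
                         seed = 1)
  dm <- build_design_matrix(run$events, motion = NULL, n_volumes = 90L)
  fit <- fit_run_glm(b, dm)
  # residual variance ~ 0: the design nests the generative model up to
  # the pmod scaling (generative weights are standardized RTs)
  expect_lt(max(fit$sigma2) / stats::var(as.numeric(b$data)), 1e-10)
})

test_that("rank-deficient designs fail loudly, naming the columns", {
  X <- cbind(1, 1:20, 2 * (1:20))
  colnames(X) <- c("constant", "a", "a_copy")
  dm <- structure(list(X = X, task_cols = "a", pmod_cols = character(0),
                       motion_cols = character(0),
                       nuisance_cols = "constant", dropped = character(0)),
                  class = "design_matrix")
  expect_error(fit_run_glm(matrix(rnorm(20), 20), dm), "a_copy")
})

test_that("pure-noise voxels show the nominal parametric type-I error", {
  run <- tiny_run(seed = 8, n_trials = 204L, n_pm = 20L, n_volumes = 306L)
  dm <- build_design_matrix(run$events, simulate_motion(306L, seed = 2))
  set.seed(12)
  Y <- matrix(rnorm(306 * 1000), 306)
  fit <- fit_run_glm(Y, dm)
  t <- column_tstat(fit, "pmod_RT_OG_correct")
  crit <- qt(0.975, fit$df_resid)
  rate <- mean(abs(t) > crit)
  expect_gte(rate, 0.035); expect_lte(rate, 0.065)
})

test_that("group maps: t distribution properties and masks", {
  # all-zero contrasts: no significant voxels, no NaN leakage into masks
  gm0 <- group_ttest_map(matrix(0, 5, 10))
  expect_false(any(gm0$pos_mask) || any(gm0$neg_mask))
  # df = n - 1
  set.seed(20)
  gm <- group_ttest_map(matrix(rnorm(21 * 50), 21))
  expect_identical(gm$df, 20L)
  # Bonferroni: corrected p = min(1, p * voxels)
  expect_equal(gm$p_corrected, pmin(gm$p * 50, 1))
})

test_that("permuted-sign group t-maps are symmetric about zero", {
  set.seed(30)
  con <- matrix(rnorm(12 * 500), 12)
  skews <- vapply(1:100, function(i) {
    flip <- sample(c(-1, 1), 12, replace = TRUE)
    t <- group_ttest_map(flip * con, correction = "none")$t
    mean(((t - mean(t)) / sd(t))^3)
  }, 0)
  expect_lt(abs(mean(skews)), 0.1)
})

test_that("deactivation/positive-modulation overlap is recovered at high SNR", {
  sp <- tiny_specs(noise_sd = 0.2)
  truth <- sp$modulation == "positive" & sp$task_amplitude < 0
  coh <- simulate_cohort(n_subjects = 6L, runs_per_subject = 1L,
                         voxel_specs = sp, n_volumes = 306L, seed = 31)
  fits <- lapply(coh$subjects, function(runs)
    lapply(runs, function(r)
      fit_run_glm(r$bold, build_design_matrix(r$events, r$motion))))
  pmod <- t(vapply(fits, subject_contrast, column = "pmod_RT_OG_correct",
                   numeric(nrow(sp))))
  task <- t(vapply(fits, subject_contrast, column = "onset_OG_correct",
                   numeric(nrow(sp))))
  mod_map <- group_ttest_map(pmod)
  task_map <- group_ttest_map(task)
  got <- overlap_map(task_map$neg_mask, mod_map$pos_mask)
  expect_identical(got, truth)
})
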