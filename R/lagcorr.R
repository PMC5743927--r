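#' Lagged cross-correlation between reaction times and BOLD
#'
#' The core analysis: for each voxel, the linearly detrended BOLD time series
#' is correlated with the (interpolated) reaction-time series of the correct
#' ongoing trials, with the behavioral series shifted in 1-s steps over lags
#' of -50 to +50 s. A negative lag means the BOLD signal precedes the
#' behavior. Correlations are Fisher-Z transformed and averaged across runs;
#' group inference uses one-sample t-tests on windows of 5 consecutive lags
#' with Bonferroni family-wise correction.
#'
#' @name lagcorr
NULL

#' Default lag grid: -50 to +50 s in 1-s steps (101 lags)
#' @return integer vector of lags in seconds.
#' @export
lag_grid <- function() -50:50

#' Remove a linear trend from each voxel time series
#'
#' Residuals of an OLS fit on (intercept, time index); output has zero mean
#' and is orthogonal to the time index. Idempotent.
#'
#' @param x numeric vector or time-by-voxel matrix.
#' @return detrended object of the same shape.
#' @export
detrend_linear <- function(x) {
  v <- is.null(dim(x))
  Y <- if (v) matrix(x, ncol = 1L) else x
  if (nrow(Y) < 3L) stop("series too short to detrend", call. = FALSE)
  X <- cbind(1, seq_len(nrow(Y)))
  r <- stats::lm.fit(X, Y)$residuals
  if (v) drop(r) else matrix(r, nrow = nrow(Y), ncol = ncol(Y))
}

#' Resample the reaction-time series onto a regular time grid
#'
#' Only correct OG trials with a response are sample points. The chosen
#' transform is applied to their RTs, then the piecewise-linear interpolant
#' through (onset, value) is evaluated at the requested times. Times outside
#' the span of usable trials are invalid, as are times inside a gap between
#' usable trials longer than `max_gap_s`. PM and incorrect trials are never
#' sample points but are interpolated across.
#'
#' @param events events table for one run.
#' @param times evaluation times in seconds (e.g. volume times `2 * 1:306`,
#'   or a 1-s grid for lagging).
#' @param transform "identity" (RT in ms), "log" (log RT), or
#'   "abs_dev" (|RT - run mean RT|, the RT-variability control).
#' @param max_gap_s gaps between consecutive usable trials longer than this
#'   are not bridged (default 15 s).
#' @param nearest_volume if TRUE, each usable RT is assigned to the next
#'   volume time instead of evaluating the interpolant (documented
#'   alternative reading; default FALSE).
#' @return list with `times`, `values`, `valid` (logical), `transform`,
#'   `n_usable`.
#' @export
rt_to_volume_grid <- function(events, times,
                              transform = c("identity", "log", "abs_dev"),
                              max_gap_s = 15, nearest_volume = FALSE) {
  transform <- match.arg(transform)
  use <- events$trial_type == "OG" & events$correct & !is.na(events$rt_ms)
  if (sum(use) < 2L)
    stop("fewer than 2 usable (correct OG) trials", call. = FALSE)
  ons <- events$onset[use]
  rt <- events$rt_ms[use]
  val <- switch(transform,
    identity = rt,
    log = log(rt),
    abs_dev = abs(rt - mean(rt)))
  if (nearest_volume) {
    # assign each RT to the next grid time at or after its onset
    values <- rep(NA_real_, length(times))
    for (i in seq_along(ons)) {
      k <- which(times >= ons[i])[1]
      if (!is.na(k)) values[k] <- val[i]
    }
    valid <- !is.na(values)
    return(list(times = times, values = values, valid = valid,
                transform = transform, n_usable = sum(use)))
  }
  values <- stats::approx(ons, val, xout = times, rule = 1)$y
  valid <- !is.na(values)
  # invalidate points bridging a gap longer than max_gap_s
  iv <- findInterval(times, ons)
  inside <- iv >= 1L & iv < length(ons)
  gap <- rep(0, length(times))
  gap[inside] <- ons[iv[inside] + 1L] - ons[iv[inside]]
  valid <- valid & !(inside & gap > max_gap_s)
  values[!valid] <- NA_real_
  list(times = times, values = values, valid = valid,
       transform = transform, n_usable = sum(use))
}

# Pair volumes (times tr*1:T) with a behavioral series sampled on a 1-s
# integer grid, at each lag; returns Fisher-Z matrix voxels x lags.
lagged_fisher_z <- function(Y, vol_times, beh, lags, min_overlap) {
  stopifnot(all(abs(diff(beh$times) - 1) < 1e-9))
  t0 <- beh$times[1]
  nb <- length(beh$times)
  Z <- matrix(NA_real_, ncol(Y), length(lags))
  for (j in seq_along(lags)) {
    bt <- vol_times - lags[j]               # behavior sampled at t - lag
    k <- round(bt - t0) + 1L
    ok <- k >= 1L & k <= nb
    ok[ok] <- beh$valid[k[ok]]
    if (sum(ok) < min_overlap) next
    x <- beh$values[k[ok]]
    if (stats::sd(x) == 0) next
    Z[, j] <- fisher_z(cor_vec_mat(x, Y[ok, , drop = FALSE]))
  }
  dimnames(Z) <- list(NULL, as.character(lags))
  Z
}

#' Voxelwise lagged cross-correlation profile for one run
#'
#' Detrends every voxel, resamples the behavioral series on a 1-s grid, and
#' for each lag correlates BOLD at volume times t with behavior at t - lag
#' over the overlap of valid samples. Correlations are Fisher-Z transformed
#' (clamped at |r| = 1 - 1e-6). Lags with fewer than `min_overlap` valid
#' pairs are NA for this run.
#'
#' @param bold a `bold_run` or time-by-voxel matrix.
#' @param events events table for the run.
#' @param lags lag grid in seconds (default [lag_grid()]).
#' @param transform behavioral transform (see [rt_to_volume_grid()]).
#' @param tr_s repetition time, taken from `bold` when it is a `bold_run`.
#' @param min_overlap minimum valid pairs per lag (default 10).
#' @param max_gap_s see [rt_to_volume_grid()].
#' @return matrix voxels x lags of Fisher-Z values (lag names as columns).
#' @export
crosscorr_profile <- function(bold, events, lags = lag_grid(),
                              transform = "identity", tr_s = NULL,
                              min_overlap = 10L, max_gap_s = 15) {
  if (inherits(bold, "bold_run")) tr_s <- bold$tr_s
  if (is.null(tr_s)) stop("`tr_s` required for matrix input", call. = FALSE)
  Y <- detrend_linear(bold_matrix(bold))
  vol_times <- tr_s * seq_len(nrow(Y))
  grid_times <- seq(1, max(vol_times))
  beh <- rt_to_volume_grid(events, grid_times, transform = transform,
                           max_gap_s = max_gap_s)
  lagged_fisher_z(Y, vol_times, beh, lags, min_overlap)
}

#' Common-timepoint control profile (no interpolation)
#'
#' Uses only samples recorded at coincident times: volumes at t are paired,
#' at lag tau, with trials whose onset is exactly t - tau and which are
#' usable (correct OG with a response). At lag 0 in a full run every second
#' trial coincides with a volume, giving at most 102 values.
#'
#' @inheritParams crosscorr_profile
#' @return matrix voxels x lags of Fisher-Z values.
#' @export
common_sample_crosscorr <- function(bold, events, lags = lag_grid(),
                                    transform = "identity", tr_s = NULL,
                                    min_overlap = 10L) {
  if (inherits(bold, "bold_run")) tr_s <- bold$tr_s
  if (is.null(tr_s)) stop("`tr_s` required for matrix input", call. = FALSE)
  Y <- detrend_linear(bold_matrix(bold))
  vol_times <- tr_s * seq_len(nrow(Y))
  use <- events$trial_type == "OG" & events$correct & !is.na(events$rt_ms)
  if (sum(use) < 2L)
    stop("fewer than 2 usable (correct OG) trials", call. = FALSE)
  ons <- events$onset[use]
  rt <- events$rt_ms[use]
  val <- switch(match.arg(transform, c("identity", "log", "abs_dev")),
    identity = rt, log = log(rt), abs_dev = abs(rt - mean(rt)))
  Z <- matrix(NA_real_, ncol(Y), length(lags))
  for (j in seq_along(lags)) {
    m <- match(round(vol_times - lags[j], 9), round(ons, 9))
    ok <- !is.na(m)
    if (sum(ok) < min_overlap) next
    x <- val[m[ok]]
    if (stats::sd(x) == 0) next
    Z[, j] <- fisher_z(cor_vec_mat(x, Y[ok, , drop = FALSE]))
  }
  dimnames(Z) <- list(NULL, as.character(lags))
  Z
}

#' Average Fisher-Z profiles across runs
#'
#' Arithmetic mean of Z over runs; lags missing in a run are averaged over
#' the available runs.
#'
#' @param profiles list of voxels-by-lags Z matrices (one per run).
#' @return voxels-by-lags matrix, with attribute `n_runs`.
#' @export
average_runs <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  a <- array(unlist(profiles),
             dim = c(dim(profiles[[1]]), length(profiles)))
  out <- apply(a, c(1, 2), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- dimnames(profiles[[1]])
  attr(out, "n_runs") <- length(profiles)
  out
}

#' Per-subject lag profile for one subject's runs
#'
#' Convenience wrapper: [crosscorr_profile()] per run, then [average_runs()].
#'
#' @param runs list of runs, each a list with `bold` and `events`.
#' @param ... passed to [crosscorr_profile()].
#' @return voxels-by-lags Fisher-Z matrix.
#' @export
subject_profile <- function(runs, ...) {
  average_runs(lapply(runs, function(r)
    crosscorr_profile(r$bold, r$events, ...)))
}

#' Stack per-subject profiles into a subjects x voxels x lags array
#' @param profiles list of voxels-by-lags matrices.
#' @return 3D array (subject, voxel, lag).
#' @export
stack_profiles <- function(profiles) {
  d <- dim(profiles[[1]])
  arr <- array(NA_real_, c(length(profiles), d[1], d[2]),
               dimnames = list(NULL, NULL, colnames(profiles[[1]])))
  for (s in seq_along(profiles)) arr[s, , ] <- profiles[[s]]
  arr
}

#' Group contrast on a window of consecutive lags
#'
#' Averages each subject's Fisher-Z over the lags of the window (labeled by
#' the mean lag, e.g. lags 1..5 s -> label 3 s) and runs a voxelwise
#' one-sample t-test with Bonferroni correction over voxels times the
#' number of pre-stimulus windows tested (`n_pretests`): with 5 pre-stimulus
#' windows at family level 0.05, the per-window corrected level is 0.01.
#'
#' @param z subjects x voxels x lags array (see [stack_profiles()]).
#' @param window_lags lags (s) forming the window, e.g. `1:5`.
#' @param alpha family-wise level.
#' @param n_pretests number of pre-stimulus windows in the family.
#' @param correction "bonferroni" or "none".
#' @return a `group_map` (see [group_ttest_map()]) with `window_label`
#'   and `window_lags` fields added.
#' @export
group_window_contrast <- function(z, window_lags, alpha = 0.05,
                                  n_pretests = 1L,
                                  correction = "bonferroni") {
  lag_names <- dimnames(z)[[3]]
  idx <- match(as.character(window_lags), lag_names)
  if (anyNA(idx)) stop("window outside the lag grid", call. = FALSE)
  con <- apply(z[, , idx, drop = FALSE], c(1, 2), mean)
  gm <- group_ttest_map(con, alpha = alpha, correction = correction,
                        extra_bonferroni = n_pretests)
  gm$window_label <- mean(window_lags)
  gm$window_lags <- window_lags
  gm
}

#' Spatial similarity between the parametric GLM map and each lag map
#'
#' Pearson correlation, over in-mask voxels, of the subject-averaged
#' parametric beta map with the subject-averaged Fisher-Z map at each lag.
#' On cohorts with no generative lead, the most similar lag sits at the
#' hemodynamic peak (about +5 s).
#'
#' @param beta_map numeric vector (voxels) of group-mean parametric betas.
#' @param z_mean voxels x lags matrix of group-mean Fisher-Z.
#' @param mask optional logical voxel mask.
#' @return list with `similarity` (data.frame lag, r) and `best_lag`
#'   (argmax of r).
#' @export
glm_similarity_by_lag <- function(beta_map, z_mean, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(beta_map))
  stopifnot(length(beta_map) == nrow(z_mean), length(mask) == nrow(z_mean))
  lags <- as.numeric(colnames(z_mean))
  r <- cor_vec_mat(beta_map[mask], z_mean[mask, , drop = FALSE])
  sim <- data.frame(lag = lags, r = r)
  list(similarity = sim, best_lag = lags[which.max(r)])
}

#' Significance threshold for the ROI lag analysis
#'
#' Bonferroni over `n_masks` ROIs and `n_lags` pre-stimulus time points:
#' 0.05 / (2 * 50) = 0.0005 for the default two-network, 50-lag family.
#'
#' @param family_alpha family-wise level.
#' @param n_masks number of ROI masks tested.
#' @param n_lags number of pre-stimulus lags tested.
#' @return numeric threshold.
#' @export
roi_alpha <- function(family_alpha = 0.05, n_masks = 2L, n_lags = 50L) {
  family_alpha / (n_masks * n_lags)
}

#' ROI lag profile and onset of significance
#'
#' Averages Fisher-Z over the mask voxels per subject and lag, then runs a
#' one-sample t-test per lag. The onset of significance is the most negative
#' lag from which p stays below the threshold at every lag through 0
#' (stimulus onset); it is NA when no such run-up exists. Note that when the
#' mask is derived from the parametric GLM the profile is biased toward a
#' peak near +5 s.
#'
#' @param z subjects x voxels x lags array.
#' @param mask logical voxel mask (must select at least one voxel).
#' @param threshold per-lag significance threshold (see [roi_alpha()]).
#' @return a `roi_profile`: data.frame with `lag`, `mean_z`, `sem`, `t`,
#'   `p`, plus attributes `onset_of_significance` and `threshold`.
#' @export
roi_profile <- function(z, mask, threshold = roi_alpha()) {
  stopifnot(length(mask) == dim(z)[2])
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  lags <- as.numeric(dimnames(z)[[3]])
  roi <- apply(z[, mask, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
  n <- nrow(roi)
  m <- colMeans(roi)
  sem <- apply(roi, 2L, stats::sd) / sqrt(n)
  t <- m / sem
  p <- 2 * stats::pt(abs(t), n - 1L, lower.tail = FALSE)
  out <- data.frame(lag = lags, mean_z = m, sem = sem, t = t, p = p)
  sig <- !is.na(p) & p < threshold
  pre <- which(lags <= 0)
  onset <- NA_real_
  if (length(pre) > 0 && sig[max(pre)]) {
    run <- rev(pre)                      # from lag 0 backwards
    stopv <- which(!sig[run])
    last <- if (length(stopv) == 0) run[length(run)] else run[stopv[1] - 1L]
    onset <- lags[last]
  }
  attr(out, "onset_of_significance") <- onset
  attr(out, "threshold") <- threshold
  class(out) <- c("roi_profile", "data.frame")
  out
}

#' Compare the onsets of significance of two ROI profiles
#'
#' @param neg,pos `roi_profile` objects (e.g. negative- and
#'   positive-modulation networks).
#' @return one of "negative_earlier", "positive_earlier", "tie", or
#'   "undefined" when either onset is NA.
#' @export
compare_onsets <- function(neg, pos) {
  on <- attr(neg, "onset_of_significance")
  op <- attr(pos, "onset_of_significance")
  if (is.na(on) || is.na(op)) return("undefined")
  if (on < op) "negative_earlier" else if (op < on) "positive_earlier"
  else "tie"
}
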