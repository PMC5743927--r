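#' First-level parametric GLM and group random-effects maps
#'
#' Each run is modeled with onset regressors for the four conditions
#' (correct/incorrect x OG/PM) convolved with a canonical HRF, four
#' parametric regressors carrying the mean-centered RT of each condition,
#' six head-motion covariates, and a discrete-cosine high-pass set
#' (cut-off period 128 s) plus constant as nuisance columns. Voxelwise OLS
#' betas are averaged across runs per subject, and group inference is a
#' voxelwise one-sample t-test with Bonferroni family-wise correction.
#'
#' @name glm_module
NULL

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities in the standard convention
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak:undershoot ratio 6, 32-s support), peak-normalized to 1.
#' The kernel peaks ~5 s after the event.
#'
#' @param dt sampling step in seconds.
#' @param peak_delay,undershoot_delay gamma delays (s).
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param duration kernel support (s).
#' @return numeric kernel sampled at `seq(0, duration, by = dt)`.
#' @export
canonical_hrf <- function(dt = 0.1, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          ratio = 6, duration = 32) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h / max(h)
}

#' Discrete-cosine high-pass basis
#'
#' Orthonormal DCT columns spanning fluctuations slower than the cut-off
#' period, plus the constant; including them in the design is equivalent to
#' high-pass filtering the data before fitting. The column count is
#' floor(2 * n_volumes * tr_s / cutoff_s) + 1 (constant included).
#'
#' @param n_volumes number of volumes.
#' @param tr_s repetition time (s).
#' @param cutoff_s cut-off period (s), default 128; `Inf` gives the constant
#'   only.
#' @return matrix `n_volumes` x K with columns `constant`, `drift_1`, ...
#' @export
highpass_basis <- function(n_volumes, tr_s, cutoff_s = 128) {
  if (is.finite(cutoff_s) && cutoff_s <= 2 * tr_s)
    stop("`cutoff_s` must exceed 2 * tr_s", call. = FALSE)
  n <- as.integer(n_volumes)
  K <- if (is.finite(cutoff_s)) floor(2 * n * tr_s / cutoff_s) else 0L
  i <- seq_len(n)
  X <- matrix(1 / sqrt(n), n, K + 1L)
  for (k in seq_len(K))
    X[, k + 1L] <- sqrt(2 / n) * cos(pi * k * (2 * i - 1) / (2 * n))
  colnames(X) <- c("constant", if (K > 0) paste0("drift_", seq_len(K)))
  X
}

glm_conditions <- c("OG_correct", "OG_incorrect", "PM_correct", "PM_incorrect")

event_condition <- function(events) {
  paste0(events$trial_type, ifelse(events$correct, "_correct", "_incorrect"))
}

#' Build the first-level design matrix for one run
#'
#' Per occurring condition: a unit-stick onset regressor and a parametric
#' regressor whose sticks are weighted by that condition's mean-centered RT
#' (trials without a response carry no parametric stick). Both are convolved
#' with the canonical HRF at 0.1-s resolution and sampled at volume times.
#' Motion columns pass through unmodified; the DCT high-pass set (constant
#' included) is appended as nuisance. Empty conditions and degenerate
#' (all-zero) parametric columns are dropped and recorded.
#'
#' @param events events table for the run.
#' @param motion `n_volumes` x 6 motion matrix (NULL to omit).
#' @param tr_s repetition time (s).
#' @param n_volumes number of volumes.
#' @param cutoff_s high-pass cut-off period (s).
#' @param hrf_args named list of overrides for [canonical_hrf()].
#' @return a `design_matrix`: list with `X` (named columns), `task_cols`,
#'   `pmod_cols`, `nuisance_cols`, `dropped`, `tr_s`, `n_volumes`.
#' @export
build_design_matrix <- function(events, motion = NULL, tr_s = 2,
                                n_volumes = 306L, cutoff_s = 128,
                                hrf_args = list()) {
  if (nrow(events) == 0L) stop("no events", call. = FALSE)
  if (max(events$onset) > n_volumes * tr_s)
    stop("events extend beyond the scan", call. = FALSE)
  vol_times <- tr_s * seq_len(n_volumes)
  cond <- event_condition(events)
  dropped <- character(0)
  cols <- list()
  for (cd in glm_conditions) {
    sel <- cond == cd
    if (!any(sel)) {
      dropped <- c(dropped, paste0("onset_", cd), paste0("pmod_RT_", cd))
      next
    }
    cols[[paste0("onset_", cd)]] <-
      onset_regressor(events$onset[sel], vol_times = vol_times)
    rt <- events$rt_ms[sel]
    resp <- !is.na(rt)
    w <- rt[resp] - mean(rt[resp])
    if (sum(resp) == 0L || all(abs(w) < 1e-12)) {
      dropped <- c(dropped, paste0("pmod_RT_", cd))
    } else {
      cols[[paste0("pmod_RT_", cd)]] <-
        onset_regressor(events$onset[sel][resp], weights = w,
                        vol_times = vol_times)
    }
  }
  if (length(cols) == 0L) stop("all conditions empty", call. = FALSE)
  task_cols <- grep("^onset_", names(cols), value = TRUE)
  pmod_cols <- grep("^pmod_", names(cols), value = TRUE)
  X <- do.call(cbind, cols)
  if (!is.null(motion)) {
    stopifnot(nrow(motion) == n_volumes, ncol(motion) == 6L)
    colnames(motion) <- paste0("motion_", 1:6)
    X <- cbind(X, motion)
  }
  hp <- highpass_basis(n_volumes, tr_s, cutoff_s)
  X <- cbind(X, hp)
  structure(list(X = X, task_cols = task_cols, pmod_cols = pmod_cols,
                 motion_cols = if (is.null(motion)) character(0)
                               else colnames(motion),
                 nuisance_cols = colnames(hp), dropped = dropped,
                 tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 cutoff_s = cutoff_s, hrf_args = hrf_args),
            class = "design_matrix")
}

bold_matrix <- function(bold) {
  if (inherits(bold, "bold_run")) {
    d <- dim(bold$data)
    nt <- d[length(d)]
    t(matrix(bold$data, ncol = nt))
  } else if (is.matrix(bold)) bold
  else stop("`bold` must be a bold_run or a time-by-voxel matrix",
            call. = FALSE)
}

#' Fit the run-level GLM by ordinary least squares
#'
#' @param bold a `bold_run` or a time-by-voxel matrix.
#' @param design a `design_matrix`.
#' @return a `glm_fit`: list with `betas` (regressors x voxels), `sigma2`
#'   (residual variance per voxel), `df_resid`, `xtx_inv_diag`, `design`.
#' @export
fit_run_glm <- function(bold, design) {
  Y <- bold_matrix(bold)
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  if (ncol(X) >= nrow(X))
    stop("more regressors than volumes", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qx, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  structure(list(betas = betas, sigma2 = sigma2, df_resid = df,
                 xtx_inv_diag = stats::setNames(diag(xtx_inv), colnames(X)),
                 design = design),
            class = "glm_fit")
}

#' Per-voxel t statistic for one design column
#'
#' @param fit a `glm_fit`.
#' @param column column name.
#' @return numeric vector of t values (df = `fit$df_resid`).
#' @export
column_tstat <- function(fit, column) {
  if (!column %in% rownames(fit$betas))
    stop("unknown design column: ", column, call. = FALSE)
  fit$betas[column, ] / sqrt(fit$sigma2 * fit$xtx_inv_diag[[column]])
}

#' Subject-level contrast: average a condition beta across runs
#'
#' Runs in which the column was dropped (empty or degenerate condition)
#' contribute nothing; the average is over the runs that carry it.
#'
#' @param fits list of `glm_fit`, one per run.
#' @param column design column name (e.g. "pmod_RT_OG_correct").
#' @return numeric vector, one value per voxel (NA if no run had the column).
#' @export
subject_contrast <- function(fits, column) {
  have <- Filter(function(f) column %in% rownames(f$betas), fits)
  if (length(have) == 0L)
    return(rep(NA_real_, ncol(fits[[1]]$betas)))
  rowMeans(do.call(cbind, lapply(have, function(f) f$betas[column, ])))
}

#' Group-level one-sample t-test map
#'
#' Voxelwise one-sample t across subjects on a subject-by-voxel contrast
#' matrix, with optional Bonferroni family-wise correction over voxels.
#' Positive and negative significance masks are returned separately, so one
#' call yields e.g. the positive and negative RT-modulation maps, and a call
#' on the onset contrast yields activation/deactivation maps.
#'
#' @param con matrix subjects x voxels.
#' @param alpha significance level (applied after correction).
#' @param correction "bonferroni" (over voxels) or "none".
#' @param extra_bonferroni additional Bonferroni factor (e.g. number of
#'   pre-stimulus windows tested), default 1.
#' @return a `group_map`: list with `mean`, `t`, `df`, `p`, `p_corrected`,
#'   `pos_mask`, `neg_mask`, `alpha`, `correction`, `n_voxels`.
#' @export
group_ttest_map <- function(con, alpha = 0.05,
                            correction = c("bonferroni", "none"),
                            extra_bonferroni = 1) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(con), nrow(con) >= 2L)
  n <- nrow(con)
  m <- colMeans(con)
  se <- apply(con, 2L, stats::sd) / sqrt(n)
  t <- m / se
  df <- n - 1L
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  factor <- if (correction == "bonferroni") ncol(con) else 1
  p_corr <- pmin(p * factor * extra_bonferroni, 1)
  structure(list(mean = m, t = t, df = df, p = p, p_corrected = p_corr,
                 pos_mask = !is.na(t) & t > 0 & p_corr < alpha,
                 neg_mask = !is.na(t) & t < 0 & p_corr < alpha,
                 alpha = alpha, correction = correction,
                 n_voxels = ncol(con)),
            class = "group_map")
}

#' Overlap of two significance masks
#'
#' E.g. voxels both deactivated by the task and positively modulated by RT.
#'
#' @param a,b logical masks of equal length.
#' @return logical mask.
#' @export
overlap_map <- function(a, b) {
  stopifnot(length(a) == length(b))
  a & b
}
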