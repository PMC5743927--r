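# Independent oracles and small fixture builders. Everything here is
# deliberately written the slow, explicit way (loops, textbook formulas)
# and shares no code with the package's vectorized implementations.

# Textbook Pearson correlation via raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxy <- sum(x * y); sxx <- sum(x^2); syy <- sum(y^2)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# Explicit linear detrend: OLS slope/intercept from closed-form sums.
oracle_detrend <- function(y) {
  t <- seq_along(y)
  b <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  a <- mean(y) - b * mean(t)
  y - (a + b * t)
}

# Piecewise-linear interpolant of (onsets, values) at time tt; NA outside.
oracle_interp <- function(onsets, values, tt) {
  if (tt < onsets[1] || tt > onsets[length(onsets)]) return(NA_real_)
  for (i in seq_len(length(onsets) - 1L)) {
    if (tt >= onsets[i] && tt <= onsets[i + 1L]) {
      f <- (tt - onsets[i]) / (onsets[i + 1L] - onsets[i])
      return(values[i] + f * (values[i + 1L] - values[i]))
    }
  }
  values[length(values)]
}

# Brute-force lagged Fisher-Z profile: explicit index shifting, per-pair
# interpolation, textbook Pearson, atanh with the same clamp rule.
oracle_lag_profile <- function(bold_mat, events, lags, tr_s,
                               max_gap_s = 15, min_overlap = 10) {
  nt <- nrow(bold_mat); nv <- ncol(bold_mat)
  Y <- apply(bold_mat, 2L, oracle_detrend)
  use <- events$trial_type == "OG" & events$correct & !is.na(events$rt_ms)
  ons <- events$onset[use]; val <- events$rt_ms[use]
  Z <- matrix(NA_real_, nv, length(lags))
  for (j in seq_along(lags)) {
    xs <- c(); rows <- c()
    for (k in seq_len(nt)) {
      bt <- tr_s * k - lags[j]
      v <- oracle_interp(ons, val, bt)
      if (is.na(v)) next
      # replicate the long-gap rule: no bridging across gaps > max_gap_s
      i <- findInterval(bt, ons)
      if (i >= 1 && i < length(ons) && ons[i + 1] - ons[i] > max_gap_s) next
      xs <- c(xs, v); rows <- c(rows, k)
    }
    if (length(xs) < min_overlap || sd(xs) == 0) next
    for (v in seq_len(nv)) {
      r <- oracle_pearson(xs, Y[rows, v])
      r <- min(max(r, -(1 - 1e-6)), 1 - 1e-6)
      Z[v, j] <- atanh(r)
    }
  }
  Z
}

# Independent trial-sequence constraint checker.
oracle_check_sequence <- function(sq, n_pm = 20L, min_gap = 4L,
                                  n_lead_og = 4L) {
  pm <- which(sq$trial_type == "PM")
  all(sq$trial_type[seq_len(n_lead_og)] == "OG") &&
    length(pm) == n_pm &&
    (length(pm) < 2L || all(diff(pm) - 1L >= min_gap)) &&
    all(sq$onset == 3 * seq_len(nrow(sq)))
}

# Small single-run fixture: sequence, RTs, events, optional BOLD.
tiny_run <- function(seed = 1L, n_trials = 60L, n_pm = 6L,
                     n_volumes = 90L, specs = NULL, ...) {
  sq <- generate_trial_sequence(n_trials = n_trials, n_pm = n_pm,
                                seed = seed)
  trace <- simulate_vigilance_trace(n_trials, seed = seed + 1L)
  rts <- simulate_rt_series(sq, trace, seed = seed + 2L, ...)
  out <- list(sequence = sq, rts = rts, events = make_events(sq, rts))
  if (!is.null(specs))
    out$bold <- simulate_bold_run(sq, rts, specs, n_volumes = n_volumes,
                                  seed = seed + 3L)
  out
}

# Voxel specs for a tiny all-modulated grid (4 positive, 4 negative).
tiny_specs <- function(neg_lead_s = 0, ...) {
  default_voxel_specs(grid_shape = c(4L, 2L, 1L), n_positive = 4L,
                      n_negative = 4L, neg_lead_s = neg_lead_s, ...)
}
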