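#' Synthetic data: latent vigilance, reaction times, and coupled BOLD
#'
#' The generator produces data with the statistical structure the analysis
#' assumes: a slowly autocorrelated latent vigilance process drives
#' trial-by-trial reaction times, and selected voxels' BOLD signal is coupled
#' to the reaction-time series with a known sign and a known temporal lead.
#' Ground truth is carried along with every simulated run so that the GLM and
#' cross-correlation stages can be validated by parameter recovery.
#'
#' @name synthetic_data
NULL

#' Simulate a latent vigilance trace
#'
#' A stationary AR(1) process on trials: x_t = ar * x_(t-1) + e_t with
#' e_t ~ N(0, innovation_sd^2) and x_1 drawn from the stationary marginal
#' N(0, innovation_sd^2 / (1 - ar^2)). With the default ar = 0.9 and a 3-s
#' trial spacing the autocorrelation decays over roughly 30 trials (~90 s),
#' emulating slow fluctuation of the attentional state.
#'
#' @param n_trials number of trials.
#' @param ar AR(1) coefficient in [0, 1).
#' @param innovation_sd innovation standard deviation.
#' @param seed integer seed.
#' @return numeric vector of length `n_trials`.
#' @export
simulate_vigilance_trace <- function(n_trials, ar = 0.9, innovation_sd = 1,
                                     seed = 1L) {
  if (ar < 0 || ar >= 1)
    stop("`ar` must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    e <- rnorm(n_trials, sd = innovation_sd)
    x0 <- rnorm(1L, sd = innovation_sd / sqrt(1 - ar^2))
    as.numeric(stats::filter(e, ar, method = "recursive",
                             init = x0))
  })
}

#' Simulate a reaction-time series for one run
#'
#' RT = baseline (+ PM penalty on PM trials) + rt_scale * vigilance trace +
#' Gaussian noise, floored at 150 ms and capped just below the next stimulus
#' onset (responses are valid until the next stimulus). Correctness is
#' Bernoulli per condition. Defaults are calibrated to group means of about
#' 816 ms (OG) / 950 ms (PM) and accuracies of 97% (OG) / 69% (PM).
#'
#' @param sequence a trial sequence from [generate_trial_sequence()].
#' @param trace vigilance trace (length = number of trials).
#' @param baseline_og_ms,pm_penalty_ms mean OG RT and additive PM penalty.
#' @param rt_scale_ms RT change in ms per unit of the latent trace.
#' @param noise_sd_ms trial-level Gaussian RT noise (ms).
#' @param accuracy_og,accuracy_pm response accuracy per condition.
#' @param seed integer seed.
#' @return data.frame with `trial_type`, `rt_ms`, `correct`, `response`.
#' @export
simulate_rt_series <- function(sequence, trace,
                               baseline_og_ms = 816, pm_penalty_ms = 134,
                               rt_scale_ms = 100, noise_sd_ms = 80,
                               accuracy_og = 0.97, accuracy_pm = 0.69,
                               seed = 1L) {
  stopifnot(nrow(sequence) == length(trace))
  if (accuracy_og < 0 || accuracy_og > 1 || accuracy_pm < 0 || accuracy_pm > 1)
    stop("accuracies must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    n <- nrow(sequence)
    is_pm <- sequence$trial_type == "PM"
    rt <- baseline_og_ms + pm_penalty_ms * is_pm +
      rt_scale_ms * trace + rnorm(n, sd = noise_sd_ms)
    soa_ms <- attr(sequence, "soa_s") * 1000
    if (is.null(soa_ms)) soa_ms <- 3000
    rt <- pmin(pmax(rt, 150), soa_ms - 1)
    acc <- ifelse(is_pm, accuracy_pm, accuracy_og)
    correct <- runif(n) < acc
    response <- ifelse(correct, sequence$correct_response,
                       wrong_response(sequence$correct_response))
    data.frame(trial_type = sequence$trial_type, rt_ms = rt,
               correct = correct, response = response,
               stringsAsFactors = FALSE)
  })
}

# A response different from the correct one (vectorized).
wrong_response <- function(correct_response) {
  opts <- c("left", "right", "pm_button")
  vapply(correct_response,
         function(cr) sample(setdiff(opts, cr), 1L), "",
         USE.NAMES = FALSE)
}

#' Combine a trial sequence and a reaction-time series into an events table
#'
#' @param sequence trial sequence.
#' @param rts RT series from [simulate_rt_series()].
#' @return events data.frame (BIDS-style, `onset` and `duration` first).
#' @export
make_events <- function(sequence, rts) {
  stopifnot(nrow(sequence) == nrow(rts))
  ev <- data.frame(
    onset = sequence$onset, duration = sequence$duration,
    trial_type = sequence$trial_type,
    response = rts$response, rt_ms = rts$rt_ms, correct = rts$correct,
    triangle_row = sequence$triangle_row, triangle_col = sequence$triangle_col,
    polygon_row = sequence$polygon_row, polygon_col = sequence$polygon_col,
    correct_response = sequence$correct_response,
    stringsAsFactors = FALSE
  )
  attr(ev, "soa_s") <- attr(sequence, "soa_s")
  ev
}

#' Voxel specification table for a simulation grid
#'
#' Assigns every voxel of the grid a coupling spec: `modulation` is
#' "positive", "negative" or "none"; `amplitude` is the signal change (%)
#' per SD of RT; `lead_s` is how many seconds the coupling precedes the
#' behavioral response (0 for task-locked voxels; the timing-recovery
#' experiments set the negative network's lead to 10 s);
#' `task_amplitude` is the % response per trial onset (half of
#' the positively modulated voxels are given a negative task response so the
#' deactivation/modulation overlap structure is present in the ground truth).
#'
#' @param grid_shape integer vector (nx, ny, nz).
#' @param n_positive,n_negative number of positively / negatively modulated
#'   voxels.
#' @param amplitude modulation amplitude (% per SD of RT).
#' @param neg_lead_s temporal lead (s) of the negative-modulation voxels
#'   (default 0; set to e.g. 10 to emulate a default-network-like region
#'   whose coupling anticipates the behavioral response).
#' @param pos_lead_s temporal lead (s) of the positive-modulation voxels.
#' @param task_amplitude task response amplitude (%).
#' @param noise_sd voxel noise SD (%).
#' @param drift_slope linear drift (% per minute).
#' @return data.frame with one row per voxel: `x`, `y`, `z`, `modulation`,
#'   `amplitude`, `lead_s`, `task_amplitude`, `noise_sd`, `drift_slope`.
#' @export
default_voxel_specs <- function(grid_shape = c(12L, 12L, 8L),
                                n_positive = 24L, n_negative = 24L,
                                amplitude = 0.5,
                                neg_lead_s = 0, pos_lead_s = 0,
                                task_amplitude = 1,
                                noise_sd = 1, drift_slope = 0.2) {
  nv <- prod(grid_shape)
  if (n_positive + n_negative > nv)
    stop("more modulated voxels than grid voxels", call. = FALSE)
  idx <- arrayInd(seq_len(nv), grid_shape)
  spec <- data.frame(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    modulation = "none", amplitude = 0, lead_s = 0,
    task_amplitude = 0, noise_sd = noise_sd, drift_slope = drift_slope,
    stringsAsFactors = FALSE
  )
  # evenly spaced voxel indices, interleaving positive and negative
  n_mod <- n_positive + n_negative
  if (n_mod > 0L) {
    pick <- unique(round(seq(1L, nv, length.out = n_mod)))
    pos <- pick[seq_len(n_positive)]
    neg <- setdiff(pick, pos)[seq_len(n_negative)]
    spec$modulation[pos] <- "positive"
    spec$amplitude[pos] <- amplitude
    spec$lead_s[pos] <- pos_lead_s
    spec$task_amplitude[pos] <- task_amplitude
    # half the positive voxels deactivate to the task (overlap structure)
    deact <- pos[seq_len(length(pos) %/% 2L)]
    spec$task_amplitude[deact] <- -task_amplitude
    spec$modulation[neg] <- "negative"
    spec$amplitude[neg] <- amplitude
    spec$lead_s[neg] <- neg_lead_s
    spec$task_amplitude[neg] <- task_amplitude
  }
  attr(spec, "grid_shape") <- as.integer(grid_shape)
  spec
}

#' Simulate one BOLD run coupled to a reaction-time series
#'
#' Each voxel's time series is
#' baseline + task_amplitude * (onset sticks convolved with the HRF)
#' + sign(modulation) * amplitude * (RT-weighted sticks, shifted earlier by
#' `lead_s`, convolved with the HRF) + linear drift + Gaussian noise.
#' RT weights are the standardized RTs of responded trials, so `amplitude`
#' is the % signal change per SD of RT. Regressors are built at 0.1-s
#' resolution and sampled at volume acquisition times 2, 4, ... seconds.
#'
#' @param sequence trial sequence.
#' @param rts RT series.
#' @param voxel_specs voxel spec table (see [default_voxel_specs()]); its
#'   `grid_shape` attribute sets the spatial dimensions.
#' @param tr_s repetition time (s).
#' @param n_volumes number of volumes (after dummy removal).
#' @param baseline mean signal level.
#' @param noise_ar AR(1) coefficient of the voxel noise (0 = white).
#' @param seed integer seed.
#' @return a `bold_run`: list with `data` (4D array x,y,z,t), `tr_s`,
#'   `n_volumes`, `grid_shape`, `ground_truth` (the voxel spec table).
#' @export
simulate_bold_run <- function(sequence, rts, voxel_specs,
                              tr_s = 2, n_volumes = 306L,
                              baseline = 100, noise_ar = 0,
                              seed = 1L) {
  grid_shape <- attr(voxel_specs, "grid_shape")
  if (is.null(grid_shape))
    stop("`voxel_specs` must carry a grid_shape attribute", call. = FALSE)
  nv <- prod(grid_shape)
  if (nrow(voxel_specs) != nv ||
      any(voxel_specs$x < 1 | voxel_specs$x > grid_shape[1]) ||
      any(voxel_specs$y < 1 | voxel_specs$y > grid_shape[2]) ||
      any(voxel_specs$z < 1 | voxel_specs$z > grid_shape[3]))
    stop("voxel index outside grid", call. = FALSE)
  run_len <- attr(sequence, "run_length_s")
  if (is.null(run_len)) run_len <- max(sequence$onset)
  if (n_volumes * tr_s < run_len)
    stop("scan shorter than the task run", call. = FALSE)

  dt <- 0.1
  vol_times <- tr_s * seq_len(n_volumes)
  task_reg <- onset_regressor(sequence$onset, weights = NULL,
                              vol_times = vol_times, dt = dt)
  responded <- !is.na(rts$rt_ms)
  w <- rep(NA_real_, nrow(rts))
  w[responded] <- scale(rts$rt_ms[responded])[, 1]

  # one modulated regressor per distinct lead among modulated voxels
  modulated <- voxel_specs$modulation != "none"
  leads <- sort(unique(voxel_specs$lead_s[modulated]))
  mod_regs <- lapply(leads, function(L)
    onset_regressor(sequence$onset[responded] - L,
                    weights = w[responded], vol_times = vol_times, dt = dt))
  names(mod_regs) <- as.character(leads)

  sgn <- ifelse(voxel_specs$modulation == "positive", 1,
         ifelse(voxel_specs$modulation == "negative", -1, 0))
  minutes <- vol_times / 60

  sig <- matrix(baseline, n_volumes, nv)
  sig <- sig + outer(task_reg, voxel_specs$task_amplitude)
  for (i in which(modulated)) {
    sig[, i] <- sig[, i] + sgn[i] * voxel_specs$amplitude[i] *
      mod_regs[[as.character(voxel_specs$lead_s[i])]]
  }
  sig <- sig + outer(minutes, voxel_specs$drift_slope)

  noise <- with_seed(seed, matrix(rnorm(n_volumes * nv), n_volumes, nv))
  if (noise_ar > 0) {
    noise <- apply(noise, 2L, function(e)
      as.numeric(stats::filter(e, noise_ar, method = "recursive"))) *
      sqrt(1 - noise_ar^2)
  }
  sig <- sig + sweep(noise, 2L, voxel_specs$noise_sd, "*")

  structure(list(
    data = array(t(sig), dim = c(grid_shape, n_volumes)),
    tr_s = tr_s, n_volumes = as.integer(n_volumes),
    grid_shape = as.integer(grid_shape),
    ground_truth = voxel_specs
  ), class = "bold_run")
}

# Stick function at `onsets` (weights default 1), convolved with the
# canonical HRF at resolution `dt`, sampled at `vol_times`. Onsets moved
# before time 0 by a lead are kept: their HRF tails still fall in the run.
onset_regressor <- function(onsets, weights = NULL, vol_times, dt = 0.1) {
  if (is.null(weights)) weights <- rep(1, length(onsets))
  t_max <- max(vol_times)
  pad <- 64  # cover HRF tails of leads/late onsets
  grid0 <- -pad
  n_grid <- round((t_max + pad - grid0) / dt) + 1L
  sticks <- numeric(n_grid)
  k <- round((onsets - grid0) / dt) + 1L
  ok <- k >= 1L & k <= n_grid
  for (i in which(ok)) sticks[k[i]] <- sticks[k[i]] + weights[i]
  h <- canonical_hrf(dt = dt)
  conv <- convolve(sticks, rev(h), type = "open")[seq_len(n_grid)]
  conv[round((vol_times - grid0) / dt) + 1L]
}

#' Simulate head-motion parameters
#'
#' Six columns (3 translations in mm, 3 rotations in radians) as smooth
#' low-amplitude random walks: cumulative Gaussian steps passed through a
#' short moving average.
#'
#' @param n_volumes number of volumes.
#' @param step_sd random-walk step SD.
#' @param seed integer seed.
#' @return matrix `n_volumes` x 6.
#' @export
simulate_motion <- function(n_volumes = 306L, step_sd = 0.01, seed = 1L) {
  with_seed(seed, {
    m <- apply(matrix(rnorm(n_volumes * 6L, sd = step_sd), n_volumes, 6L),
               2L, cumsum)
    sm <- apply(m, 2L, function(x)
      as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2)))
    sm[is.na(sm)] <- m[is.na(sm)]
    colnames(sm) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    sm
  })
}

#' Simulate a cohort of subjects
#'
#' Generates `n_subjects` subjects with `runs_per_subject` runs each; every
#' run has its own trial sequence, vigilance trace, RT series, BOLD run and
#' motion table. Per-run seeds are derived deterministically from the master
#' seed, so the whole cohort is reproducible from one integer.
#'
#' @param n_subjects number of subjects (default 21).
#' @param runs_per_subject runs per subject (default 6).
#' @param voxel_specs voxel spec table shared by all subjects.
#' @param tr_s,n_volumes scan parameters.
#' @param task named list of overrides for [generate_trial_sequence()].
#' @param vigilance named list of overrides for [simulate_vigilance_trace()].
#' @param rt named list of overrides for [simulate_rt_series()].
#' @param noise_ar AR(1) coefficient of BOLD noise.
#' @param keep_bold if FALSE, BOLD runs are not generated (behavioral-only
#'   cohorts are much cheaper).
#' @param seed master seed.
#' @return a `cohort`: list with `subjects` (list of lists of runs, each run
#'   a list with `events`, `bold`, `motion`), `voxel_specs`, `config`.
#' @export
simulate_cohort <- function(n_subjects = 21L, runs_per_subject = 6L,
                            voxel_specs = default_voxel_specs(),
                            tr_s = 2, n_volumes = 306L,
                            task = list(), vigilance = list(), rt = list(),
                            noise_ar = 0, keep_bold = TRUE, seed = 1L) {
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    runs <- vector("list", runs_per_subject)
    for (r in seq_len(runs_per_subject)) {
      sq <- do.call(generate_trial_sequence,
                    c(task, list(seed = derive_seed(seed, s, r, 1L))))
      tr_args <- c(list(n_trials = nrow(sq)), vigilance,
                   list(seed = derive_seed(seed, s, r, 2L)))
      trace <- do.call(simulate_vigilance_trace, tr_args)
      rts <- do.call(simulate_rt_series,
                     c(list(sequence = sq, trace = trace), rt,
                       list(seed = derive_seed(seed, s, r, 3L))))
      run <- list(events = make_events(sq, rts),
                  motion = simulate_motion(n_volumes,
                                           seed = derive_seed(seed, s, r, 4L)))
      if (keep_bold)
        run$bold <- simulate_bold_run(sq, rts, voxel_specs,
                                      tr_s = tr_s, n_volumes = n_volumes,
                                      noise_ar = noise_ar,
                                      seed = derive_seed(seed, s, r, 5L))
      runs[[r]] <- run
    }
    subjects[[s]] <- runs
  }
  structure(list(subjects = subjects, voxel_specs = voxel_specs,
                 config = list(n_subjects = n_subjects,
                               runs_per_subject = runs_per_subject,
                               tr_s = tr_s, n_volumes = n_volumes,
                               noise_ar = noise_ar, seed = seed)),
            class = "cohort")
}
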