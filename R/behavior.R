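#' Behavioral analyses of a cohort of event tables
#'
#' Four analyses on the per-run event tables of a cohort: (1) accuracy and
#' correct-trial RT, OG vs PM, with paired t-tests; (2) RT of correct OG
#' trials immediately preceding PM trials, split by PM correctness, and the
#' correlation between the preceding-OG RT and the following correct-PM RT
#' (pooled across subjects, and per subject with Fisher-Z + one-sample t);
#' (3) the correlation between the OG stimulus-configuration distance
#' classes' deviation from the knight-move (PM) distance and their mean RT.
#'
#' @name behavior
NULL

# Normalize input: a cohort object or a list of subjects, each a list of
# runs that are either events data.frames or lists with an $events field.
cohort_events <- function(x) {
  subjects <- if (inherits(x, "cohort")) x$subjects else x
  lapply(subjects, function(runs)
    lapply(runs, function(r) if (is.data.frame(r)) r else r$events))
}

#' Accuracy and RT summary, OG vs PM, with paired group tests
#'
#' Accuracy is the fraction of correct responses; RT means use correct
#' trials only. Group tests are two-sided paired t-tests across subjects.
#' Subjects without correct trials in a condition are excluded from the RT
#' test (and listed in the `excluded` attribute).
#'
#' @param x a cohort or list of subjects' event tables.
#' @return list with `subjects` (per-subject, per-condition data.frame),
#'   `group` (mean/SEM per condition and measure), `tests` (data.frame:
#'   analysis, statistic, df, p, n).
#' @export
performance_summary <- function(x) {
  ev <- cohort_events(x)
  if (length(ev) < 2L) stop("need >= 2 subjects for group tests",
                            call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(ev), function(s) {
    d <- do.call(rbind, ev[[s]])
    do.call(rbind, lapply(c("OG", "PM"), function(tt) {
      sel <- d$trial_type == tt
      ok <- sel & d$correct
      data.frame(subject = s, condition = tt,
                 n_trials = sum(sel),
                 accuracy = mean(d$correct[sel]),
                 mean_rt_ms = if (any(ok)) mean(d$rt_ms[ok], na.rm = TRUE)
                              else NA_real_)
    }))
  }))
  acc <- stats::reshape(per[, c("subject", "condition", "accuracy")],
                        direction = "wide", idvar = "subject",
                        timevar = "condition")
  rt <- stats::reshape(per[, c("subject", "condition", "mean_rt_ms")],
                       direction = "wide", idvar = "subject",
                       timevar = "condition")
  rt_ok <- stats::complete.cases(rt)
  excluded <- rt$subject[!rt_ok]
  t_acc <- stats::t.test(acc$accuracy.OG, acc$accuracy.PM, paired = TRUE)
  t_rt <- stats::t.test(rt$mean_rt_ms.OG[rt_ok], rt$mean_rt_ms.PM[rt_ok],
                        paired = TRUE)
  group <- stats::aggregate(cbind(accuracy, mean_rt_ms) ~ condition,
                            data = per, FUN = mean)
  group$sem_accuracy <- stats::aggregate(accuracy ~ condition, data = per,
    FUN = function(v) stats::sd(v) / sqrt(length(v)))$accuracy
  group$sem_rt <- stats::aggregate(mean_rt_ms ~ condition, data = per,
    FUN = function(v) stats::sd(v) / sqrt(length(v)))$mean_rt_ms
  tests <- data.frame(
    analysis = c("accuracy_OG_vs_PM", "rt_OG_vs_PM"),
    statistic = c(unname(t_acc$statistic), unname(t_rt$statistic)),
    df = c(unname(t_acc$parameter), unname(t_rt$parameter)),
    p = c(t_acc$p.value, t_rt$p.value),
    n = c(nrow(acc), sum(rt_ok))
  )
  out <- list(subjects = per, group = group, tests = tests)
  attr(out, "excluded_from_rt_test") <- excluded
  out
}

# Pairs (preceding correct OG trial, PM trial) per subject: the trial at
# the sequence position immediately before each PM trial, kept only if it
# is OG and correct with a response.
pre_pm_pairs <- function(runs) {
  do.call(rbind, lapply(runs, function(d) {
    pm <- which(d$trial_type == "PM")
    pm <- pm[pm > 1L]
    prev <- pm - 1L
    keep <- d$trial_type[prev] == "OG" & d$correct[prev] &
      !is.na(d$rt_ms[prev])
    data.frame(og_rt = d$rt_ms[prev[keep]],
               pm_rt = d$rt_ms[pm[keep]],
               pm_correct = d$correct[pm[keep]])
  }))
}

#' RT before PM trials: pre-error analysis and OG-PM coupling
#'
#' (a) Paired t-test across subjects on mean correct-OG RT immediately
#' preceding correct vs incorrect PM trials. (b) Correlation between the
#' preceding-OG RT and the following correct-PM RT, computed both pooled
#' over all trials of all subjects and per subject (Fisher-Z transformed,
#' then a one-sample t-test). Subjects with fewer than 3 usable pairs are
#' excluded from the per-subject correlation.
#'
#' @param x a cohort or list of subjects' event tables.
#' @return list with `pre_error` (t-test summary), `pooled_correlation`
#'   (r, p, n), `subject_correlation` (mean Fisher-Z, t, df, p, n), and
#'   `excluded` (subjects dropped from the per-subject correlation).
#' @export
pre_pm_analysis <- function(x) {
  ev <- cohort_events(x)
  pairs <- lapply(ev, pre_pm_pairs)
  # (a) pre-error: subject means of OG RT before correct vs incorrect PM
  before <- do.call(rbind, lapply(seq_along(pairs), function(s) {
    p <- pairs[[s]]
    data.frame(subject = s,
               before_correct = mean(p$og_rt[p$pm_correct]),
               before_incorrect = mean(p$og_rt[!p$pm_correct]))
  }))
  ok <- stats::complete.cases(before)
  pre_error <- if (sum(ok) >= 2L) {
    tt <- stats::t.test(before$before_correct[ok],
                        before$before_incorrect[ok], paired = TRUE)
    data.frame(statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, n = sum(ok))
  } else data.frame(statistic = NA_real_, df = NA_real_, p = NA_real_,
                    n = sum(ok))
  # (b) correlation, correct PM trials only
  all_pairs <- do.call(rbind, pairs)
  cp <- all_pairs[all_pairs$pm_correct, ]
  pooled <- if (nrow(cp) >= 3L && stats::sd(cp$og_rt) > 0 &&
                stats::sd(cp$pm_rt) > 0) {
    ct <- stats::cor.test(cp$og_rt, cp$pm_rt)
    data.frame(r = unname(ct$estimate), p = ct$p.value, n = nrow(cp))
  } else data.frame(r = NA_real_, p = NA_real_, n = nrow(cp))
  per_z <- vapply(pairs, function(p) {
    q <- p[p$pm_correct, ]
    if (nrow(q) < 3L || stats::sd(q$og_rt) == 0 || stats::sd(q$pm_rt) == 0)
      return(NA_real_)
    fisher_z(stats::cor(q$og_rt, q$pm_rt))
  }, 0)
  usable <- !is.na(per_z)
  subj <- if (sum(usable) >= 2L) {
    st <- stats::t.test(per_z[usable])
    data.frame(mean_z = mean(per_z[usable]),
               statistic = unname(st$statistic),
               df = unname(st$parameter), p = st$p.value, n = sum(usable))
  } else data.frame(mean_z = NA_real_, statistic = NA_real_,
                    df = NA_real_, p = NA_real_, n = sum(usable))
  list(
    pre_error = pre_error,
    pooled_correlation = pooled,
    subject_correlation = subj,
    excluded = which(!usable)
  )
}

#' Correlation between stimulus-distance classes and mean RT
#'
#' Correct OG trials are grouped by the Euclidean distance between the two
#' shapes (8 classes on the 4x4 grid once the knight-move distance is
#' removed). For each populated class the mean RT is computed (pooled over
#' subjects), and the Pearson correlation between |class distance - sqrt(5)|
#' and the class mean RT is returned, with n = number of populated classes.
#'
#' @param x a cohort or list of subjects' event tables.
#' @return list with `classes` (data.frame: distance, abs_diff_from_pm,
#'   mean_rt_ms, n_trials) and `correlation` (r, p, n).
#' @export
distance_rt_correlation <- function(x) {
  ev <- cohort_events(x)
  d <- do.call(rbind, lapply(ev, function(runs) do.call(rbind, runs)))
  ok <- d$trial_type == "OG" & d$correct & !is.na(d$rt_ms)
  d <- d[ok, ]
  dist <- trial_distance(d)
  classes <- enumerate_distance_classes()$og
  cls <- vapply(dist, function(v) classes[which.min(abs(classes - v))], 0)
  tab <- do.call(rbind, lapply(classes, function(cv) {
    sel <- abs(cls - cv) < 1e-9
    if (!any(sel)) return(NULL)
    data.frame(distance = cv, abs_diff_from_pm = abs(cv - sqrt(5)),
               mean_rt_ms = mean(d$rt_ms[sel]), n_trials = sum(sel))
  }))
  if (is.null(tab) || nrow(tab) < 2L)
    stop("fewer than 2 populated distance classes", call. = FALSE)
  if (stats::sd(tab$mean_rt_ms) == 0)
    stop("class mean RTs are constant; correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(tab$abs_diff_from_pm, tab$mean_rt_ms)
  list(classes = tab,
       correlation = data.frame(r = unname(ct$estimate), p = ct$p.value,
                                n = nrow(tab)))
}
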