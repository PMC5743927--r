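#' Task model: grid geometry and trial sequencing
#'
#' The task is a continuous-performance paradigm on a 4 x 4 grid. Each trial
#' shows a triangle and a non-triangle polygon in two distinct cells. On
#' frequent ongoing (OG) trials the subject judges whether the polygon lies
#' left or right of the triangle; on rare prospective-memory (PM) trials the
#' two shapes are a chess knight's move apart and a third button is required.
#' Trials are presented every 3 s (0.5 s stimulus duration), 204 trials per
#' run, 20 of them PM, randomly placed with at least 4 OG trials between
#' consecutive PM trials and the first 4 trials always OG.
#'
#' @name task_model
NULL

GRID_SIZE <- 4L

check_cell <- function(cell, what = "cell") {
  if (length(cell) != 2L || anyNA(cell) ||
      any(cell < 0L) || any(cell > GRID_SIZE - 1L) ||
      any(cell != floor(cell)))
    stop(sprintf("%s must be integer (row, col) with both in [0, %d]",
                 what, GRID_SIZE - 1L), call. = FALSE)
  as.integer(cell)
}

#' Is a pair of grid cells a chess knight's move apart?
#'
#' A knight's move is an L-shape: two cells in one direction and one in the
#' orthogonal direction, i.e. (|drow|, |dcol|) is (1,2) or (2,1).
#'
#' @param a,b length-2 integer vectors (row, col), zero-based, on the 4x4 grid.
#' @return logical.
#' @examples
#' is_knight_move(c(0, 0), c(1, 2))  # TRUE
#' is_knight_move(c(0, 0), c(1, 1))  # FALSE
#' @export
is_knight_move <- function(a, b) {
  a <- check_cell(a, "a"); b <- check_cell(b, "b")
  d <- sort(abs(a - b))
  d[1] == 1L && d[2] == 2L
}

all_grid_cells <- function() {
  as.matrix(expand.grid(row = 0:(GRID_SIZE - 1L), col = 0:(GRID_SIZE - 1L)))
}

#' Euclidean distance classes of two-shape configurations
#'
#' Enumerates the distinct Euclidean distances between two distinct cells of
#' the 4x4 grid. The knight-move distance sqrt(5) defines the PM
#' configuration; the remaining distances are the OG configuration classes
#' (8 of them) used in the distance-vs-RT behavioral analysis.
#'
#' @return a list with `all` (sorted distinct distances), `og` (distances
#'   excluding sqrt(5)) and `pm` (sqrt(5)).
#' @export
enumerate_distance_classes <- function() {
  cells <- all_grid_cells()
  n <- nrow(cells)
  d2 <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d2 <- c(d2, sum((cells[i, ] - cells[j, ])^2))
  all <- sort(unique(sqrt(d2)))
  pm <- sqrt(5)
  list(all = all, og = all[abs(all - pm) > 1e-9], pm = pm)
}

#' Sample a stimulus configuration for one trial
#'
#' Draws triangle and polygon cells consistent with the trial type: a
#' knight's-move pair for PM trials; for OG trials a non-knight pair whose
#' cells differ in column, so that the left/right judgment is well defined.
#' The OG correct response is "left" when the polygon column is smaller than
#' the triangle column, "right" when larger; PM trials require "pm_button".
#' Colors are drawn from 6 categories. Uses the current RNG stream.
#'
#' @param trial_type "OG" or "PM".
#' @return a list with `triangle`, `polygon` (length-2 integer row/col),
#'   `triangle_color`, `polygon_color` (1..6), `trial_type`,
#'   `correct_response`.
#' @export
sample_stimulus <- function(trial_type = c("OG", "PM")) {
  trial_type <- match.arg(trial_type)
  cells <- all_grid_cells()
  repeat {
    ij <- sample.int(nrow(cells), 2L)
    tri <- cells[ij[1], ]; poly <- cells[ij[2], ]
    knight <- is_knight_move(tri, poly)
    if (trial_type == "PM" && knight) break
    if (trial_type == "OG" && !knight && tri[2] != poly[2]) break
  }
  list(triangle = unname(tri), polygon = unname(poly),
       triangle_color = sample.int(6L, 1L),
       polygon_color = sample.int(6L, 1L),
       trial_type = trial_type,
       correct_response = if (trial_type == "PM") "pm_button"
                          else if (poly[2] < tri[2]) "left" else "right")
}

# Sample PM positions uniformly over the feasible set: n_pm positions in
# (n_lead_og, n_trials] with every gap between consecutive PM trials
# >= min_gap OG trials. Uses the stars-and-bars bijection: a sorted
# gap-constrained n_pm-subset of a range of length m corresponds one-to-one
# to an unconstrained n_pm-subset of a range of length m - (n_pm-1)*min_gap,
# so sampling the latter uniformly and re-inflating the gaps is exactly
# uniform over the constrained set, in O(n).
sample_pm_positions <- function(n_trials, n_pm, min_gap, n_lead_og) {
  if (n_pm == 0L) return(integer(0))
  m <- n_trials - n_lead_og
  m_free <- m - (n_pm - 1L) * min_gap
  if (m_free < n_pm)
    stop("infeasible trial-sequence constraints", call. = FALSE)
  base <- sort(sample.int(m_free, n_pm))
  n_lead_og + base + min_gap * (seq_len(n_pm) - 1L)
}

#' Generate a constrained trial sequence for one run
#'
#' Trial i (1-based) onsets at `soa_s * i` seconds, so the default 204 trials
#' span 612 s, matching a 306-volume run at TR 2 s. PM positions are drawn by
#' rejection sampling over the feasible set (uniform given the constraints);
#' stimuli are then sampled per trial type.
#'
#' @param n_trials number of trials (default 204).
#' @param n_pm number of PM trials (default 20).
#' @param min_gap minimum number of OG trials between consecutive PM trials
#'   (default 4).
#' @param n_lead_og number of leading trials forced to OG (default 4).
#' @param soa_s stimulus-onset asynchrony in seconds (default 3).
#' @param duration_s stimulus duration in seconds (default 0.5).
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @return a `trial_sequence`: data.frame with columns `onset`, `duration`,
#'   `trial_type`, `triangle_row`, `triangle_col`, `polygon_row`,
#'   `polygon_col`, `correct_response`, plus attributes `run_length_s`,
#'   `soa_s`.
#' @export
generate_trial_sequence <- function(n_trials = 204L, n_pm = 20L,
                                    min_gap = 4L, n_lead_og = 4L,
                                    soa_s = 3, duration_s = 0.5,
                                    seed = 1L) {
  with_seed(seed, {
    pm_pos <- sample_pm_positions(n_trials, n_pm, min_gap, n_lead_og)
    type <- rep("OG", n_trials)
    type[pm_pos] <- "PM"
    stim <- lapply(type, sample_stimulus)
    out <- data.frame(
      onset = soa_s * seq_len(n_trials),
      duration = duration_s,
      trial_type = type,
      triangle_row = vapply(stim, function(s) s$triangle[1], 0L),
      triangle_col = vapply(stim, function(s) s$triangle[2], 0L),
      polygon_row = vapply(stim, function(s) s$polygon[1], 0L),
      polygon_col = vapply(stim, function(s) s$polygon[2], 0L),
      correct_response = vapply(stim, function(s) s$correct_response, ""),
      stringsAsFactors = FALSE
    )
    attr(out, "run_length_s") <- soa_s * n_trials
    attr(out, "soa_s") <- soa_s
    class(out) <- c("trial_sequence", "data.frame")
    out
  })
}

#' Euclidean shape distance of each trial
#'
#' @param sequence a trial sequence (or events table with the stimulus
#'   geometry columns).
#' @return numeric vector of per-trial triangle-polygon distances.
#' @export
trial_distance <- function(sequence) {
  sqrt((sequence$triangle_row - sequence$polygon_row)^2 +
       (sequence$triangle_col - sequence$polygon_col)^2)
}
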