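#' File formats: events, motion, NIfTI runs, manifests
#'
#' Events and motion tables are tab-separated text; BOLD runs are NIfTI-1
#' 4D files; manifests and sidecars are JSON. The cohort layout is
#' BIDS-like (sub-XX/func/...).
#'
#' @name cli_io
NULL

#' Write / read an events table (tab-separated, BIDS-style columns)
#' @param events events data.frame.
#' @param path file path.
#' @return `read_events` returns the events data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("correct" %in% names(ev)) ev$correct <- as.logical(ev$correct)
  ev
}

#' Write / read a motion-parameter table (6 columns, one row per volume)
#' @param motion numeric matrix n_volumes x 6.
#' @param path file path.
#' @return `read_motion` returns the matrix.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion table must have 6 columns", call. = FALSE)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Write a BOLD run as a NIfTI-1 4D file
#' @param bold a `bold_run`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(3, 3, 3, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a BOLD run from a NIfTI file
#'
#' Drops the configured number of leading dummy volumes (acquired for
#' magnetic saturation) and checks the remaining volume count against the
#' configuration when given.
#'
#' @param path NIfTI file.
#' @param dummy_volumes leading volumes to discard (default 0).
#' @param tr_s repetition time override; taken from the header otherwise.
#' @param expect_volumes if given, error unless the retained volume count
#'   matches.
#' @return a `bold_run`.
#' @export
load_bold <- function(path, dummy_volumes = 0L, tr_s = NULL,
                      expect_volumes = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D NIfTI file, got ", length(d), "D", call. = FALSE)
  if (dummy_volumes >= d[4])
    stop("fewer volumes than dummy_volumes", call. = FALSE)
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  }
  dat <- img[, , , (dummy_volumes + 1L):d[4], drop = FALSE]
  nt <- d[4] - dummy_volumes
  if (!is.null(expect_volumes) && nt != expect_volumes)
    stop(sprintf("expected %d volumes after dummy removal, found %d",
                 expect_volumes, nt), call. = FALSE)
  structure(list(data = array(as.numeric(dat), dim = c(d[1:3], nt)),
                 tr_s = tr_s, n_volumes = as.integer(nt),
                 grid_shape = as.integer(d[1:3]), ground_truth = NULL),
            class = "bold_run")
}

#' Write / read a JSON manifest or sidecar
#' @param x a list.
#' @param path file path.
#' @return `read_manifest` returns the list.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a simulated cohort in a BIDS-like layout
#'
#' One directory per subject (`sub-01/func/...`) holding the BOLD runs
#' (NIfTI), event tables (TSV) and motion tables (TSV), plus a top-level
#' JSON ground-truth manifest listing every voxel's coupling spec.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects)) {
    sub <- sprintf("sub-%02d", s)
    fdir <- file.path(dir, sub, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_along(cohort$subjects[[s]])) {
      run <- cohort$subjects[[s]][[r]]
      stem <- sprintf("%s_task-vigilance_run-%02d", sub, r)
      write_events(run$events, file.path(fdir, paste0(stem, "_events.tsv")))
      write_motion(run$motion, file.path(fdir, paste0(stem, "_motion.tsv")))
      if (!is.null(run$bold))
        write_bold(run$bold, file.path(fdir, paste0(stem, "_bold.nii.gz")))
    }
  }
  gt <- cohort$voxel_specs
  write_manifest(list(grid_shape = attr(gt, "grid_shape"),
                      config = cohort$config,
                      voxel_specs = gt),
                 file.path(dir, "ground_truth.json"))
  invisible(dir)
}
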