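#' Write a run's events as a BIDS-style TSV
#'
#' Columns: onset, duration, trial_type, delay, iti, correct, plus
#' stim_onset as an extra column so stimulus-anchored windows survive the
#' round trip.
#'
#' @param design a `task_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  tt <- design$trials
  ev <- data.frame(
    onset = tt$onset,
    duration = (tt$stim_onset + design$stim_dur) - tt$onset,
    trial_type = tt$condition,
    delay = tt$delay,
    iti = tt$iti,
    correct = as.integer(tt$correct),
    stim_onset = tt$stim_onset
  )
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events TSV back into a trial table
#'
#' @param path events TSV written by [write_events_tsv()].
#' @return A data frame with onset, condition, delay, iti, correct,
#'   stim_onset.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a")
  data.frame(
    onset = ev$onset, condition = ev$trial_type, delay = ev$delay,
    iti = ev$iti, correct = as.logical(ev$correct),
    stim_onset = ev$stim_onset
  )
}

#' Write a voxel-by-time matrix as plain text
#'
#' Whitespace-delimited matrix, one voxel per row; TR, run id and units go
#' into a JSON sidecar next to the matrix file.
#'
#' @param ts a `voxel_ts`.
#' @param path output file path (sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_ts_matrix <- function(ts, path) {
  utils::write.table(ts$data, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(tr = ts$tr, run_id = ts$run_id, units = ts$units,
         task = ts$task %||% NA),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a voxel-by-time matrix written by [write_ts_matrix()]
#'
#' @param path matrix file path.
#' @return A `voxel_ts`.
#' @export
read_ts_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path))
  dimnames(data) <- NULL
  new_voxel_ts(data, tr = meta$tr, run_id = meta$run_id, units = meta$units,
               task = if (is.na(meta$task %||% NA)) NULL else meta$task)
}

#' Write a voxel time series as NIfTI
#'
#' Voxels are unraveled along the first spatial axis (V x 1 x 1 x T); the
#' TR is stored in the header's time dimension. Requires the RNifti package.
#'
#' @param ts a `voxel_ts`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(ts, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("write_bold_nifti requires the RNifti package")
  }
  arr <- aperm(array(ts$data, dim = c(nrow(ts$data), ncol(ts$data), 1L, 1L)),
               c(1, 3, 4, 2))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, ts$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI written by [write_bold_nifti()]
#'
#' @param path NIfTI file path.
#' @param run_id,units,task metadata not carried by the NIfTI header.
#' @return A `voxel_ts`.
#' @export
read_bold_nifti <- function(path, run_id = 1L, units = "raw", task = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("read_bold_nifti requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  tr <- RNifti::pixdim(img)[4]
  d <- dim(img)
  new_voxel_ts(matrix(img, nrow = d[1], ncol = d[4]), tr = tr,
               run_id = run_id, units = units, task = task)
}

#' Serialize ground truth to a JSON sidecar
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path JSON path written by [write_ground_truth_json()].
#' @return A `ground_truth`.
#' @export
read_ground_truth_json <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$n_voxels <- as.integer(gt$n_voxels)
  structure(gt, class = "ground_truth")
}
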