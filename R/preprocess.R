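#' Voxel-by-time BOLD container
#'
#' @param data numeric matrix, voxels x timepoints, no missing values.
#' @param tr repetition time in seconds.
#' @param run_id integer run identifier.
#' @param units `"raw"` scanner units or `"psc"` percent signal change.
#' @param task optional task tag carried through from the design.
#' @return A `voxel_ts` object.
#' @export
new_voxel_ts <- function(data, tr, run_id = 1L, units = c("raw", "psc"),
                         task = NULL) {
  units <- match.arg(units)
  data <- as.matrix(data)
  if (anyNA(data)) stopf("voxel_ts data must not contain missing values")
  if (tr <= 0) stopf("tr must be positive")
  structure(
    list(data = data, tr = tr, run_id = as.integer(run_id), units = units,
         task = task),
    class = "voxel_ts"
  )
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf(
    "<voxel_ts> %d voxels x %d timepoints, TR %.1f s, units %s (run %d)\n",
    nrow(x$data), ncol(x$data), x$tr, x$units, x$run_id
  ))
  invisible(x)
}

#' Convert a raw time series to percent signal change
#'
#' Divides each voxel's time course by its run mean:
#' `100 * (x - mean) / mean`, so every voxel has mean 0 in psc units.
#'
#' @param ts a `voxel_ts` with units `"raw"` and strictly positive voxel means.
#' @return A `voxel_ts` with units `"psc"`.
#' @export
to_percent_signal_change <- function(ts) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (ts$units != "raw") stopf("to_percent_signal_change expects raw units, got %s", ts$units)
  m <- rowMeans(ts$data)
  bad <- which(m <= 0)
  if (length(bad)) {
    stopf("degenerate voxel(s) with non-positive run mean: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  ts$data <- 100 * (ts$data - m) / m
  ts$units <- "psc"
  ts
}

# Discrete-cosine high-pass basis: DCT-II components k = 1..K have frequency
# k / (2 * N * TR); K spans all components strictly below the cutoff.
dct_basis <- function(n, tr, cutoff_hz) {
  k_max <- floor(2 * n * tr * cutoff_hz)
  if (k_max < 1) return(NULL)
  t_idx <- seq_len(n) - 0.5
  vapply(seq_len(k_max), function(k) cos(pi * k * t_idx / n), numeric(n))
}

# Orthonormal basis of the nuisance subspace removed by preprocessing:
# constant, linear trend, and sub-cutoff DCT components.
nuisance_basis <- function(n, tr, cutoff_hz) {
  qr.Q(qr(cbind(1, seq_len(n), dct_basis(n, tr, cutoff_hz))))
}

#' Linear detrend and temporal high-pass filter
#'
#' Removes, per voxel, the best-fit line and all discrete-cosine components
#' with frequency below `cutoff_hz` (a deterministic, edge-artifact-free
#' high-pass, as in standard fMRI GLM software). Output voxel means are ~0.
#'
#' @param ts a `voxel_ts` in psc units with at least 4 timepoints.
#' @param cutoff_hz high-pass cutoff in Hz, default 0.01.
#' @return Filtered `voxel_ts`.
#' @export
detrend_highpass <- function(ts, cutoff_hz = 0.01) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (ts$units != "psc") stopf("detrend_highpass expects psc units, got %s", ts$units)
  n <- ncol(ts$data)
  if (n < 4) stopf("need at least 4 timepoints, got %d", n)
  if (cutoff_hz >= 1 / (2 * ts$tr)) {
    stopf("cutoff %g Hz is at or above Nyquist (%g Hz)", cutoff_hz, 1 / (2 * ts$tr))
  }
  q <- nuisance_basis(n, ts$tr, cutoff_hz)
  ts$data <- ts$data - (ts$data %*% q) %*% t(q)
  ts
}

#' Drop voxels exceeding a psc magnitude threshold in any run
#'
#' A voxel is removed from all runs if its absolute psc exceeds
#' `threshold_psc` at any timepoint of any run (default 10, i.e. responses
#' larger than 10% signal change are treated as noise artifacts).
#'
#' @param ts_list list of `voxel_ts` in psc units sharing a voxel count.
#' @param threshold_psc threshold in percent signal change.
#' @return List with `ts_list` (filtered) and `kept` (original indices of
#'   the retained voxels).
#' @export
remove_noisy_voxels <- function(ts_list, threshold_psc = 10) {
  stopifnot(length(ts_list) >= 1)
  nv <- vapply(ts_list, function(t) nrow(t$data), integer(1))
  if (length(unique(nv)) != 1) stopf("runs disagree on voxel count")
  for (t in ts_list) {
    if (t$units != "psc") stopf("remove_noisy_voxels expects psc units")
  }
  bad <- Reduce(`|`, lapply(ts_list, function(t) {
    apply(abs(t$data) > threshold_psc, 1, any)
  }))
  kept <- which(!bad)
  if (!length(kept)) stopf("all voxels exceeded the %g psc threshold", threshold_psc)
  list(
    ts_list = lapply(ts_list, function(t) {
      t$data <- t$data[kept, , drop = FALSE]
      t
    }),
    kept = kept
  )
}

#' Concatenate runs in time
#'
#' Joins run time series along the time axis and merges their trial tables,
#' offsetting each run's onsets by the cumulative duration of the preceding
#' runs. Per-trial run ids are preserved for leave-one-run-out folds.
#'
#' @param ts_list list of `voxel_ts` with equal voxel counts and TR.
#' @param designs matching list of `task_design`.
#' @return List with `ts` (concatenated `voxel_ts`), `design` (merged
#'   `task_design` whose trials carry a `run_id` column), and
#'   `run_boundaries` (first timepoint index of each run, 1-based).
#' @export
concatenate_runs <- function(ts_list, designs) {
  stopifnot(length(ts_list) == length(designs), length(ts_list) >= 1)
  nv <- vapply(ts_list, function(t) nrow(t$data), integer(1))
  trs <- vapply(ts_list, function(t) t$tr, numeric(1))
  if (length(unique(nv)) != 1) stopf("runs disagree on voxel count")
  if (length(unique(trs)) != 1) stopf("runs disagree on TR")
  tr <- trs[1]
  n_tp <- vapply(ts_list, function(t) ncol(t$data), integer(1))
  offsets_tp <- cumsum(c(0L, n_tp[-length(n_tp)]))
  trials <- do.call(rbind, Map(function(d, off_tp) {
    tt <- d$trials
    off_s <- off_tp * tr
    tt$onset <- tt$onset + off_s
    tt$nominal_onset <- tt$nominal_onset + off_s
    tt$stim_onset <- tt$stim_onset + off_s
    tt$nominal_stim_onset <- tt$nominal_stim_onset + off_s
    tt$run_id <- d$run_id
    tt
  }, designs, as.list(offsets_tp)))
  ts <- new_voxel_ts(do.call(cbind, lapply(ts_list, `[[`, "data")),
    tr = tr, run_id = ts_list[[1]]$run_id, units = ts_list[[1]]$units,
    task = designs[[1]]$task
  )
  design <- new_task_design(
    run_id = designs[[1]]$run_id, task = designs[[1]]$task,
    trials = trials, tr = tr, n_timepoints = sum(n_tp),
    cue_mapping = designs[[1]]$cue_mapping
  )
  list(ts = ts, design = design, run_boundaries = offsets_tp + 1L)
}

#' Standard preprocessing chain for a set of runs
#'
#' Percent-signal-change conversion, linear detrend + 0.01 Hz high-pass per
#' run, removal of voxels exceeding 10 psc, then concatenation. (Head-motion
#' correction is a pass-through here: synthetic data contain no motion.)
#'
#' @param ts_list raw `voxel_ts` runs.
#' @param designs matching `task_design` list.
#' @param cutoff_hz high-pass cutoff, default 0.01.
#' @param threshold_psc noisy-voxel threshold, default 10.
#' @return As [concatenate_runs()], plus `kept` voxel indices.
#' @export
preprocess_runs <- function(ts_list, designs, cutoff_hz = 0.01,
                            threshold_psc = 10) {
  psc <- lapply(ts_list, function(t) {
    detrend_highpass(to_percent_signal_change(t), cutoff_hz)
  })
  cleaned <- remove_noisy_voxels(psc, threshold_psc)
  out <- concatenate_runs(cleaned$ts_list, designs)
  out$kept <- cleaned$kept
  out
}
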