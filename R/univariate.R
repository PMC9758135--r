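#' Window specification for amplitude extraction
#'
#' A window of FIR bins (TRs) counted from an anchor: bin 0 is the TR of the
#' anchor event itself, so "2 to 3 TRs after the trial onset" is
#' `window_spec("trial_onset", 2, 3)`. Stimulus-anchored windows are
#' translated to trial-anchored bins with `round(delay / tr)`.
#'
#' @param anchor `"trial_onset"` or `"stimulus_onset"`.
#' @param start_tr,end_tr inclusive bin offsets from the anchor,
#'   `0 <= start_tr <= end_tr`.
#' @return A `window_spec`.
#' @export
window_spec <- function(anchor = c("trial_onset", "stimulus_onset"),
                        start_tr = 2L, end_tr = 3L) {
  anchor <- match.arg(anchor)
  if (!(start_tr >= 0 && start_tr <= end_tr)) {
    stopf("need 0 <= start_tr <= end_tr, got [%d, %d]", start_tr, end_tr)
  }
  structure(list(anchor = anchor, start_tr = as.integer(start_tr),
                 end_tr = as.integer(end_tr)),
            class = "window_spec")
}

#' Mean FIR time course over conditions and voxels
#'
#' Averages the FIR betas of the requested labels over the selected voxels,
#' returning one mean psc value per bin.
#'
#' @param fit a `deconv_fit`.
#' @param labels regressor labels to average (must share a bin count).
#' @param voxels voxel indices; default all.
#' @return Numeric vector, one value per FIR bin.
#' @export
condition_timecourse <- function(fit, labels, voxels = NULL) {
  missing_l <- setdiff(labels, names(fit$betas))
  if (length(missing_l)) stopf("label(s) not in fit: %s", paste(missing_l, collapse = ", "))
  voxels <- voxels %||% seq_len(ncol(fit$betas[[1]]))
  if (!length(voxels)) stopf("empty voxel selection")
  bins <- vapply(fit$betas[labels], nrow, integer(1))
  if (length(unique(bins)) != 1) stopf("labels have differing bin counts")
  tcs <- vapply(labels, function(l) {
    rowMeans(fit$betas[[l]][, voxels, drop = FALSE])
  }, numeric(bins[1]))
  rowMeans(as.matrix(tcs))
}

#' Mean amplitude over a bin window
#'
#' Mean of the time-course bins `start_tr..end_tr` counted from an anchor
#' bin (`anchor_bin` = offset of the anchor within the time course, 0 for
#' trial onset).
#'
#' @param timecourse per-bin psc vector.
#' @param window a `window_spec`.
#' @param anchor_bin bin index (0-based) of the anchor event within the
#'   time course; e.g. `round(delay / tr)` for a stimulus anchor inside a
#'   trial-onset-locked FIR.
#' @return Scalar mean psc.
#' @export
window_amplitude <- function(timecourse, window, anchor_bin = 0L) {
  idx <- anchor_bin + (window$start_tr:window$end_tr) + 1L
  if (min(idx) < 1 || max(idx) > length(timecourse)) {
    stopf("window bins [%d, %d] outside time course of length %d",
          min(idx) - 1L, max(idx) - 1L, length(timecourse))
  }
  mean(timecourse[idx])
}

#' Baseline shift index
#'
#' Ratio of the peak preparatory response to the peak stimulus response,
#' from the condition-averaged long-delay FIR time courses: the maximum over
#' a preparation window (default bins 1-3 after trial onset) divided by the
#' maximum over a stimulus window (default bins 1-3 after stimulus onset,
#' located per delay via `round(delay / tr)` and averaged across the two
#' long delays). Larger values mean proportionally stronger anticipatory
#' activity.
#'
#' @param fit a `deconv_fit` from the attention FIR model.
#' @param voxels voxel indices to average over; default all.
#' @param prep_window,stim_window `window_spec`s; defaults bins 1-3 from
#'   trial onset and stimulus onset respectively.
#' @param long_delays the delays (s) whose regressors enter, default 6.1, 8.3.
#' @param conditions attended directions to average, default both.
#' @param tr repetition time, default from the FIR spec.
#' @return A `bsi_result`: `value`, `prep_peak`, `stim_peak`.
#' @export
compute_bsi <- function(fit, voxels = NULL,
                        prep_window = window_spec("trial_onset", 1L, 3L),
                        stim_window = window_spec("stimulus_onset", 1L, 3L),
                        long_delays = c(6.1, 8.3),
                        conditions = c("attend_left", "attend_right"),
                        tr = fit$spec$tr) {
  labels_for <- function(d) paste0(conditions, sprintf("_d%.1f", d))
  # preparation: average across conditions and long delays, peak in window
  all_labels <- unlist(lapply(long_delays, labels_for))
  tc_all <- condition_timecourse(fit, all_labels, voxels)
  prep_idx <- (prep_window$start_tr:prep_window$end_tr) + 1L
  prep_peak <- max(tc_all[prep_idx])
  # stimulus: anchor each delay's time course at its own stimulus bin, then
  # average the aligned windows across delays before taking the peak
  seg <- rowMeans(vapply(long_delays, function(d) {
    tc <- condition_timecourse(fit, labels_for(d), voxels)
    anchor <- round(d / tr)
    idx <- anchor + (stim_window$start_tr:stim_window$end_tr) + 1L
    if (max(idx) > length(tc)) stopf("stimulus window outside FIR range for delay %.1f", d)
    tc[idx]
  }, numeric(stim_window$end_tr - stim_window$start_tr + 1L)))
  stim_peak <- max(seg)
  if (stim_peak <= 0) {
    stopf("undefined BSI: non-positive stimulus peak (%.3g)", stim_peak)
  }
  structure(list(value = prep_peak / stim_peak, prep_peak = prep_peak,
                 stim_peak = stim_peak),
            class = "bsi_result")
}

#' Quadrant-based covert spatial-attention contrast
#'
#' Tests whether preparatory activity follows a spatial-attention strategy:
#' per subject, the mean preparatory amplitude over voxels in the quadrants
#' the hypothesis marks as attended for each trial's condition versus the
#' remaining quadrants, then a group paired t-test of attended vs unattended
#' means. Under `"upper_two"`, attend-left maps to UL and attend-right to
#' UR; under `"diagonal_four"`, attend-left maps to UL+LR and attend-right
#' to UR+LL.
#'
#' @param pattern_sets list (one per subject) of `trial_patterns` from the
#'   preparation period.
#' @param qmaps list (one per subject) of per-voxel quadrant labels
#'   (UL/UR/LL/LR), matching each pattern set's voxel columns.
#' @param hypothesis `"upper_two"` or `"diagonal_four"`.
#' @return List with per-subject `attended_mean` and `unattended_mean`
#'   vectors and `t` (a `t_test_result` from [paired_t()]).
#' @export
quadrant_contrast <- function(pattern_sets, qmaps,
                              hypothesis = c("upper_two", "diagonal_four")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(length(pattern_sets) == length(qmaps))
  per_subj <- vapply(seq_along(pattern_sets), function(s) {
    set <- pattern_sets[[s]]
    qmap <- qmaps[[s]]
    if (length(qmap) != ncol(set$patterns)) {
      stopf("subject %d: quadrant map length != voxel count", s)
    }
    if (length(unique(qmap)) < 4) stopf("subject %d: a quadrant has zero voxels", s)
    att <- un <- numeric(nrow(set$patterns))
    for (i in seq_len(nrow(set$patterns))) {
      qs <- attended_quadrants(set$labels[i], hypothesis)
      in_att <- qmap %in% qs
      att[i] <- mean(set$patterns[i, in_att])
      un[i] <- mean(set$patterns[i, !in_att])
    }
    c(mean(att), mean(un))
  }, numeric(2))
  attended <- per_subj[1, ]
  unattended <- per_subj[2, ]
  list(
    attended_mean = attended, unattended_mean = unattended,
    # identically-zero contrasts (e.g. perfectly uniform signal) make the
    # paired t degenerate; report no test rather than fail
    t = tryCatch(paired_t(attended, unattended), error = function(e) NULL)
  )
}
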