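#' FIR model specification
#'
#' An ordered set of regressor labels, each estimated with `n_bins` free
#' finite-impulse-response coefficients (one per TR after trial onset).
#'
#' @param labels character vector of unique regressor labels.
#' @param n_bins bins per regressor (recycled), >= 1.
#' @param tr repetition time in seconds.
#' @return A `fir_spec` object.
#' @export
fir_spec <- function(labels, n_bins, tr = task_timing$tr) {
  if (anyDuplicated(labels)) stopf("fir_spec labels must be unique")
  n_bins <- rep_len(as.integer(n_bins), length(labels))
  if (any(n_bins < 1)) stopf("n_bins must be >= 1")
  structure(list(labels = labels, n_bins = stats::setNames(n_bins, labels), tr = tr),
            class = "fir_spec")
}

#' Default attention-task FIR specification (10 regressors x 12 bins)
#'
#' Four regressors for long-delay (6.1, 8.3 s) correct trials (2 attended
#' directions x 2 delays), two for short-delay (1.7, 3.9 s) correct trials
#' (directions collapsed), and four for incorrect trials, one per delay
#' length, each with twelve FIR bins after trial onset.
#'
#' @param n_bins bins per regressor, default 12.
#' @param tr repetition time in seconds.
#' @return A `fir_spec` with 10 labels.
#' @export
attention_fir_spec <- function(n_bins = 12L, tr = task_timing$tr) {
  fir_spec(c(
    "attend_left_d6.1", "attend_left_d8.3",
    "attend_right_d6.1", "attend_right_d8.3",
    "short_d1.7", "short_d3.9",
    "incorrect_d1.7", "incorrect_d3.9", "incorrect_d6.1", "incorrect_d8.3"
  ), n_bins, tr)
}

#' Default baseline-task FIR specification (2 regressors x 8 bins)
#'
#' One regressor per motion direction, eight FIR bins each.
#'
#' @inheritParams attention_fir_spec
#' @return A `fir_spec` with 2 labels.
#' @export
baseline_fir_spec <- function(n_bins = 8L, tr = task_timing$tr) {
  fir_spec(c("left", "right"), n_bins, tr)
}

#' Map attention-task trials to the default 10-regressor labeling
#'
#' @param trials trial data frame with `condition`, `delay`, `correct`.
#' @return Character vector of labels matching [attention_fir_spec()].
#' @export
attention_trial_labels <- function(trials) {
  dl <- sprintf("d%.1f", trials$delay)
  ifelse(!trials$correct, paste0("incorrect_", dl),
    ifelse(trials$delay >= 6.1, paste0(trials$condition, "_", dl),
      paste0("short_", dl)
    )
  )
}

#' Build an FIR design matrix from a trial table
#'
#' For a trial whose onset falls in TR `k` (`k = round(onset / tr)`) with
#' label `L` of `B` bins, rows `k..k+B-1` receive a 1 in `L`'s bins `0..B-1`
#' (rows past the run end truncated). Overlapping trials superpose.
#'
#' @param design a `task_design` (possibly run-concatenated).
#' @param spec a `fir_spec`.
#' @param trial_labels label per trial; default uses
#'   [attention_trial_labels()] for attention designs and the condition for
#'   baseline designs.
#' @return A `fir_design`: indicator `matrix` (timepoints x total columns)
#'   and `column_map` data frame (label, bin).
#' @export
build_fir_design <- function(design, spec, trial_labels = NULL) {
  stopifnot(inherits(design, "task_design"), inherits(spec, "fir_spec"))
  trials <- design$trials
  if (is.null(trial_labels)) {
    trial_labels <- if (design$task == "attention") {
      attention_trial_labels(trials)
    } else {
      trials$condition
    }
  }
  unknown <- setdiff(unique(trial_labels), spec$labels)
  if (length(unknown)) {
    stopf("trial label(s) not in FIR spec: %s", paste(unknown, collapse = ", "))
  }
  n_tp <- design$n_timepoints
  column_map <- do.call(rbind, lapply(spec$labels, function(l) {
    data.frame(label = l, bin = seq_len(spec$n_bins[[l]]) - 1L)
  }))
  col_start <- cumsum(c(0L, unname(spec$n_bins[-length(spec$n_bins)])))
  names(col_start) <- spec$labels
  x <- matrix(0, nrow = n_tp, ncol = nrow(column_map))
  for (i in seq_len(nrow(trials))) {
    k <- round(trials$onset[i] / spec$tr)
    if (k >= n_tp) stopf("trial onset %.1f s beyond run end", trials$onset[i])
    l <- trial_labels[i]
    b <- spec$n_bins[[l]]
    rows <- (k + 1L):min(n_tp, k + b)
    cols <- col_start[[l]] + seq_along(rows)
    x[cbind(rows, cols)] <- x[cbind(rows, cols)] + 1
  }
  structure(list(matrix = x, column_map = column_map, spec = spec),
            class = "fir_design")
}

#' Apply the preprocessing filter to an FIR design matrix
#'
#' Projects each run segment of the design columns onto the residual space
#' of the nuisance basis (constant, linear trend, sub-cutoff DCT components)
#' that [detrend_highpass()] removed from the data. Filtering the design the
#' same way as the data keeps the FIR estimates unbiased: without it, the
#' run-mean and slow components absorbed from the event responses during
#' preprocessing would reappear as a downward shift of every beta.
#'
#' @param fir a `fir_design`.
#' @param run_boundaries first timepoint index of each run (1-based), e.g.
#'   from [concatenate_runs()]; a single run is `1`.
#' @param tr repetition time in seconds.
#' @param cutoff_hz high-pass cutoff matching the data filtering.
#' @return The `fir_design` with filtered (no longer binary) columns.
#' @export
filter_fir_design <- function(fir, run_boundaries, tr, cutoff_hz = 0.01) {
  x <- fir$matrix
  n <- nrow(x)
  bounds <- c(run_boundaries, n + 1L)
  for (i in seq_along(run_boundaries)) {
    rows <- bounds[i]:(bounds[i + 1L] - 1L)
    q <- nuisance_basis(length(rows), tr, cutoff_hz)
    x[rows, ] <- x[rows, , drop = FALSE] -
      q %*% crossprod(q, x[rows, , drop = FALSE])
  }
  fir$matrix <- x
  fir$filtered <- TRUE
  fir
}

# Moore-Penrose pseudoinverse via SVD (minimum-norm least squares when the
# design is rank-deficient, e.g. an all-zero regressor column).
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Fit an FIR deconvolution model
#'
#' Estimates per-condition, per-bin hemodynamic responses by multiplying the
#' pseudoinverse of the FIR design with the time series (the minimum-norm
#' least-squares solution; no intercept, since psc + detrended data are
#' mean-zero per run). All-zero design columns (e.g. no incorrect trials at
#' some delay) yield zero betas.
#'
#' @param fir a `fir_design`.
#' @param ts a `voxel_ts` in psc units with matching timepoint count.
#' @return A `deconv_fit`: `betas` (list label -> bins x voxels matrix),
#'   `r2` per voxel, `fitted` voxels x timepoints, and `beta_matrix`
#'   (columns x voxels).
#' @export
fit_fir <- function(fir, ts) {
  stopifnot(inherits(fir, "fir_design"), inherits(ts, "voxel_ts"))
  if (ts$units != "psc") stopf("fit_fir expects psc units, got %s", ts$units)
  x <- fir$matrix
  if (nrow(x) != ncol(ts$data)) {
    stopf("design rows (%d) != timepoints (%d)", nrow(x), ncol(ts$data))
  }
  b <- pinv(x) %*% t(ts$data) # columns x voxels
  fitted <- t(x %*% b)
  betas <- lapply(stats::setNames(fir$spec$labels, fir$spec$labels), function(l) {
    b[fir$column_map$label == l, , drop = FALSE]
  })
  fit <- structure(
    list(betas = betas, beta_matrix = b, fitted = fitted,
         column_map = fir$column_map, spec = fir$spec, r2 = NULL),
    class = "deconv_fit"
  )
  fit$r2 <- compute_r2(fit, ts)
  fit
}

#' Per-voxel variance explained by a deconvolution fit
#'
#' `r2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about each
#' voxel's mean. Zero-variance voxels get r2 = 0 with a warning.
#'
#' @param fit a `deconv_fit` produced from `ts`.
#' @param ts the `voxel_ts` the fit was estimated on.
#' @return Numeric vector, one r2 per voxel (all <= 1).
#' @export
compute_r2 <- function(fit, ts) {
  y <- ts$data
  ss_res <- rowSums((y - fit$fitted)^2)
  ss_tot <- rowSums((y - rowMeans(y))^2)
  zero <- ss_tot <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance voxel(s); r2 set to 0", sum(zero)))
  }
  r2 <- ifelse(zero, 0, 1 - ss_res / ss_tot)
  unname(r2)
}

#' Select the most task-responsive voxels by r2
#'
#' Indices of the `k` largest r2 values, in descending r2 order; ties broken
#' by ascending original index.
#'
#' @param r2 per-voxel r2 vector.
#' @param k number of voxels to keep, default 70.
#' @return Integer vector of length `k`.
#' @export
select_top_voxels <- function(r2, k = 70L) {
  if (k > length(r2)) {
    stopf("cannot select %d voxels from %d available", k, length(r2))
  }
  order(-r2, seq_along(r2))[seq_len(k)]
}
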