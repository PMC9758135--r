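#' Task timing constants
#'
#' Timing of the cue-delay-stimulus attention task and the single-feature
#' baseline task: 0.5 s cue, delays of 1.7/3.9/6.1/8.3 s with 10/10/40/40%
#' frequency, 0.5 s compound stimulus, inter-trial intervals of 4.4-8.8 s in
#' 2.2 s steps (attention) or 3.9-8.3 s (baseline), TR 2.2 s.
#'
#' @format A list of timing constants in seconds.
#' @export
task_timing <- list(
  tr = 2.2,
  cue_dur = 0.5,
  stim_dur = 0.5,
  delays = c(1.7, 3.9, 6.1, 8.3),
  delay_props = c(0.1, 0.1, 0.4, 0.4),
  attention_itis = c(4.4, 6.6, 8.8),
  baseline_itis = c(3.9, 6.1, 8.3)
)

snap_to_tr <- function(onset, tr) round(onset / tr) * tr

new_task_design <- function(run_id, task, trials, tr, n_timepoints,
                            cue_mapping = "mapping_A") {
  structure(
    list(
      run_id = run_id, task = task, trials = trials, tr = tr,
      n_timepoints = n_timepoints, cue_mapping = cue_mapping,
      cue_dur = task_timing$cue_dur, stim_dur = task_timing$stim_dur
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "<task_design> %s run %d: %d trials, TR %.1f s, %d timepoints (%s)\n",
    x$task, x$run_id, nrow(x$trials), x$tr, x$n_timepoints, x$cue_mapping
  ))
  invisible(x)
}

# Common onset bookkeeping: chain nominal onsets from per-trial durations,
# snap onsets and stimulus onsets to the TR grid, and size the run so the
# last trial's stimulus window and ITI fit inside n_timepoints * tr.
build_trial_table <- function(condition, delay, iti, cue_dur, stim_dur, tr,
                              tail_trs = 8L) {
  n <- length(condition)
  trial_dur <- cue_dur + delay + stim_dur + iti
  nominal_onset <- c(0, cumsum(trial_dur))[seq_len(n)]
  onset <- snap_to_tr(nominal_onset, tr)
  nominal_stim <- nominal_onset + cue_dur + delay
  stim_onset <- snap_to_tr(nominal_stim, tr)
  trials <- data.frame(
    onset = onset, nominal_onset = nominal_onset,
    condition = condition, delay = delay,
    stim_onset = stim_onset, nominal_stim_onset = nominal_stim,
    iti = iti, correct = NA,
    stringsAsFactors = FALSE
  )
  total <- sum(trial_dur)
  n_timepoints <- as.integer(ceiling(total / tr)) + tail_trs
  list(trials = trials, n_timepoints = n_timepoints)
}

#' Generate one attention-task run design
#'
#' Builds a run of the motion-based attention task: each trial is a 0.5 s
#' color cue, a delay of 1.7/3.9/6.1/8.3 s, a 0.5 s compound stimulus, and an
#' ITI drawn from {4.4, 6.6, 8.8} s. Delay counts are exact per run
#' (10/10/40/40% of trials), so 80% of trials are long-delay by construction;
#' the two attended directions are balanced and the trial order is shuffled.
#' Onsets are chained from the nominal trial durations and snapped to the TR
#' grid (both nominal and snapped onsets are recorded).
#'
#' @param run_id integer run identifier.
#' @param n_trials trials per run; must be even and divisible by 10 so the
#'   delay proportions are exact counts. Default 30.
#' @param tr repetition time in seconds, default 2.2.
#' @param seed integer seed for trial-order shuffling and ITI draws.
#' @param cue_mapping which color-direction mapping this run used
#'   (`"mapping_A"` or `"mapping_B"`); the mapping is reversed halfway
#'   through a session to decouple cue color from attended direction.
#' @return A `task_design` with a `trials` data frame (onset, condition,
#'   delay, stim_onset, iti, correct) and timing constants.
#' @examples
#' d <- make_attention_design(1, n_trials = 30, seed = 1)
#' table(d$trials$delay) # exactly 3/3/12/12
#' @export
make_attention_design <- function(run_id, n_trials = 30L, tr = task_timing$tr,
                                  seed = 1L, cue_mapping = "mapping_A") {
  if (n_trials < 10 || n_trials %% 10 != 0) {
    stopf("invalid design: n_trials (%d) must be divisible by 10 so delay proportions are exact", n_trials)
  }
  if (n_trials %% 2 != 0) {
    stopf("invalid design: n_trials (%d) must be even to balance conditions", n_trials)
  }
  stopifnot(tr > 0)
  with_seed(seed, {
    delay <- sample(rep(task_timing$delays, n_trials * task_timing$delay_props))
    condition <- sample(rep(c("attend_left", "attend_right"), n_trials / 2))
    iti <- sample(task_timing$attention_itis, n_trials, replace = TRUE)
    tab <- build_trial_table(condition, delay, iti,
      cue_dur = task_timing$cue_dur,
      stim_dur = task_timing$stim_dur, tr = tr
    )
    new_task_design(run_id, "attention", tab$trials, tr, tab$n_timepoints,
      cue_mapping = cue_mapping
    )
  })
}

#' Generate one baseline-task run design
#'
#' Single-feature baseline task: a lone moving dot field (leftward or
#' rightward) is shown for 0.5 s at trial onset, followed by an ITI from
#' {3.9, 6.1, 8.3} s. Conditions are balanced to within one trial. There is
#' no cue or delay; the trial onset is the stimulus onset.
#'
#' @inheritParams make_attention_design
#' @param n_trials trials per run, default 61 (so condition counts are 31/30).
#' @return A `task_design`; the `delay` column is `NA`.
#' @export
make_baseline_design <- function(run_id, n_trials = 61L, tr = task_timing$tr,
                                 seed = 1L) {
  if (n_trials < 2) stopf("invalid design: baseline run needs >= 2 trials, got %d", n_trials)
  stopifnot(tr > 0)
  with_seed(seed, {
    condition <- sample(rep(c("left", "right"), length.out = n_trials))
    iti <- sample(task_timing$baseline_itis, n_trials, replace = TRUE)
    # trial = 0.5 s stimulus + ITI; no cue, no delay
    tab <- build_trial_table(condition,
      delay = rep(0, n_trials), iti = iti,
      cue_dur = 0, stim_dur = task_timing$stim_dur, tr = tr
    )
    tab$trials$delay <- NA_real_
    new_task_design(run_id, "baseline", tab$trials, tr, tab$n_timepoints)
  })
}

#' Assign behavioral accuracy to a design
#'
#' Marks each trial correct with independent Bernoulli(`accuracy`) draws,
#' emulating the ~75% performance level a staircase would hold observers at.
#'
#' @param design a `task_design`.
#' @param accuracy probability correct, in (0, 1]. Default 0.75.
#' @param seed integer seed.
#' @return The design with the `correct` column filled in.
#' @export
simulate_behavior <- function(design, accuracy = 0.75, seed = 1L) {
  if (!(accuracy > 0 && accuracy <= 1)) {
    stopf("accuracy must be in (0, 1], got %g", accuracy)
  }
  with_seed(seed, {
    design$trials$correct <- stats::runif(nrow(design$trials)) < accuracy
  })
  design
}

#' Construct ground-truth voxel patterns for a simulated subject
#'
#' Builds the generative counterpart of the sensory-template question: a
#' sensory condition-difference axis `d_s` and a preparatory difference axis
#' `d_p` whose cosine similarity equals `overlap` exactly (Gram-Schmidt mix
#' of `d_s` with an orthogonal random direction). `overlap = 1` makes the
#' preparatory pattern a scaled copy of the sensory one (a sensory template);
#' `overlap = 0` makes them orthogonal (an abstract, non-sensory template).
#' Condition patterns are the common mean amplitude plus/minus half the
#' scaled difference axis, in percent-signal-change units at response peak.
#'
#' @param n_voxels number of voxels (>= 2).
#' @param overlap requested cosine similarity between the preparatory and
#'   sensory difference axes, in \[0, 1\].
#' @param mean_amplitude_prep,mean_amplitude_stim condition-common peak
#'   response amplitude (psc) of the preparatory and stimulus events.
#' @param pattern_amplitude_prep,pattern_amplitude_stim norm of the
#'   condition-difference axis (psc) for each period; 0 gives a null cohort
#'   with no decodable signal.
#' @param noise_sd i.i.d. Gaussian noise sd in psc units.
#' @param baseline_level raw-signal baseline the psc modulation rides on.
#' @param seed integer seed for the random axes.
#' @param quadrant_bias additional preparatory amplitude (psc) injected into
#'   the voxels of the quadrants a covertly shifted spatial-attention
#'   strategy would favor; 0 (default) means no spatial strategy.
#' @param quadrant_bias_scheme `"upper_two"` (attend_left -> UL) or
#'   `"diagonal_four"` (attend_left -> UL+LR).
#' @param incorrect_swap if `TRUE`, incorrect trials carry the opposite
#'   condition's pattern (misallocated attention); default `FALSE`.
#' @param hrf_params list passed to [hrf_double_gamma()].
#' @return A `ground_truth` object with per-condition `sensory_pattern` and
#'   `prep_pattern` vectors, the achieved `overlap`, a per-voxel
#'   `quadrant_map` (UL/UR/LL/LR in equal proportions), and the noise model.
#' @export
make_ground_truth <- function(n_voxels = 70L, overlap = 0,
                              mean_amplitude_prep = 0.3,
                              mean_amplitude_stim = 1.0,
                              pattern_amplitude_prep = 0.5,
                              pattern_amplitude_stim = 0.5,
                              noise_sd = 1.0, baseline_level = 1000,
                              seed = 1L,
                              quadrant_bias = 0,
                              quadrant_bias_scheme = c("upper_two", "diagonal_four"),
                              incorrect_swap = FALSE,
                              hrf_params = list(peak = 5, undershoot = 15, ratio = 6)) {
  if (overlap < 0 || overlap > 1) stopf("overlap must be in [0, 1], got %g", overlap)
  if (n_voxels < 2) stopf("n_voxels must be >= 2, got %d", n_voxels)
  quadrant_bias_scheme <- match.arg(quadrant_bias_scheme)
  with_seed(seed, {
    u_s <- stats::rnorm(n_voxels)
    u_s <- u_s / sqrt(sum(u_s^2))
    raw <- stats::rnorm(n_voxels)
    orth <- raw - sum(raw * u_s) * u_s
    orth <- orth / sqrt(sum(orth^2))
    u_p <- overlap * u_s + sqrt(1 - overlap^2) * orth
    quadrant_map <- sample(rep(c("UL", "UR", "LL", "LR"),
      length.out = n_voxels
    ))
  })
  half_s <- pattern_amplitude_stim * u_s / 2
  half_p <- pattern_amplitude_prep * u_p / 2
  structure(
    list(
      n_voxels = as.integer(n_voxels),
      overlap = overlap,
      sensory_pattern = list(
        attend_left = mean_amplitude_stim + half_s,
        attend_right = mean_amplitude_stim - half_s
      ),
      prep_pattern = list(
        attend_left = mean_amplitude_prep + half_p,
        attend_right = mean_amplitude_prep - half_p
      ),
      mean_amplitude_prep = mean_amplitude_prep,
      mean_amplitude_stim = mean_amplitude_stim,
      pattern_amplitude_prep = pattern_amplitude_prep,
      pattern_amplitude_stim = pattern_amplitude_stim,
      noise_sd = noise_sd, baseline_level = baseline_level,
      quadrant_map = quadrant_map,
      quadrant_bias = quadrant_bias,
      quadrant_bias_scheme = quadrant_bias_scheme,
      incorrect_swap = incorrect_swap,
      hrf_params = hrf_params
    ),
    class = "ground_truth"
  )
}

# Which quadrants a spatial-attention strategy would favor per condition.
attended_quadrants <- function(condition, scheme) {
  leftish <- condition %in% c("attend_left", "left")
  if (scheme == "upper_two") {
    if (leftish) "UL" else "UR"
  } else {
    if (leftish) c("UL", "LR") else c("UR", "LL")
  }
}

#' Render a run of synthetic BOLD data
#'
#' Turns a task design plus ground truth into a voxels x timepoints raw BOLD
#' matrix. Each attention trial contributes a preparatory event (boxcar from
#' cue onset to stimulus onset, i.e. sustained preparation; optionally a
#' 0.5 s transient at the cue) and a stimulus event (0.5 s boxcar at stimulus
#' onset); baseline-task trials contribute only the stimulus event. Events
#' are convolved with the double-gamma HRF on a fine time grid, each response
#' shape normalized to unit peak so amplitudes are peak psc, scaled by the
#' condition's per-voxel pattern, sampled at the TR grid, summed with i.i.d.
#' Gaussian noise (optionally AR(1)) and an optional linear drift, and
#' expressed as raw signal `baseline * (1 + psc / 100)`.
#'
#' @param design a `task_design` (with behavior simulated if the incorrect
#'   -trial pattern swap is enabled in `truth`).
#' @param truth a `ground_truth` with matching voxel count.
#' @param seed integer seed for the noise draw.
#' @param noise_sd,drift_slope,ar_rho noise sd (psc), linear drift slope
#'   (psc per TR), and AR(1) coefficient; defaults come from `truth` / 0.
#' @param prep_mode `"sustained"` (default) or `"transient"` preparatory
#'   time course.
#' @param dt fine-grid step (s) for HRF convolution.
#' @return A `voxel_ts` (units `"raw"`).
#' @export
render_bold <- function(design, truth, seed = 1L,
                        noise_sd = truth$noise_sd, drift_slope = 0,
                        ar_rho = 0, prep_mode = c("sustained", "transient"),
                        dt = 0.1) {
  prep_mode <- match.arg(prep_mode)
  v <- truth$n_voxels
  if (length(truth$sensory_pattern[[1]]) != v) {
    stopf("ground truth pattern length does not match n_voxels")
  }
  tr <- design$tr
  n_tp <- design$n_timepoints
  n_fine <- round(n_tp * tr / dt) + 1L
  trials <- design$trials

  conds <- if (design$task == "attention") {
    c("attend_left", "attend_right")
  } else {
    c("left", "right")
  }
  pattern_cond <- trials$condition
  if (isTRUE(truth$incorrect_swap) && !anyNA(trials$correct)) {
    flip <- !trials$correct
    pattern_cond[flip] <- setdiff(conds, NA)[3L - match(pattern_cond[flip], conds)]
  }

  stamp <- function(drive, shape, onset) {
    i0 <- round(onset / dt) + 1L
    idx <- i0:min(n_fine, i0 + length(shape) - 1L)
    drive[idx] <- drive[idx] + shape[seq_along(idx)]
    drive
  }

  stim_shape <- boxcar_response(design$stim_dur, dt, truth$hrf_params)
  # prep boxcar spans cue onset to (snapped) stimulus onset; cache per width
  shape_cache <- new.env(parent = emptyenv())
  prep_shape <- function(width) {
    key <- sprintf("%.4f", width)
    if (is.null(shape_cache[[key]])) {
      shape_cache[[key]] <- boxcar_response(width, dt, truth$hrf_params)
    }
    shape_cache[[key]]
  }

  zero <- rep(0, n_fine)
  prep_drive <- stats::setNames(list(zero, zero), conds)
  stim_drive <- stats::setNames(list(zero, zero), conds)
  for (i in seq_len(nrow(trials))) {
    cc <- pattern_cond[i]
    stim_drive[[cc]] <- stamp(stim_drive[[cc]], stim_shape, trials$stim_onset[i])
    if (design$task == "attention") {
      width <- if (prep_mode == "sustained") {
        max(trials$stim_onset[i] - trials$onset[i], dt)
      } else {
        design$cue_dur
      }
      prep_drive[[cc]] <- stamp(prep_drive[[cc]], prep_shape(width), trials$onset[i])
    }
  }

  tr_idx <- round((seq_len(n_tp) - 1L) * tr / dt) + 1L
  # map ground-truth pattern names onto baseline condition names
  pat_name <- function(cc) if (cc %in% c("left", "right")) paste0("attend_", cc) else cc
  psc <- matrix(0, nrow = v, ncol = n_tp)
  for (cc in conds) {
    sens <- truth$sensory_pattern[[pat_name(cc)]]
    psc <- psc + sens %o% stim_drive[[cc]][tr_idx]
    if (design$task == "attention") {
      prep <- truth$prep_pattern[[pat_name(cc)]]
      if (truth$quadrant_bias != 0) {
        qs <- attended_quadrants(cc, truth$quadrant_bias_scheme)
        prep <- prep + truth$quadrant_bias * (truth$quadrant_map %in% qs)
      }
      psc <- psc + prep %o% prep_drive[[cc]][tr_idx]
    }
  }

  if (noise_sd > 0 || drift_slope != 0) {
    with_seed(seed, {
      if (noise_sd > 0) {
        eps <- matrix(stats::rnorm(v * n_tp, sd = noise_sd), nrow = v)
        if (ar_rho != 0) {
          innov_sd <- sqrt(1 - ar_rho^2) # keep marginal sd = noise_sd
          eps <- t(apply(eps, 1, function(e) {
            as.numeric(stats::filter(e * innov_sd, ar_rho,
              method = "recursive", init = e[1]
            ))
          }))
        }
        psc <- psc + eps
      }
    })
    if (drift_slope != 0) {
      drift <- drift_slope * (seq_len(n_tp) - (n_tp + 1) / 2)
      psc <- sweep(psc, 2, drift, `+`)
    }
  }

  new_voxel_ts(
    data = truth$baseline_level * (1 + psc / 100),
    tr = tr, run_id = design$run_id, units = "raw", task = design$task
  )
}

#' Cohort specification
#'
#' Bundle of cohort-level simulation parameters: 12 subjects, 6 attention
#' runs of 30 trials, 2 baseline runs of 61 trials, 70 voxels, ~75%
#' behavioral accuracy — the study conditions the analyses assume.
#'
#' @param n_subjects,n_attention_runs,n_baseline_runs,n_voxels counts (>= 1).
#' @param n_attention_trials,n_baseline_trials trials per run.
#' @param behavioral_accuracy probability in (0, 1].
#' @param seed integer master seed; every subject, run, and noise draw is
#'   derived from it deterministically.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 12L, n_attention_runs = 6L,
                        n_baseline_runs = 2L, n_voxels = 70L,
                        n_attention_trials = 30L, n_baseline_trials = 61L,
                        behavioral_accuracy = 0.75, seed = 1L) {
  stopifnot(
    n_subjects >= 1, n_attention_runs >= 1, n_baseline_runs >= 1,
    n_voxels >= 1, behavioral_accuracy > 0, behavioral_accuracy <= 1
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_attention_runs = as.integer(n_attention_runs),
      n_baseline_runs = as.integer(n_baseline_runs),
      n_voxels = as.integer(n_voxels),
      n_attention_trials = as.integer(n_attention_trials),
      n_baseline_trials = as.integer(n_baseline_trials),
      behavioral_accuracy = behavioral_accuracy,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a cohort of simulated subjects
#'
#' Each subject receives an independent `ground_truth` (random axes, shared
#' `overlap`), `n_attention_runs` attention runs (cue-direction mapping
#' reversed halfway through the session) and `n_baseline_runs` baseline runs,
#' behavior at the configured accuracy, and rendered BOLD for every run.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param overlap cosine similarity between preparatory and sensory axes,
#'   shared across subjects.
#' @param ... further arguments to [make_ground_truth()] (amplitudes,
#'   noise, flags).
#' @return A list of subjects; each subject is a list with `id`, `truth`,
#'   `attention_designs`, `attention_ts`, `baseline_designs`, `baseline_ts`.
#' @export
generate_cohort <- function(spec = cohort_spec(), overlap = 0, ...) {
  lapply(seq_len(spec$n_subjects), function(s) {
    sseed <- child_seed(spec$seed, s)
    truth <- make_ground_truth(
      n_voxels = spec$n_voxels, overlap = overlap,
      seed = child_seed(sseed, 1L), ...
    )
    att <- lapply(seq_len(spec$n_attention_runs), function(r) {
      d <- make_attention_design(
        run_id = r, n_trials = spec$n_attention_trials,
        seed = child_seed(sseed, 10L + r),
        cue_mapping = if (r <= spec$n_attention_runs / 2) "mapping_A" else "mapping_B"
      )
      simulate_behavior(d, spec$behavioral_accuracy, seed = child_seed(sseed, 30L + r))
    })
    base <- lapply(seq_len(spec$n_baseline_runs), function(r) {
      d <- make_baseline_design(
        run_id = r, n_trials = spec$n_baseline_trials,
        seed = child_seed(sseed, 50L + r)
      )
      simulate_behavior(d, spec$behavioral_accuracy, seed = child_seed(sseed, 70L + r))
    })
    list(
      id = s, truth = truth,
      attention_designs = att,
      attention_ts = lapply(att, function(d) {
        render_bold(d, truth, seed = child_seed(sseed, 100L + d$run_id))
      }),
      baseline_designs = base,
      baseline_ts = lapply(base, function(d) {
        render_bold(d, truth, seed = child_seed(sseed, 200L + d$run_id))
      })
    )
  })
}
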