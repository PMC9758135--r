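# Shared fixture builders. Everything is generated in code at test time.

# A noiseless single subject with configurable truth, 6 attention runs.
make_test_subject <- function(n_voxels = 30, overlap = 0, noise_sd = 0,
                              accuracy = 1.0, n_runs = 6, seed = 1,
                              prep_mode = "sustained", ...) {
  gt <- make_ground_truth(n_voxels, overlap = overlap, noise_sd = noise_sd,
                          seed = seed, ...)
  designs <- lapply(seq_len(n_runs), function(r) {
    simulate_behavior(make_attention_design(r, seed = seed + r), accuracy,
                      seed = seed + 100 + r)
  })
  tss <- lapply(designs, function(d) {
    render_bold(d, gt, seed = seed + 200 + d$run_id, prep_mode = prep_mode)
  })
  list(truth = gt, designs = designs, tss = tss)
}

# A toy trial-pattern set with Gaussian classes: n_per_class trials per
# class per run, class means separated by delta along the first voxel.
make_toy_patterns <- function(n_voxels = 5, n_per_class = 6, n_runs = 3,
                              delta = 0, sd = 1, seed = 1,
                              labels = c("attend_left", "attend_right"),
                              period = "preparation") {
  set.seed(seed)
  n <- n_per_class * n_runs * 2
  lab <- rep(labels, each = n_per_class * n_runs)
  runs <- rep(rep(seq_len(n_runs), each = n_per_class), 2)
  x <- matrix(rnorm(n * n_voxels, sd = sd), nrow = n)
  x[lab == labels[2], 1] <- x[lab == labels[2], 1] + delta
  structure(
    list(patterns = x, labels = lab, run_ids = runs, period = period,
         normalized = FALSE),
    class = "trial_patterns"
  )
}

# Independent discrete-convolution oracle: the expected noiseless raw BOLD
# for one design/truth, built event-by-event with an explicit convolution
# loop (no calls into the package's rendering path beyond the HRF curve).
oracle_render <- function(design, truth, prep_mode = "sustained", dt = 0.1) {
  n_tp <- design$n_timepoints
  tr <- design$tr
  n_fine <- round(n_tp * tr / dt) + 1
  t_h <- seq(0, 32, by = dt)
  h <- do.call(hrf_double_gamma, c(list(t = t_h), truth$hrf_params))
  conv_box <- function(width) {
    drive <- rep(0, n_fine + length(h))
    drive[seq_len(max(1, round(width / dt)))] <- 1
    out <- rep(0, length(drive))
    for (j in seq_along(h)) { # direct convolution sum
      out[j:length(drive)] <- out[j:length(drive)] +
        h[j] * drive[seq_len(length(drive) - j + 1)]
    }
    out / max(out)
  }
  pat <- function(cc) if (cc %in% c("left", "right")) paste0("attend_", cc) else cc
  psc <- matrix(0, truth$n_voxels, n_fine)
  for (i in seq_len(nrow(design$trials))) {
    tt <- design$trials[i, ]
    stim <- conv_box(design$stim_dur)
    i0 <- round(tt$stim_onset / dt) + 1
    idx <- i0:min(n_fine, i0 + length(stim) - 1)
    psc[, idx] <- psc[, idx] +
      truth$sensory_pattern[[pat(tt$condition)]] %o% stim[seq_along(idx)]
    if (design$task == "attention") {
      w <- if (prep_mode == "sustained") max(tt$stim_onset - tt$onset, dt) else design$cue_dur
      prep <- conv_box(w)
      i0 <- round(tt$onset / dt) + 1
      idx <- i0:min(n_fine, i0 + length(prep) - 1)
      psc[, idx] <- psc[, idx] +
        truth$prep_pattern[[pat(tt$condition)]] %o% prep[seq_along(idx)]
    }
  }
  keep <- round((seq_len(n_tp) - 1) * tr / dt) + 1
  truth$baseline_level * (1 + psc[, keep, drop = FALSE] / 100)
}
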