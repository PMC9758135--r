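# A hand-built deconv_fit with known betas for the time-course operations.
fake_fit <- function(betas_by_label, tr = 2.2) {
  structure(
    list(betas = betas_by_label, spec = list(tr = tr,
                                             labels = names(betas_by_label))),
    class = "deconv_fit"
  )
}

test_that("condition time courses average betas over labels and voxels", {
  b1 <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2) # 3 bins x 2 voxels
  fit <- fake_fit(list(a = b1, b = -b1))
  expect_equal(condition_timecourse(fit, "a", voxels = 1), c(1, 2, 3))
  # antisymmetric labels cancel
  expect_equal(condition_timecourse(fit, c("a", "b")), rep(0, 3))
  # loop oracle on random betas
  set.seed(1)
  fit2 <- fake_fit(list(x = matrix(rnorm(40), 8, 5), y = matrix(rnorm(40), 8, 5)))
  vox <- c(2, 4)
  want <- sapply(1:8, function(bin) {
    mean(c(fit2$betas$x[bin, vox], fit2$betas$y[bin, vox]))
  })
  expect_equal(condition_timecourse(fit2, c("x", "y"), vox), want)
  expect_error(condition_timecourse(fit, "nope"), "not in fit")
  expect_error(condition_timecourse(fit, "a", voxels = integer(0)), "empty")
})

test_that("window amplitudes are anchored slice means", {
  tc <- c(0, 0, 4, 6, 0, 0)
  expect_equal(window_amplitude(tc, window_spec("trial_onset", 2, 3)), 5)
  expect_equal(window_amplitude(tc, window_spec("trial_onset", 3, 3)), 6)
  # anchor translation: the same window relative to an anchor at bin 2
  expect_equal(window_amplitude(tc, window_spec("stimulus_onset", 0, 1),
                                anchor_bin = 2), 5)
  expect_error(window_amplitude(tc, window_spec("trial_onset", 4, 9)),
               "outside")
  # slice-mean oracle on random series
  set.seed(2)
  for (i in 1:20) {
    tc <- rnorm(12)
    a <- sample(0:4, 1)
    b <- sample(a:6, 1)
    expect_equal(window_amplitude(tc, window_spec("trial_onset", a, b)),
                 mean(tc[(a + 1):(b + 1)]))
  }
  # linearity in the time course
  t1 <- rnorm(12); t2 <- rnorm(12)
  w <- window_spec("trial_onset", 1, 3)
  expect_equal(window_amplitude(2 * t1 + t2, w),
               2 * window_amplitude(t1, w) + window_amplitude(t2, w))
})

test_that("BSI equals the ratio of windowed peaks and scales correctly", {
  sub <- make_test_subject(n_voxels = 12, noise_sd = 0, seed = 21)
  pp <- preprocess_runs(sub$tss, sub$designs)
  fir <- filter_fir_design(build_fir_design(pp$design, attention_fir_spec()),
                           pp$run_boundaries, pp$ts$tr)
  fit <- fit_fir(fir, pp$ts)
  bsi <- compute_bsi(fit)
  expect_equal(bsi$value, bsi$prep_peak / bsi$stim_peak)
  # invariance to rescaling all betas by a positive constant
  fit2 <- fit
  fit2$betas <- lapply(fit$betas, function(b) 3.7 * b)
  expect_equal(compute_bsi(fit2)$value, bsi$value, tolerance = 1e-12)
})

test_that("BSI is ~0 when the truth has no preparatory signal", {
  sub <- make_test_subject(n_voxels = 12, noise_sd = 0, seed = 22,
                           mean_amplitude_prep = 0, pattern_amplitude_prep = 0)
  pp <- preprocess_runs(sub$tss, sub$designs)
  fir <- filter_fir_design(build_fir_design(pp$design, attention_fir_spec()),
                           pp$run_boundaries, pp$ts$tr)
  bsi <- compute_bsi(fit_fir(fir, pp$ts))
  expect_lt(abs(bsi$value), 0.02)
})

test_that("BSI recovers the preparatory/stimulus amplitude ratio", {
  # transient preparatory events peak inside the 1-3 TR window, so the
  # estimated ratio lands close to the embedded 0.3
  sub <- make_test_subject(n_voxels = 12, noise_sd = 0, seed = 23,
                           prep_mode = "transient")
  pp <- preprocess_runs(sub$tss, sub$designs)
  fir <- filter_fir_design(build_fir_design(pp$design, attention_fir_spec()),
                           pp$run_boundaries, pp$ts$tr)
  bsi_t <- compute_bsi(fit_fir(fir, pp$ts))
  expect_lt(abs(bsi_t$value - 0.3), 0.05)

  # sustained preparation: the BOLD response is still rising during the
  # preparation window, so compare against the convolution oracle's
  # prediction from the embedded shapes rather than the neural ratio
  sub_s <- make_test_subject(n_voxels = 12, noise_sd = 0, seed = 23)
  pp_s <- preprocess_runs(sub_s$tss, sub_s$designs)
  fir_s <- filter_fir_design(build_fir_design(pp_s$design, attention_fir_spec()),
                             pp_s$run_boundaries, pp_s$ts$tr)
  bsi_s <- compute_bsi(fit_fir(fir_s, pp_s$ts))
  # oracle: average the noiseless single-trial response of an isolated
  # long-delay trial and window it the same way
  oracle_ratio <- local({
    dt <- 0.1
    h <- hrf_double_gamma(seq(0, 32, by = dt))
    conv_unit <- function(width) {
      drive <- c(rep(1, round(width / dt)), rep(0, length(h)))
      y <- stats::convolve(drive, rev(h), type = "open")[seq_along(drive)]
      y / max(y)
    }
    tr <- 2.2
    vals <- sapply(c(6.1, 8.3), function(delay) {
      stim_onset <- round((0.5 + delay) / tr) * tr
      t_grid <- seq(0, 30, by = tr)
      prep <- 0.3 * conv_unit(stim_onset)[round(t_grid / dt) + 1]
      stim_shift <- round(stim_onset / dt)
      stim_tc <- c(rep(0, stim_shift), conv_unit(0.5))[round(t_grid / dt) + 1]
      stim_tc[is.na(stim_tc)] <- 0
      total <- prep + 1.0 * stim_tc
      sbin <- round(delay / tr)
      c(prep_win = max(total[2:4]), stim_win_vals = total[sbin + 2:4])
    })
    prep_peak <- max(rowMeans(vals)["prep_win"])
    stim_peak <- max(rowMeans(vals[2:4, , drop = FALSE]))
    unname(prep_peak / stim_peak)
  })
  expect_lt(abs(bsi_s$value - oracle_ratio), 0.05)
})

test_that("quadrant contrast is symmetric under no spatial bias and detects one", {
  # spatially uniform preparatory signal (no multivoxel pattern, only the
  # condition-common amplitudes): contrast exactly zero without a bias
  mk_set <- function(bias, seed, scheme = "upper_two") {
    gt <- make_ground_truth(16, overlap = 0, noise_sd = 0, seed = seed,
                            pattern_amplitude_prep = 0,
                            pattern_amplitude_stim = 0,
                            quadrant_bias = bias,
                            quadrant_bias_scheme = scheme)
    designs <- lapply(1:2, function(r) {
      simulate_behavior(make_attention_design(r, 10, seed = seed + r), 1, seed = r)
    })
    tss <- lapply(designs, function(d) render_bold(d, gt, seed = d$run_id))
    pp <- preprocess_runs(tss, designs)
    list(pat = extract_trial_patterns(pp$ts, pp$design, "preparation"),
         qmap = gt$quadrant_map)
  }
  flat <- lapply(1:6, function(s) mk_set(0, 100 + s))
  res0 <- quadrant_contrast(lapply(flat, `[[`, "pat"),
                            lapply(flat, `[[`, "qmap"), "upper_two")
  expect_lt(max(abs(res0$attended_mean - res0$unattended_mean)), 1e-6)

  biased <- lapply(1:6, function(s) mk_set(0.5, 100 + s))
  res1 <- quadrant_contrast(lapply(biased, `[[`, "pat"),
                            lapply(biased, `[[`, "qmap"), "upper_two")
  expect_true(all(res1$attended_mean > res1$unattended_mean))
  expect_lt(res1$t$p, 0.05)

  # under the diagonal hypothesis the attended and unattended quadrant sets
  # partition the voxels into two fixed halves, so swapping the condition
  # labels flips the contrast exactly
  diag_sets <- lapply(1:6, function(s) mk_set(0.5, 100 + s, "diagonal_four"))
  res_d <- quadrant_contrast(lapply(diag_sets, `[[`, "pat"),
                             lapply(diag_sets, `[[`, "qmap"), "diagonal_four")
  swapped <- quadrant_contrast(
    lapply(diag_sets, function(x) {
      p <- x$pat
      p$labels <- ifelse(p$labels == "attend_left", "attend_right", "attend_left")
      p
    }),
    lapply(diag_sets, `[[`, "qmap"), "diagonal_four"
  )
  expect_equal(swapped$attended_mean - swapped$unattended_mean,
               -(res_d$attended_mean - res_d$unattended_mean), tolerance = 1e-10)
})

test_that("quadrant contrast type-I error is near nominal under exchangeable noise", {
  # null-centred t: simulate label-exchangeable data directly at the
  # pattern level (the contrast only sees patterns, labels, quadrants)
  set.seed(31)
  n_rep <- 200
  rejections <- 0
  for (rep in seq_len(n_rep)) {
    sets <- lapply(1:6, function(s) {
      structure(
        list(patterns = matrix(rnorm(20 * 16), 20, 16),
             labels = sample(rep(c("attend_left", "attend_right"), 10)),
             run_ids = rep(1:2, 10), period = "preparation",
             normalized = FALSE),
        class = "trial_patterns"
      )
    })
    qmaps <- lapply(1:6, function(s) rep(c("UL", "UR", "LL", "LR"), 4))
    res <- quadrant_contrast(sets, qmaps, "upper_two")
    if (res$t$p < 0.05) rejections <- rejections + 1
  }
  # binomial 99% band around 5% of 200
  expect_gte(rejections, 1)
  expect_lte(rejections, 19)
})
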