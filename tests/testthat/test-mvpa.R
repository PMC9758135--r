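test_that("trial patterns are window means of the psc series", {
  sub <- make_test_subject(n_voxels = 6, noise_sd = 0.5, n_runs = 2, seed = 41,
                           accuracy = 0.8)
  pp <- preprocess_runs(sub$tss, sub$designs)
  pat <- extract_trial_patterns(pp$ts, pp$design, "preparation")
  trials <- pp$design$trials
  keep <- trials$delay %in% c(6.1, 8.3) & trials$correct
  expect_equal(nrow(pat$patterns), sum(keep))
  expect_setequal(unique(pat$labels), c("attend_left", "attend_right"))
  # slice-mean oracle for the first retained trial
  t1 <- trials[keep, ][1, ]
  k <- round(t1$onset / pp$ts$tr)
  want <- rowMeans(pp$ts$data[, k + (2:3) + 1])
  expect_equal(pat$patterns[1, ], want)
  # stimulus period anchors at the stimulus onset instead
  pat_s <- extract_trial_patterns(pp$ts, pp$design, "stimulus")
  ks <- round(t1$stim_onset / pp$ts$tr)
  expect_equal(pat_s$patterns[1, ], rowMeans(pp$ts$data[, ks + (2:3) + 1]))
})

test_that("attention-period extraction retains long correct trials only", {
  sub <- make_test_subject(n_voxels = 4, noise_sd = 0, n_runs = 6, seed = 42,
                           accuracy = 1.0)
  pp <- preprocess_runs(sub$tss, sub$designs)
  pat <- extract_trial_patterns(pp$ts, pp$design, "preparation")
  # accuracy 1, 80% long delays: 6 runs x 24 long trials
  expect_equal(nrow(pat$patterns), 6 * 24)
  all_tr <- extract_trial_patterns(pp$ts, pp$design, "preparation",
                                   long_only = FALSE)
  expect_equal(nrow(all_tr$patterns), 180)
})

test_that("retention matches the ~56 trials per condition the task yields", {
  # 6 runs x 30 trials, 80% long delays, ~78% accuracy: binomial mean
  # 144 * 0.778 / 2 = 56 retained trials per attended direction
  counts <- vapply(1:8, function(s) {
    spec <- cohort_spec(n_subjects = 1, n_voxels = 2, seed = 600 + s,
                        behavioral_accuracy = 0.778)
    sub <- generate_cohort(spec, overlap = 0,
                           pattern_amplitude_prep = 0,
                           pattern_amplitude_stim = 0)[[1]]
    pp <- preprocess_runs(sub$attention_ts, sub$attention_designs)
    pat <- extract_trial_patterns(pp$ts, pp$design, "preparation")
    nrow(pat$patterns) / 2
  }, numeric(1))
  expect_lt(abs(mean(counts) - 56), 6)
})

test_that("z-normalization centres and scales pooled columns", {
  set.seed(43)
  pat <- make_toy_patterns(n_voxels = 4, seed = 43)
  pat$patterns[, 4] <- 2.5 # constant column
  expect_message(z <- znorm_patterns(pat), "constant")
  expect_true(all(abs(colMeans(z$patterns)) < 1e-8))
  expect_equal(apply(z$patterns[, 1:3], 2, sd), rep(1, 3), tolerance = 1e-6)
  expect_true(all(z$patterns[, 4] == 0))
  # two-point column: symmetric around 0, scaled by the sample sd sqrt(2)
  two <- make_toy_patterns(n_voxels = 1, n_per_class = 1, n_runs = 1)
  two$patterns <- matrix(c(1, 3), 2, 1)
  expect_equal(as.vector(znorm_patterns(two)$patterns), c(-1, 1) / sqrt(2))
  # idempotence: z of z equals z
  zz <- z
  zz$normalized <- FALSE
  expect_equal(suppressMessages(znorm_patterns(zz))$patterns[, 1:3],
               z$patterns[, 1:3], tolerance = 1e-10)
  expect_error(znorm_patterns(z), "already normalized")
})

test_that("FLD matches the closed form with identity covariance", {
  # two clean clusters along voxel 1; at lambda -> 1 the shrunken
  # covariance is spherical so weights align with the mean difference
  x <- rbind(
    matrix(c(0, 0, 0.1, -0.1, 0, 0.1, -0.1, 0), 4, 2),
    matrix(c(2, 2, 2.1, 1.9, 0, 0.1, -0.1, 0), 4, 2)
  )
  set <- structure(
    list(patterns = x, labels = rep(c("a", "b"), each = 4),
         run_ids = rep(1:2, 4), period = "preparation", normalized = TRUE),
    class = "trial_patterns"
  )
  m <- fld_fit(set, lambda = 1)
  expect_gt(abs(m$weights[1]) / abs(m$weights[2]), 50)
  # boundary midway: x1 = 1 scores 0
  expect_equal(as.numeric(c(1, 0) %*% m$weights + m$bias), 0, tolerance = 1e-10)
  expect_equal(m$class_order, c("a", "b"))

  # identical class means: zero weights
  same <- set
  same$patterns <- rbind(x[1:4, ], x[1:4, ])
  m0 <- fld_fit(same, lambda = 0.5)
  expect_equal(m0$weights, c(0, 0))
  expect_equal(unique(fld_predict(m0, x)), "a") # ties go to the first class
})

test_that("FLD equals an independent linear-solve oracle on random toys", {
  set.seed(44)
  for (i in 1:15) {
    v <- sample(2:6, 1)
    n <- sample(c(8, 12, 16), 1)
    lam <- runif(1, 0.01, 0.9)
    x <- matrix(rnorm(n * v), n, v)
    labs <- rep(c("neg", "pos"), each = n / 2)
    set <- structure(
      list(patterns = x, labels = labs, run_ids = rep(1:2, n / 2),
           period = "stimulus", normalized = TRUE),
      class = "trial_patterns"
    )
    m <- fld_fit(set, lambda = lam)
    # oracle: explicit pooled covariance and solve
    mu_n <- colMeans(x[labs == "neg", , drop = FALSE])
    mu_p <- colMeans(x[labs == "pos", , drop = FALSE])
    xc <- rbind(
      sweep(x[labs == "neg", , drop = FALSE], 2, mu_n),
      sweep(x[labs == "pos", , drop = FALSE], 2, mu_p)
    )
    s <- t(xc) %*% xc / (n - 2)
    s_l <- (1 - lam) * s + lam * mean(diag(s)) * diag(v)
    w <- solve(s_l) %*% (mu_p - mu_n)
    expect_equal(m$weights, as.vector(w), tolerance = 1e-10)
    expect_equal(m$bias, as.numeric(-t(w) %*% (mu_p + mu_n) / 2),
                 tolerance = 1e-10)
  }
})

test_that("FLD prediction follows the decision rule and its symmetries", {
  m <- structure(
    list(weights = c(1, -2), bias = 0.5, lambda = 0.05,
         class_order = c("neg", "pos")),
    class = "fld_model"
  )
  x <- matrix(c(1, 0, 0, 0.25, -1, 1), 3, 2, byrow = TRUE)
  expect_equal(fld_predict(m, x), c("pos", "neg", "neg")) # score 0 -> neg
  # negating weights and bias flips every non-tied prediction
  m2 <- m
  m2$weights <- -m$weights
  m2$bias <- -m$bias
  p1 <- fld_predict(m, x[c(1, 3), ])
  p2 <- fld_predict(m2, x[c(1, 3), ])
  expect_true(all(p1 != p2))
  expect_error(fld_predict(m, matrix(0, 1, 3)), "width")

  # separable training data are classified perfectly at resubstitution
  sep <- make_toy_patterns(delta = 10, seed = 45)
  sepz <- znorm_patterns(sep)
  ms <- fld_fit(sepz)
  expect_equal(fld_predict(ms, sepz$patterns), sepz$labels)
})

test_that("leave-one-run-out folds each run exactly once", {
  pat <- make_toy_patterns(n_runs = 6, n_per_class = 5, delta = 10, seed = 46)
  res <- cv_loro(pat)
  expect_length(res$fold_accuracies, 6)
  expect_equal(res$n_trials, nrow(pat$patterns))
  expect_equal(res$accuracy, 1.0) # strongly separated classes
  expect_error(cv_loro(make_toy_patterns(n_runs = 1)), ">= 2 runs")
})

test_that("null patterns decode at chance and signal patterns above it", {
  accs <- vapply(1:10, function(s) {
    cv_loro(make_toy_patterns(n_voxels = 10, n_per_class = 10, n_runs = 4,
                              delta = 0, seed = 400 + s))$accuracy
  }, numeric(1))
  # binomial 99% band around 0.5 for 10 x 80 trials
  se <- sqrt(0.25 / (10 * 80))
  expect_lt(abs(mean(accs) - 0.5), 2.58 * se)

  strong <- cv_loro(make_toy_patterns(n_voxels = 5, delta = 5, seed = 47))
  expect_equal(strong$accuracy, 1.0)
})

test_that("cv_loro is invariant to shuffling trial order", {
  pat <- make_toy_patterns(n_voxels = 6, n_per_class = 6, n_runs = 3,
                           delta = 1, seed = 48)
  res1 <- cv_loro(pat)
  set.seed(49)
  perm <- sample(nrow(pat$patterns))
  pat2 <- pat
  pat2$patterns <- pat$patterns[perm, ]
  pat2$labels <- pat$labels[perm]
  pat2$run_ids <- pat$run_ids[perm]
  expect_equal(cv_loro(pat2)$accuracy, res1$accuracy)
})

test_that("cross-task decoding maps labels and detects shared axes", {
  train <- make_toy_patterns(delta = 8, seed = 50, labels = c("left", "right"),
                             period = "baseline")
  # resubstitution on the training set itself
  self <- cross_decode(train, train)
  expect_equal(self$accuracy, 1.0)
  # attention-task labels map through the left/right correspondence
  test <- make_toy_patterns(delta = 8, seed = 51,
                            labels = c("attend_left", "attend_right"))
  res <- cross_decode(train, test)
  expect_gt(res$accuracy, 0.9)
  # orthogonal generative axes: generalization falls to chance
  orth <- make_toy_patterns(delta = 0, seed = 52,
                            labels = c("attend_left", "attend_right"))
  res0 <- cross_decode(train, orth)
  expect_lt(abs(res0$accuracy - 0.5), 0.2)
  bad <- train
  bad$labels <- rep(c("up", "down"), length.out = length(bad$labels))
  expect_error(cross_decode(bad, test), "correspondence")
})

test_that("cross-task generalization tracks the ground-truth overlap", {
  run_overlap <- function(ov) {
    spec <- cohort_spec(n_subjects = 1, n_voxels = 24, seed = 77)
    sub <- generate_cohort(spec, overlap = ov, pattern_amplitude_prep = 2,
                           pattern_amplitude_stim = 2, noise_sd = 0.5)[[1]]
    att <- preprocess_runs(sub$attention_ts, sub$attention_designs)
    base <- preprocess_runs(sub$baseline_ts, sub$baseline_designs)
    prep <- extract_trial_patterns(att$ts, att$design, "preparation")
    stim <- extract_trial_patterns(att$ts, att$design, "stimulus")
    bl <- extract_trial_patterns(base$ts, base$design, "baseline")
    c(prep = cross_decode(bl, prep)$accuracy,
      stim = cross_decode(bl, stim)$accuracy)
  }
  r0 <- run_overlap(0)
  r1 <- run_overlap(1)
  expect_lt(abs(r0["prep"] - 0.5), 0.2) # orthogonal axes: chance
  expect_gt(r0["stim"], 0.9) # sensory axis always generalizes
  expect_gt(r1["stim"], 0.9)
  expect_gt(r1["prep"], r0["prep"] + 0.1) # aligned axes: well above chance
})

test_that("permutation nulls are reproducible, chance-centred, right-sized", {
  pat <- make_toy_patterns(n_voxels = 6, n_per_class = 8, n_runs = 4,
                           delta = 2, seed = 53)
  n1 <- subject_permutation_null(pat, scheme = "loro", n_perm = 60, seed = 9)
  n2 <- subject_permutation_null(pat, scheme = "loro", n_perm = 60, seed = 9)
  expect_identical(n1, n2)
  expect_length(n1, 60)
  expect_lt(abs(mean(n1) - 0.5), 0.05)
  # cross scheme
  train <- make_toy_patterns(delta = 5, seed = 54, labels = c("left", "right"))
  test <- make_toy_patterns(delta = 5, seed = 55,
                            labels = c("attend_left", "attend_right"))
  nc <- subject_permutation_null(train, test, scheme = "cross", n_perm = 40,
                                 seed = 10)
  expect_length(nc, 40)
  expect_lt(abs(mean(nc) - 0.5), 0.08)
})

test_that("group permutation test matches an enumeration oracle", {
  # observed above every null value
  nulls <- matrix(0.4, 3, 10)
  g <- group_permutation_test(c(0.9, 0.8, 0.85), nulls)
  expect_equal(g$p_value, 1 / 11)
  expect_true(g$significant)
  # observed below every null value
  g2 <- group_permutation_test(c(0.1, 0.2, 0.15), matrix(0.6, 3, 10))
  expect_equal(g2$p_value, 1.0)
  expect_false(g2$significant)
  # random small case: nearest-rank threshold and +1-corrected p recomputed
  # by brute force
  set.seed(56)
  for (i in 1:10) {
    obs <- runif(3, 0.4, 0.8)
    nulls <- matrix(runif(30, 0.3, 0.7), 3, 10)
    g3 <- group_permutation_test(obs, nulls)
    gn <- colMeans(nulls)
    expect_equal(g3$null, gn)
    expect_equal(g3$threshold, sort(gn)[ceiling(0.95 * 10)])
    expect_equal(g3$p_value, (1 + sum(gn >= mean(obs))) / 11)
  }
  expect_error(group_permutation_test(c(0.5, 0.5), matrix(0.5, 3, 10)),
               "subjects")
})
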