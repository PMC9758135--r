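#' Pipeline configuration
#'
#' Gathers every tunable of the end-to-end experiment: the cohort
#' specification, the ground-truth overlap and amplitudes, window and FIR
#' settings, FLD shrinkage, permutation count, and FDR level.
#'
#' @param cohort a [cohort_spec()].
#' @param overlap preparatory/sensory axis cosine similarity in \[0, 1\].
#' @param truth_args list of extra arguments to [make_ground_truth()]
#'   (amplitudes, noise, flags).
#' @param window MVPA extraction window, default bins 2-3 after the anchor.
#' @param n_top_voxels voxels kept by r2 selection (capped at the number
#'   surviving the noisy-voxel filter), default 70.
#' @param lambda FLD shrinkage, default 0.05.
#' @param norm_scope `"fold"` (leakage-free, default) or `"pooled"`
#'   (whole-set z-normalization before fold splitting).
#' @param n_perm permutations per subject and scheme, default 1000.
#' @param alpha group permutation percentile level, default 0.05.
#' @param q FDR level across schemes, default 0.05.
#' @param cutoff_hz,threshold_psc preprocessing settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), overlap = 0,
                            truth_args = list(),
                            window = window_spec(start_tr = 2L, end_tr = 3L),
                            n_top_voxels = 70L, lambda = 0.05,
                            norm_scope = "fold",
                            n_perm = 1000L, alpha = 0.05, q = 0.05,
                            cutoff_hz = 0.01, threshold_psc = 10) {
  structure(
    list(cohort = cohort, overlap = overlap, truth_args = truth_args,
         window = window, n_top_voxels = as.integer(n_top_voxels),
         lambda = lambda, norm_scope = norm_scope,
         n_perm = as.integer(n_perm), alpha = alpha, q = q,
         cutoff_hz = cutoff_hz, threshold_psc = threshold_psc),
    class = "pipeline_config"
  )
}

# Decoding schemes evaluated for every subject: within-task leave-one-run-
# out decoding per period, cross-task generalization from the baseline task
# to both attention periods, and baseline-task decoding itself.
decoding_schemes <- data.frame(
  scheme = c("loro", "loro", "cross", "cross", "loro"),
  period = c("preparation", "stimulus", "preparation", "stimulus", "baseline"),
  stringsAsFactors = FALSE
)

#' Run the full analysis for one simulated subject
#'
#' Preprocesses and concatenates the subject's attention and baseline runs,
#' fits the attention FIR model, selects the top-r2 voxels, extracts trial
#' patterns for the preparation, stimulus, and baseline periods, and runs
#' every decoding scheme with its permutation null. Also computes the
#' subject's baseline shift index.
#'
#' @param subject one element of a [generate_cohort()] list.
#' @param config a [pipeline_config()].
#' @param perm_seed seed for this subject's permutation streams.
#' @return List with `decoding` (data frame: scheme, period, accuracy,
#'   n_trials), `nulls` (list of per-scheme null vectors), `bsi`
#'   (`bsi_result`), `patterns` (the three `trial_patterns`), `n_voxels`
#'   used, and `behavior` (proportion correct).
#' @export
run_subject <- function(subject, config, perm_seed = 1L) {
  att <- preprocess_runs(subject$attention_ts, subject$attention_designs,
                         config$cutoff_hz, config$threshold_psc)
  base <- preprocess_runs(subject$baseline_ts, subject$baseline_designs,
                          config$cutoff_hz, config$threshold_psc)
  # voxel selection: noisy-voxel filters may disagree across task sets, so
  # work in the intersection of surviving voxels
  common <- intersect(att$kept, base$kept)
  att_idx <- match(common, att$kept)
  base_idx <- match(common, base$kept)

  fir <- build_fir_design(att$design, attention_fir_spec(tr = att$ts$tr))
  fir <- filter_fir_design(fir, att$run_boundaries, att$ts$tr, config$cutoff_hz)
  fit <- fit_fir(fir, att$ts)
  k <- min(config$n_top_voxels, length(att_idx))
  top <- select_top_voxels(fit$r2[att_idx], k) # ranks within common voxels
  vox_att <- att_idx[top]
  vox_base <- base_idx[top]

  patterns <- list(
    preparation = extract_trial_patterns(att$ts, att$design, "preparation",
                                         config$window, voxels = vox_att),
    stimulus = extract_trial_patterns(att$ts, att$design, "stimulus",
                                      config$window, voxels = vox_att),
    baseline = extract_trial_patterns(base$ts, base$design, "baseline",
                                      config$window, voxels = vox_base)
  )

  res <- vector("list", nrow(decoding_schemes))
  nulls <- vector("list", nrow(decoding_schemes))
  for (i in seq_len(nrow(decoding_schemes))) {
    sch <- decoding_schemes$scheme[i]
    per <- decoding_schemes$period[i]
    if (sch == "loro") {
      r <- cv_loro(patterns[[per]], config$lambda, config$norm_scope)
      nulls[[i]] <- subject_permutation_null(
        patterns[[per]], scheme = "loro", n_perm = config$n_perm,
        seed = child_seed(perm_seed, i), lambda = config$lambda,
        norm_scope = config$norm_scope
      )
    } else {
      r <- cross_decode(patterns$baseline, patterns[[per]], config$lambda)
      nulls[[i]] <- subject_permutation_null(
        patterns$baseline, patterns[[per]], scheme = "cross",
        n_perm = config$n_perm, seed = child_seed(perm_seed, i),
        lambda = config$lambda
      )
    }
    res[[i]] <- data.frame(
      scheme = sch, period = per, accuracy = r$accuracy,
      n_trials = r$n_trials, stringsAsFactors = FALSE
    )
  }

  bsi <- tryCatch(compute_bsi(fit, voxels = vox_att),
                  error = function(e) {
                    message("BSI undefined for subject: ", conditionMessage(e))
                    NULL
                  })
  behavior <- mean(unlist(lapply(subject$attention_designs,
                                 function(d) d$trials$correct)))
  list(
    decoding = do.call(rbind, res), nulls = nulls, bsi = bsi,
    patterns = patterns, n_voxels = k, behavior = behavior
  )
}

#' Run the full simulated experiment
#'
#' Generates a cohort, runs every subject through preprocessing, FIR
#' fitting, voxel selection, pattern extraction, all decoding schemes and
#' their permutation nulls, then assembles group-level results: the group
#' permutation test per scheme (with FDR-adjusted p-values across schemes),
#' the baseline-shift-index one-sample t-test, the covert-spatial-attention
#' quadrant contrast, and a behavioral summary.
#'
#' @param config a [pipeline_config()].
#' @return A results bundle (list):
#'   \describe{
#'     \item{group_decoding}{data frame: scheme, period, group accuracy,
#'       permutation threshold, p, FDR-adjusted p, significance.}
#'     \item{subject_decoding}{per-subject accuracy table.}
#'     \item{bsi}{per-subject BSI values plus the group one-sample t.}
#'     \item{quadrant}{quadrant-contrast results for both hypotheses.}
#'     \item{behavior}{per-subject proportion correct.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
run_experiment <- function(config = pipeline_config()) {
  cohort <- do.call(
    generate_cohort,
    c(list(spec = config$cohort, overlap = config$overlap), config$truth_args)
  )
  subj <- lapply(seq_along(cohort), function(s) {
    run_subject(cohort[[s]], config,
                perm_seed = child_seed(config$cohort$seed, 9000L + s))
  })

  subject_decoding <- do.call(rbind, lapply(seq_along(subj), function(s) {
    cbind(subject = s, subj[[s]]$decoding)
  }))

  group_rows <- lapply(seq_len(nrow(decoding_schemes)), function(i) {
    observed <- vapply(subj, function(x) x$decoding$accuracy[i], numeric(1))
    nulls <- do.call(rbind, lapply(subj, function(x) x$nulls[[i]]))
    g <- group_permutation_test(observed, nulls, config$alpha)
    data.frame(
      scheme = decoding_schemes$scheme[i],
      period = decoding_schemes$period[i],
      accuracy = g$observed, threshold = g$threshold, p = g$p_value,
      stringsAsFactors = FALSE
    )
  })
  group_decoding <- do.call(rbind, group_rows)
  fdr <- bh_fdr(group_decoding$p, config$q)
  group_decoding$p_fdr <- fdr$p_adjusted
  group_decoding$significant <- fdr$rejected

  bsi_values <- vapply(subj, function(x) {
    if (is.null(x$bsi)) NA_real_ else x$bsi$value
  }, numeric(1))
  bsi_test <- if (sum(!is.na(bsi_values)) >= 2) {
    one_sample_t(bsi_values[!is.na(bsi_values)], 0)
  } else {
    NULL
  }

  quadrant <- lapply(c(upper_two = "upper_two", diagonal_four = "diagonal_four"),
    function(h) {
      quadrant_contrast(
        lapply(subj, function(x) x$patterns$preparation),
        lapply(cohort, function(s) s$truth$quadrant_map),
        hypothesis = h
      )
    }
  )

  list(
    group_decoding = group_decoding,
    subject_decoding = subject_decoding,
    bsi = list(values = bsi_values, test = bsi_test),
    quadrant = quadrant,
    behavior = vapply(subj, `[[`, numeric(1), "behavior"),
    config = config
  )
}

#' Write a results bundle to tidy TSV tables and a text summary
#'
#' @param bundle result of [run_experiment()].
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
summarise_experiment <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(bundle$group_decoding, "group_decoding.tsv")
  wt(bundle$subject_decoding, "subject_decoding.tsv")
  wt(data.frame(subject = seq_along(bundle$bsi$values),
                bsi = bundle$bsi$values), "bsi.tsv")
  wt(data.frame(subject = seq_along(bundle$behavior),
                accuracy = bundle$behavior), "behavior.tsv")

  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Simulated preparatory-attention experiment (overlap = %g, %d subjects)",
    bundle$config$overlap, bundle$config$cohort$n_subjects)
  w("Behavioral accuracy: mean %.3f", mean(bundle$behavior))
  w("")
  if (nrow(bundle$group_decoding)) {
    w("Group decoding (chance 0.5, %d permutations):", bundle$config$n_perm)
    for (i in seq_len(nrow(bundle$group_decoding))) {
      g <- bundle$group_decoding[i, ]
      w("  %-5s %-11s accuracy %.3f (threshold %.3f, p = %.4g, p_fdr = %.4g)%s",
        g$scheme, g$period, g$accuracy, g$threshold, g$p, g$p_fdr,
        if (g$significant) " *" else "")
    }
  } else {
    w("No decoding results.")
  }
  w("")
  if (!is.null(bundle$bsi$test)) {
    w("Baseline shift index: mean %.3f, t(%g) = %.2f, p = %.4g",
      mean(bundle$bsi$values, na.rm = TRUE), bundle$bsi$test$df,
      bundle$bsi$test$t, bundle$bsi$test$p)
  }
  for (h in names(bundle$quadrant)) {
    qt <- bundle$quadrant[[h]]$t
    w("Quadrant contrast (%s): t(%g) = %.2f, p = %.4g",
      h, qt$df, qt$t, qt$p)
  }
  paths <- c(paths, summary_path)
  invisible(paths)
}
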