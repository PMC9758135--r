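#!/usr/bin/env Rscript
# Final report: combine the two cohorts' decoding tables, test whether
# cross-task generalization differs between the preparation and stimulus
# periods (two-way repeated-measures ANOVA on subject accuracies), and
# attach within-subject error bars.

library(prepdecode)

out_dir <- "results/report"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

bundles <- lapply(c(0, 1), function(ov) {
  f <- file.path("scratch", sprintf("bundle_overlap%d.rds", ov))
  if (!file.exists(f)) stop("run analysis/03_decode.R first (missing ", f, ")")
  readRDS(f)
})

combined <- do.call(rbind, lapply(seq_along(bundles), function(i) {
  cbind(overlap = c(0, 1)[i], bundles[[i]]$group_decoding)
}))
write.table(combined, file.path(out_dir, "group_decoding_combined.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Does cross-task generalization differ between periods? Subjects x
# period x cohort on the cross-decoding accuracies.
cross_acc <- function(bundle, period) {
  s <- bundle$subject_decoding
  s$accuracy[s$scheme == "cross" & s$period == period]
}
arr <- array(0, dim = c(12, 2, 2),
             dimnames = list(NULL, c("preparation", "stimulus"), c("ov0", "ov1")))
for (i in 1:2) {
  arr[, "preparation", i] <- cross_acc(bundles[[i]], "preparation")
  arr[, "stimulus", i] <- cross_acc(bundles[[i]], "stimulus")
}
an <- rm_anova_twoway(arr)
message("Two-way RM-ANOVA on cross-task accuracy (period x cohort):")
print(an)
write.table(an$effects, file.path(out_dir, "cross_anova.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Period effect within each cohort, with Bayes factors
for (i in 1:2) {
  tt <- paired_t(arr[, "stimulus", i], arr[, "preparation", i])
  bf <- jzs_bf01_paired(arr[, "stimulus", i], arr[, "preparation", i])
  message(sprintf(
    "  overlap %d: stimulus vs preparation cross-decoding t(%d) = %.2f, p = %.2g, BF01 = %.3g",
    c(0, 1)[i], tt$df, tt$t, tt$p, bf$bf01))
}

# Cousineau within-subject error bars for the four cross-decoding cells
sem <- cousineau_sem(cbind(arr[, , 1], arr[, , 2]))
write.table(
  data.frame(cell = c("ov0_prep", "ov0_stim", "ov1_prep", "ov1_stim"),
             mean = c(colMeans(arr[, , 1]), colMeans(arr[, , 2])),
             sem = sem),
  file.path(out_dir, "cross_cells.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
message("Wrote ", out_dir)
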