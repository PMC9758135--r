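Package: prepdecode
Title: Simulation and Decoding of Preparatory Feature-Based Attention in fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A parameter-recovery pipeline for multivoxel analyses of
    preparatory (pre-stimulus) feature-based attention. Generates synthetic
    multi-voxel BOLD time series for a cue-delay-stimulus attention task and
    a single-feature baseline task, with the overlap between preparatory and
    sensory activity patterns as a known ground-truth parameter. Implements
    percent-signal-change preprocessing, finite-impulse-response (FIR)
    deconvolution by pseudoinverse regression, baseline-shift-index
    univariate statistics, Fisher linear discriminant decoding with
    leave-one-run-out cross-validation and cross-task generalization, and
    group-level permutation inference, plus the accompanying inferential
    utilities (paired and one-sample t tests, repeated-measures ANOVA,
    JZS Bayes factors, Benjamini-Hochberg FDR, Cousineau within-subject
    error bars).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
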