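as_t_result <- function(ht, mean_diff) {
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_diff = mean_diff),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g (mean diff %.4g)\n",
              x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test on per-subject value pairs.
#'
#' @param a,b numeric vectors of equal length (>= 2 pairs).
#' @return A `t_test_result`: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) stopf("degenerate paired t: zero-variance differences")
  as_t_result(stats::t.test(a, b, paired = TRUE), mean(d))
}

#' One-sample t-test
#'
#' Two-sided one-sample t-test of `x` against `mu0`.
#'
#' @param x numeric vector (>= 2 values, non-zero variance).
#' @param mu0 null value, default 0.
#' @return A `t_test_result`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) stopf("degenerate one-sample t: zero variance")
  as_t_result(stats::t.test(x, mu = mu0), mean(x) - mu0)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a complete subjects x levels matrix:
#' `F = MS_levels / MS_(levels x subjects)` with df `(L - 1, (L - 1)(S - 1))`.
#' No sphericity correction is applied by default; `gg = TRUE` applies the
#' Greenhouse-Geisser correction to the df and p-value.
#'
#' @param data numeric matrix, subjects in rows, levels in columns, no
#'   missing cells.
#' @param gg apply Greenhouse-Geisser correction, default `FALSE`.
#' @return An `anova_result` with one effect row (name, F, df_num, df_den, p).
#' @export
rm_anova_oneway <- function(data, gg = FALSE) {
  data <- as.matrix(data)
  if (anyNA(data)) stopf("balanced-design error: missing cells")
  s <- nrow(data)
  l <- ncol(data)
  stopifnot(s >= 2, l >= 2)
  df <- data.frame(
    y = as.vector(data),
    subject = factor(rep(seq_len(s), times = l)),
    level = factor(rep(seq_len(l), each = s))
  )
  fit <- stats::aov(y ~ level + Error(subject / level), data = df)
  tab <- summary(fit)[["Error: subject:level"]][[1]]
  f_val <- tab["level", "F value"]
  df1 <- tab["level", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["level", "Pr(>F)"]
  # degenerate case: an effect sum of squares of (numerically) zero makes
  # the F ratio 0/0; report a null effect instead of rounding noise
  if (tab["level", "Sum Sq"] <= 1e-12 * max(sum((df$y - mean(df$y))^2), 1e-20 * (1 + sum(df$y^2)))) {
    f_val <- 0
    p <- 1
  }
  if (gg) {
    eps <- gg_epsilon(data)
    p <- stats::pf(f_val, df1 * eps, df2 * eps, lower.tail = FALSE)
    df1 <- df1 * eps
    df2 <- df2 * eps
  }
  structure(
    list(effects = data.frame(
      name = "level", F = f_val, df_num = df1, df_den = df2, p = p,
      stringsAsFactors = FALSE
    )),
    class = "anova_result"
  )
}

# Greenhouse-Geisser epsilon from the double-centered covariance of levels.
gg_epsilon <- function(data) {
  v <- stats::cov(data)
  k <- ncol(v)
  j <- diag(k) - 1 / k
  vc <- j %*% v %*% j
  sum(diag(vc))^2 / ((k - 1) * sum(vc^2))
}

#' Two-way repeated-measures ANOVA
#'
#' Fully-crossed within-subject two-way ANOVA on a subjects x A-levels x
#' B-levels array; each effect (A, B, A:B) is tested against its own
#' effect-by-subject error term.
#'
#' @param data numeric 3-d array `[subject, A, B]`, no missing cells.
#' @return An `anova_result` with three effect rows (A, B, A:B).
#' @export
rm_anova_twoway <- function(data) {
  stopifnot(length(dim(data)) == 3)
  if (anyNA(data)) stopf("balanced-design error: missing cells")
  dims <- dim(data)
  s <- dims[1]
  stopifnot(s >= 2, dims[2] >= 2, dims[3] >= 2)
  idx <- expand.grid(subject = seq_len(dims[1]), A = seq_len(dims[2]),
                     B = seq_len(dims[3]))
  df <- data.frame(
    y = as.vector(data),
    subject = factor(idx$subject), A = factor(idx$A), B = factor(idx$B)
  )
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = df)
  su <- summary(fit)
  ss_tot <- max(sum((df$y - mean(df$y))^2), 1e-20 * (1 + sum(df$y^2)))
  pull <- function(stratum, term) {
    tab <- su[[stratum]][[1]]
    f_val <- tab[term, "F value"]
    p <- tab[term, "Pr(>F)"]
    if (tab[term, "Sum Sq"] <= 1e-12 * max(ss_tot, 1e-300)) { # 0/0 guard
      f_val <- 0
      p <- 1
    }
    data.frame(
      name = term, F = f_val, df_num = tab[term, "Df"],
      df_den = tab["Residuals", "Df"], p = p,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(effects = rbind(
      pull("Error: subject:A", "A"),
      pull("Error: subject:B", "B"),
      pull("Error: subject:A:B", "A:B")
    )),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    cat(sprintf("%s: F(%g, %g) = %.3f, p = %.4g\n",
                e$name, e$df_num, e$df_den, e$F, e$p))
  }
  invisible(x)
}

# Rouder et al. JZS marginal likelihood ratio: BF10 for a one-sample /
# paired t statistic with n observations (pairs) and Cauchy(prior_scale)
# prior on standardized effect size, computed by adaptive quadrature over
# the inverse-gamma mixing variable g.
jzs_bf10 <- function(t, n, prior_scale) {
  nu <- n - 1
  like0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      prior_scale / sqrt(2 * pi) * g^(-3 / 2) *
      exp(-prior_scale^2 / (2 * g))
  }
  int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                          stop.on.error = FALSE)
  if (int$message != "OK") {
    stopf("JZS integration failed: %s (t = %g, n = %d)", int$message, t, n)
  }
  int$value / like0
}

#' JZS Bayes factor for a paired t-test
#'
#' Default two-sided Jeffreys-Zellner-Siow Bayes factor quantifying evidence
#' for the null over the alternative (BF01), with a Cauchy prior of scale
#' `prior_scale` on the standardized effect size (0.707, the JASP default),
#' computed by numerical integration of the marginal likelihood.
#'
#' @param a,b per-subject paired values.
#' @param prior_scale Cauchy prior scale, default `sqrt(2) / 2`.
#' @return A `bayes_factor_result`: `bf01`, `bf10`, `t`, `n`, `prior_scale`.
#' @export
jzs_bf01_paired <- function(a, b, prior_scale = sqrt(2) / 2) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) stopf("degenerate data: zero-variance differences")
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  jzs_bf01_from_t(t, n, prior_scale)
}

#' JZS Bayes factor from a t statistic
#'
#' @param t observed t statistic.
#' @param n number of observations (pairs).
#' @param prior_scale Cauchy prior scale, default `sqrt(2) / 2`.
#' @return A `bayes_factor_result`.
#' @export
jzs_bf01_from_t <- function(t, n, prior_scale = sqrt(2) / 2) {
  bf10 <- jzs_bf10(t, n, prior_scale)
  structure(
    list(bf01 = 1 / bf10, bf10 = bf10, t = t, n = n,
         prior_scale = prior_scale),
    class = "bayes_factor_result"
  )
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("BF01 = %.3f (t = %.3f, n = %d, Cauchy scale %.3f)\n",
              x$bf01, x$t, x$n, x$prior_scale))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; hypotheses with
#' adjusted p at or below `q` are rejected.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @param q FDR level, default 0.05.
#' @return An `fdr_result`: `p_raw`, `p_adjusted`, `rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  structure(
    list(p_raw = p, p_adjusted = adj, rejected = adj <= q, q = q),
    class = "fdr_result"
  )
}

#' Cousineau within-subject standard errors
#'
#' Removes between-subject offsets (cell minus subject mean plus grand mean)
#' before computing per-condition SEMs, so the error bars reflect the
#' within-subject variability relevant to repeated-measures contrasts. The
#' Morey cluster correction `sqrt(C / (C - 1))` is optional.
#'
#' @param data numeric matrix, subjects x conditions (>= 2 subjects).
#' @param morey apply the Morey correction factor, default `FALSE`.
#' @return Numeric vector of per-condition standard errors.
#' @export
cousineau_sem <- function(data, morey = FALSE) {
  data <- as.matrix(data)
  s <- nrow(data)
  if (s < 2) stopf("need >= 2 subjects for within-subject error bars")
  norm <- data - rowMeans(data) + mean(data)
  sems <- apply(norm, 2, stats::sd) / sqrt(s)
  if (morey) {
    cc <- ncol(data)
    sems <- sems * sqrt(cc / (cc - 1))
  }
  sems
}
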