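# Paired-volume agreement statistics: Pearson r with Fisher CI, one-way
# random-effects ICC, Bland-Altman limits of agreement, mixed-model method
# contrast, Wilcoxon-Mann-Whitney tests and median/IQR summaries.

check_pairs <- function(a, b, min_n = 2) {
  if (length(a) != length(b)) stopf("methods must be paired (equal length)")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < min_n) stopf("need at least %d complete pairs", min_n)
  list(a = a, b = b, n = length(a))
}

#' Pearson correlation with Fisher confidence interval
#'
#' Product-moment correlation of paired measurements, 95% CI by the Fisher
#' z-transform `tanh(atanh(r) +/- 1.96/sqrt(n-3))`, and a two-sided p-value
#' from `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param a,b paired numeric vectors (method A and method B), n >= 4.
#' @param conf confidence level.
#' @return list with `r`, `r2`, `ci` (length 2), `p`, `n`.
#' @export
pearson_ci <- function(a, b, conf = 0.95) {
  p <- check_pairs(a, b, min_n = 4)
  if (sd(p$a) == 0 || sd(p$b) == 0) stopf("zero variance in one method")
  am <- p$a - mean(p$a); bm <- p$b - mean(p$b)
  r <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zc <- qnorm(1 - (1 - conf) / 2)
  ci <- tanh(z + c(-1, 1) * zc / sqrt(p$n - 3))
  tstat <- r * sqrt((p$n - 2) / max(1 - r^2, 1e-300))
  pval <- 2 * pt(-abs(tstat), df = p$n - 2)
  list(r = r, r2 = r^2, ci = ci, p = pval, n = p$n)
}

# balanced one-way random-effects ANOVA pieces for n subjects x k replicates
anova_icc_pieces <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  msb <- k * var(rowMeans(mat))
  msw <- sum((mat - rowMeans(mat))^2) / (n * (k - 1))
  list(msb = msb, msw = msw, n = n, k = k)
}

#' Intraclass correlation (one-way random effects)
#'
#' Agreement of paired measurements as the share of between-subject variance
#' in the total: ICC = sigma^2_subject / (sigma^2_subject + sigma^2_residual),
#' with the variance components estimated by REML (subject random intercept,
#' methods as replicates) and an ANOVA ICC(1,1) estimator as fallback when
#' the mixed model fails to converge. The CI is the exact F-distribution
#' interval for ICC(1,1).
#'
#' @param a,b paired numeric vectors, n >= 5.
#' @param conf confidence level.
#' @param estimator `"reml"` (default) or `"anova"`.
#' @return list with `icc`, `ci`, `icc_anova`, `n`, `estimator`.
#' @export
icc_mixed <- function(a, b, conf = 0.95, estimator = c("reml", "anova")) {
  estimator <- match.arg(estimator)
  p <- check_pairs(a, b, min_n = 5)
  mat <- cbind(p$a, p$b)
  pieces <- anova_icc_pieces(mat)
  k <- pieces$k; n <- pieces$n
  icc_anova <- (pieces$msb - pieces$msw) /
    (pieces$msb + (k - 1) * pieces$msw)
  icc <- icc_anova
  used <- "anova"
  if (estimator == "reml") {
    df <- data.frame(y = c(mat), subject = factor(rep(seq_len(n), k)))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(y ~ 1 + (1 | subject), data = df,
                                  REML = TRUE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      vs <- vc$vcov[vc$grp == "subject"]
      ve <- vc$vcov[vc$grp == "Residual"]
      icc <- vs / (vs + ve)
      used <- "reml"
    } else {
      message("mixed model did not converge; using ANOVA ICC(1,1)")
    }
  }
  alpha <- 1 - conf
  fstat <- pieces$msb / pieces$msw
  fl <- fstat / qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- fstat * qf(1 - alpha / 2, n * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci = ci, icc_anova = icc_anova, n = n, estimator = used)
}

#' Bland-Altman agreement analysis
#'
#' Per-subject differences `diff = a - b`; bias = mean(diff), 95% limits of
#' agreement = bias +/- 1.96 sd(diff), and the bias CI
#' bias +/- 1.96 sd/sqrt(n).
#'
#' @param a,b paired numeric vectors (difference reported as A - B).
#' @return list with `bias`, `bias_ci`, `limits`, `sd_diff`, `n`, `diff`,
#'   `mean_pair`.
#' @export
bland_altman <- function(a, b) {
  p <- check_pairs(a, b, min_n = 2)
  d <- p$a - p$b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias,
       bias_ci = bias + c(-1, 1) * 1.96 * s / sqrt(p$n),
       limits = bias + c(-1, 1) * 1.96 * s,
       sd_diff = s, n = p$n, diff = d, mean_pair = (p$a + p$b) / 2)
}

#' Method contrast from a subject-random-intercept model
#'
#' The fixed between-method effect ("difference in contrast", DC) from
#' `volume ~ method + (1 | subject)`, reported as method B minus method A
#' with a CI and p-value on n-1 degrees of freedom. On balanced paired data
#' this equals the paired-t mean difference; the paired t-test is also the
#' fallback when the mixed model fails.
#'
#' @param a,b paired numeric vectors.
#' @param conf confidence level.
#' @return list with `dc`, `ci`, `p`, `se`, `n`, `estimator`.
#' @export
method_contrast <- function(a, b, conf = 0.95) {
  p <- check_pairs(a, b, min_n = 3)
  n <- p$n
  df <- data.frame(y = c(p$a, p$b),
                   method = factor(rep(c("A", "B"), each = n)),
                   subject = factor(rep(seq_len(n), 2)))
  d <- p$b - p$a
  if (sd(d) == 0) {
    # degenerate paired data (constant offset): the contrast is exact
    est <- mean(d)
    return(list(dc = est, ci = c(est, est),
                p = if (est == 0) 1 else 0, se = 0, n = n,
                estimator = "exact"))
  }
  est <- se <- NULL
  used <- "lmm"
  fit <- tryCatch(
    suppressMessages(lme4::lmer(y ~ method + (1 | subject), data = df,
                                REML = TRUE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    est <- unname(lme4::fixef(fit)["methodB"])
    se <- unname(sqrt(diag(as.matrix(stats::vcov(fit))))[2])
  } else {
    message("mixed model did not converge; using the paired t-test")
    tt <- t.test(p$b, p$a, paired = TRUE)
    est <- unname(tt$estimate)
    se <- unname(tt$stderr)
    used <- "paired-t"
  }
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  tstat <- est / se
  pval <- if (se == 0) as.numeric(est == 0) else 2 * pt(-abs(tstat), df = n - 1)
  list(dc = est, ci = est + c(-1, 1) * tq * se, p = pval, se = unname(se),
       n = n, estimator = used)
}

# U statistic for group A: number of (a, b) pairs with a > b (+ 0.5 per tie)
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Wilcoxon-Mann-Whitney U test
#'
#' Two-sided rank-sum test comparing two independent groups. For
#' `nA + nB <= exact_limit` without ties the null distribution of U is built
#' by full enumeration of all group assignments; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact_limit maximum pooled size for the exact enumeration.
#' @return list with `u` (U of group `a`), `p`, `method`.
#' @export
wilcoxon_mwu <- function(a, b, exact_limit = 12) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stopf("both groups must be nonempty")
  pooled <- c(a, b)
  ties <- any(duplicated(pooled))
  u <- u_statistic(a, b)
  if (na + nb <= exact_limit && !ties) {
    picks <- combn(na + nb, na)
    us <- apply(picks, 2, function(ix)
      u_statistic(pooled[ix], pooled[-ix]))
    lo <- min(u, na * nb - u); hi <- max(u, na * nb - u)
    p <- (sum(us <= lo) + sum(us >= hi)) / ncol(picks)
    return(list(u = u, p = min(p, 1), method = "exact enumeration"))
  }
  n <- na + nb
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal approximation"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  list(u = u, p = min(2 * pnorm(-max(z, 0)), 1),
       method = "normal approximation")
}

#' Median and interquartile range
#'
#' Linear-interpolation (type-7) quantiles, the convention recorded in the
#' output so cross-language checks agree.
#'
#' @param values numeric vector (nonempty).
#' @return list with `median`, `iqr` (`c(q1, q3)`), `n`, `quantile_type`.
#' @export
summarize_volumes <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stopf("no finite values")
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = qs[2], iqr = c(qs[1], qs[3]), n = length(values),
       quantile_type = 7)
}

#' Full agreement battery for one paired-volume comparison
#'
#' @param a,b paired volumes (ml) for methods A and B.
#' @param label comparison label.
#' @return object of class `agreement_report` combining [pearson_ci()],
#'   [icc_mixed()], [bland_altman()], [method_contrast()] and per-method
#'   [summarize_volumes()].
#' @export
agreement_report <- function(a, b, label = "A vs B") {
  structure(list(label = label,
                 pearson = pearson_ci(a, b),
                 icc = icc_mixed(a, b),
                 bland_altman = bland_altman(a, b),
                 dc = method_contrast(a, b),
                 summary_a = summarize_volumes(a),
                 summary_b = summarize_volumes(b)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  pr <- x$pearson
  cat(sprintf("%s (n = %d)\n", x$label, pr$n))
  cat(sprintf("  r = %.2f, 95%% CI %.2f-%.2f, p = %.3g; r2 = %.2f\n",
              pr$r, pr$ci[1], pr$ci[2], pr$p, pr$r2))
  cat(sprintf("  ICC = %.2f, 95%% CI %.2f-%.2f (%s)\n",
              x$icc$icc, x$icc$ci[1], x$icc$ci[2], x$icc$estimator))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman bias %.2f ml (95%% CI %.2f-%.2f), limits %.1f-%.1f ml\n",
              ba$bias, ba$bias_ci[1], ba$bias_ci[2], ba$limits[1],
              ba$limits[2]))
  cat(sprintf("  DC = %.2f ml, 95%% CI %.2f-%.2f, p = %.3g\n",
              x$dc$dc, x$dc$ci[1], x$dc$ci[2], x$dc$p))
  cat(sprintf("  medians: A %.1f (IQR %.1f-%.1f), B %.1f (IQR %.1f-%.1f)\n",
              x$summary_a$median, x$summary_a$iqr[1], x$summary_a$iqr[2],
              x$summary_b$median, x$summary_b$iqr[1], x$summary_b$iqr[2]))
  invisible(x)
}
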