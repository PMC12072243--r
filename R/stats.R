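#' @include AllGenerics.R
#' @importFrom stats pchisq pnorm cor.test t.test wilcox.test aov psmirnov
#'   sd ecdf
NULL

## Cohort-level statistics: two-sample Kolmogorov-Smirnov, chi-squared
## with adjusted standardized residuals (the post-hoc used on the subtype
## proportion tables), correlations, and paired/group tests with
## Holm-Sidak correction.

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum distance between the two empirical CDFs,
#' computed directly from the pooled order statistics (ties contribute
#' only at tie-group edges). The p-value is exact (network algorithm over
#' the pooled sample, ties respected) when `n*m <= 10^4`, otherwise the
#' asymptotic Smirnov distribution is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List: `D`, `p.value`, `exact` (logical).
#' @examples
#' ksTwoSample(1:10, 1:10)$D
#' @export
ksTwoSample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  o <- order(pooled)
  z <- cumsum(c(rep(1 / n, n), rep(-1 / m, m))[o])
  # the ECDF difference is only meaningful at the upper edge of each tie
  # group of the pooled sample
  edge <- c(diff(pooled[o]) != 0, TRUE)
  D <- max(abs(z[edge]))
  exact <- (n * m <= 1e4)
  p <- psmirnov(D, sizes = c(n, m), z = sort(pooled),
                two.sided = TRUE, exact = exact, lower.tail = FALSE)
  p <- min(1, max(0, p))
  list(D = D, p.value = p, exact = exact)
}

#' Chi-squared test with adjusted standardized residual analysis
#'
#' Pearson chi-squared test of independence on a contingency table of
#' counts, followed by the per-cell post-hoc used on subtype proportion
#' tables: adjusted standardized residuals
#' `r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - R_i/N) (1 - C_j/N))`, each
#' referred to the standard normal for a two-sided per-cell p-value, with
#' cells flagged at `alpha` as increased or decreased relative to
#' independence. No continuity correction is applied unless requested; the
#' per-cell p-values are raw unless `adjust = "holm"`.
#'
#' @param table Matrix of non-negative counts (at least 2x2).
#' @param alpha Per-cell significance level for the direction flags.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @param adjust `"none"` (default) or `"holm"` for the per-cell p-values.
#' @return List: `statistic`, `df`, `p.value`, `expected`, `residuals`
#'   (adjusted standardized), `residual_p`, `direction` (character matrix:
#'   `"increase"`, `"decrease"` or `""`).
#' @examples
#' chiSquaredResiduals(matrix(c(10, 0, 0, 10), 2))$statistic
#' @export
chiSquaredResiduals <- function(table, alpha = 0.05, correct = FALSE,
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  O <- as.matrix(table)
  if (any(O < 0) || any(abs(O - round(O)) > 1e-8))
    stop("table must contain non-negative integer counts")
  if (nrow(O) < 2 || ncol(O) < 2) stop("need at least a 2x2 table")
  N <- sum(O)
  R <- rowSums(O); C <- colSums(O)
  E <- outer(R, C) / N
  if (any(E <= 0))
    stop("zero expected counts: merge sparse categories before testing")
  if (correct && nrow(O) == 2 && ncol(O) == 2) {
    stat <- sum((pmax(0, abs(O - E) - 0.5))^2 / E)
  } else {
    stat <- sum((O - E)^2 / E)
  }
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  r <- (O - E) / sqrt(E * outer(1 - R / N, 1 - C / N))
  rp <- 2 * pnorm(-abs(r))
  if (adjust == "holm") rp[] <- stats::p.adjust(rp, method = "holm")
  dir <- matrix("", nrow(O), ncol(O), dimnames = dimnames(O))
  dir[rp < alpha & O > E] <- "increase"
  dir[rp < alpha & O < E] <- "decrease"
  list(statistic = stat, df = df, p.value = p, expected = E,
       residuals = r, residual_p = rp, direction = dir)
}

#' Pearson or Spearman correlation with p-value
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"pearson"` or `"spearman"` (midranks for ties).
#' @return List: `estimate`, `p.value`, `method`.
#' @examples
#' correlations(1:10, (1:10)^3, method = "spearman")$estimate
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the inputs")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak procedure: order the p-values increasingly, adjust the
#' i-th as `1 - (1 - p_(i))^(m - i + 1)`, and enforce monotonicity by
#' running maxima.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @examples
#' holmSidak(c(0.01, 0.04, 0.03))
#' @export
holmSidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Paired and group comparisons
#'
#' Dispatcher for the group-level tests used on cohort measurements:
#' two-sided paired t, Wilcoxon signed-rank, one-way ANOVA (optionally
#' with Holm-Sidak-adjusted pairwise post-hoc t comparisons), and one-way
#' repeated-measures ANOVA. The requested test is run as named; no silent
#' switching on assumption checks (record the design choice explicitly).
#'
#' @param values Numeric measurements. For paired tests supply `values`
#'   and `values2`; for ANOVA supply `values` with `groups` (and `subject`
#'   for repeated measures).
#' @param values2 Second member of each pair (paired tests only).
#' @param groups Factor of group labels (ANOVA).
#' @param subject Factor of subject ids (repeated-measures ANOVA);
#'   the design must be balanced.
#' @param test One of `"paired_t"`, `"wilcoxon"`, `"anova"`, `"rm_anova"`.
#' @param posthoc Run Holm-Sidak-adjusted pairwise t comparisons after a
#'   significant ANOVA.
#' @return List with `test`, `statistic`, `df`, `p.value` and, when
#'   applicable, `posthoc` (data.frame of pairwise comparisons).
#' @examples
#' groupTests(c(1, 2, 3), values2 = c(1.1, 2.4, 2.9), test = "paired_t")$p.value
#' @export
groupTests <- function(values, values2 = NULL, groups = NULL,
                       subject = NULL,
                       test = c("paired_t", "wilcoxon", "anova", "rm_anova"),
                       posthoc = TRUE) {
  test <- match.arg(test)
  if (test %in% c("paired_t", "wilcoxon")) {
    if (is.null(values2)) stop("paired tests need values2")
    if (length(values) != length(values2)) stop("pairs must align")
    d <- values - values2
    if (test == "paired_t") {
      if (all(d == 0))
        return(list(test = test, statistic = 0,
                    df = length(d) - 1, p.value = 1))
      tt <- t.test(values, values2, paired = TRUE)
      return(list(test = test, statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p.value = tt$p.value))
    }
    wt <- suppressWarnings(wilcox.test(values, values2, paired = TRUE,
                                       exact = FALSE))
    return(list(test = test, statistic = unname(wt$statistic),
                df = NA_real_, p.value = wt$p.value))
  }
  if (is.null(groups)) stop("ANOVA needs group labels")
  groups <- factor(groups)
  if (test == "anova") {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    out <- list(test = test, statistic = s[["F value"]][1],
                df = c(s[["Df"]][1], s[["Df"]][2]),
                p.value = s[["Pr(>F)"]][1])
  } else {
    if (is.null(subject)) stop("repeated-measures ANOVA needs subject ids")
    subject <- factor(subject)
    if (any(table(subject, groups) != 1))
      stop("unbalanced repeated-measures design: one value per subject x group required")
    fit <- aov(values ~ groups + Error(subject))
    s <- summary(fit)[["Error: Within"]][[1]]
    out <- list(test = test, statistic = s[["F value"]][1],
                df = c(s[["Df"]][1], s[["Df"]][2]),
                p.value = s[["Pr(>F)"]][1])
  }
  if (posthoc && nlevels(groups) > 2) {
    lev <- levels(groups)
    cmb <- utils::combn(lev, 2)
    praw <- apply(cmb, 2, function(pr) {
      t.test(values[groups == pr[1]], values[groups == pr[2]])$p.value
    })
    out$posthoc <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                              p.raw = praw, p.adj = holmSidak(praw))
  }
  out
}
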