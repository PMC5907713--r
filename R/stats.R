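# Assumption-dispatched group comparisons, effect sizes, post-hoc tests
# and correlations.

#' Eta-squared effect size
#'
#' Between-group sum of squares over total sum of squares.
#'
#' @param values numeric vector.
#' @param labels group assignment.
#' @return Value in `[0, 1]` (1 when all within-group variance is zero).
#' @examples
#' eta_squared(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # 27/31
#' @export
eta_squared <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  grand <- mean(values)
  sst <- sum((values - grand)^2)
  if (sst == 0) return(0)
  ssb <- sum(tapply(values, labels, function(v) length(v) * (mean(v) - grand)^2))
  ssb / sst
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and a median-centered Levene (Brown-Forsythe)
#' test across groups, both at level `alpha`.
#'
#' @param values numeric vector.
#' @param labels group assignment (each group n >= 3).
#' @param alpha significance level.
#' @return List with `normal`, `homoscedastic`, `shapiro_p` (named per
#'   group) and `levene_p`.
#' @export
check_assumptions <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  groups <- split(values, labels)
  if (any(lengths(groups) < 3)) stop("every group needs n >= 3")
  shapiro_p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, 0)
  lev <- car::leveneTest(values ~ labels, center = median)
  levene_p <- lev[["Pr(>F)"]][1]
  list(normal = all(shapiro_p > alpha),
       homoscedastic = levene_p > alpha,
       shapiro_p = shapiro_p, levene_p = levene_p)
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z-tests on mean ranks with tie correction, following a
#' significant Kruskal-Wallis omnibus test. P-values are Holm-adjusted by
#' default (set `adjust = "none"` for unadjusted values).
#'
#' @param values numeric vector.
#' @param labels group assignment.
#' @param adjust p-value adjustment method (see [stats::p.adjust()]).
#' @param alpha significance level for the `significant` flag.
#' @return Data frame `pair, z, p_value, p_adjusted, significant`.
#' @export
dunn_test <- function(values, labels, adjust = "holm", alpha = 0.05) {
  labels <- factor(labels)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, labels, mean)
  ns <- table(labels)
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(v0 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = adjust)
  data.frame(pair = apply(pairs, 2, paste, collapse = " vs "),
             z = z, p_value = p, p_adjusted = padj,
             significant = padj < alpha, row.names = NULL)
}

#' Assumption-dispatched group comparison
#'
#' One-way ANOVA with Tukey HSD post-hoc when every group passes
#' Shapiro-Wilk and the groups pass a median-centered Levene test at
#' `alpha`; otherwise Kruskal-Wallis with Holm-adjusted Dunn post-hoc.
#' Post-hoc tests run only when the omnibus p-value is below `alpha`.
#' Effect size is eta-squared on the ANOVA branch and its rank-based
#' analogue `(H - k + 1) / (n - k)` (clipped to `[0, 1]`) on the
#' Kruskal-Wallis branch.
#'
#' @param values numeric vector.
#' @param labels group assignment (>= 2 groups).
#' @param alpha significance level.
#' @param variable optional variable name carried on the result.
#' @param posthoc_adjust adjustment for Dunn p-values.
#' @return A `comparison_result`: list with `variable`, `test_used`
#'   (`"anova"` or `"kruskal_wallis"`), `statistic`, `df`, `p_value`,
#'   `effect_size`, `effect_type`, `posthoc` (data frame or `NULL`) and
#'   `assumptions`.
#' @export
compare_groups <- function(values, labels, alpha = 0.05,
                           variable = NULL, posthoc_adjust = "holm") {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  assum <- check_assumptions(values, labels, alpha)
  k <- nlevels(labels)
  n <- length(values)
  if (assum$normal && assum$homoscedastic) {
    fit <- stats::aov(values ~ labels)
    tab <- summary(fit)[[1]]
    stat <- tab[["F value"]][1]
    df <- c(tab[["Df"]][1], tab[["Df"]][2])
    p <- tab[["Pr(>F)"]][1]
    es <- eta_squared(values, labels)
    posthoc <- NULL
    if (p < alpha) {
      tk <- stats::TukeyHSD(fit)[[1]]
      posthoc <- data.frame(pair = gsub("-", " vs ", rownames(tk)),
                            diff = tk[, "diff"], p_value = tk[, "p adj"],
                            p_adjusted = tk[, "p adj"],
                            significant = tk[, "p adj"] < alpha,
                            row.names = NULL)
    }
    test_used <- "anova"
  } else {
    kw <- stats::kruskal.test(values, labels)
    stat <- unname(kw$statistic)
    df <- unname(kw$parameter)
    p <- kw$p.value
    es <- max(0, min(1, (stat - k + 1) / (n - k)))
    posthoc <- if (p < alpha)
      dunn_test(values, labels, adjust = posthoc_adjust, alpha = alpha)
    test_used <- "kruskal_wallis"
  }
  structure(list(variable = variable, groups = levels(labels),
                 test_used = test_used, statistic = stat, df = df,
                 p_value = p, effect_size = es,
                 effect_type = if (test_used == "anova") "eta_squared"
                               else "eta_squared_rank",
                 posthoc = posthoc, assumptions = assum),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: %s, stat = %.3f, p = %.4g, %s = %.3f\n",
              x$variable %||% "?", x$test_used, x$statistic, x$p_value,
              x$effect_type, x$effect_size))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Chi-squared association with Cramer's V
#'
#' Pearson chi-squared without continuity correction on an r x c count
#' table, with `V = sqrt(chi2 / (N * (min(r, c) - 1)))`.
#'
#' @param tab r x c contingency table (matrix or table of counts).
#' @return List with `chi2`, `df`, `p`, `v` and `expected`; warns when any
#'   expected count is below 5.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count below 5; chi-squared approximation is coarse")
  N <- sum(tab)
  v <- sqrt(unname(ct$statistic) / (N * (min(dim(tab)) - 1)))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, v = v, expected = ct$expected)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need paired n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
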