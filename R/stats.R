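#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test, via [stats::oneway.test()]). The degenerate case of zero
#' within-group variance everywhere with equal group means is reported as
#' F = 0, p = 1.
#'
#' @param groups Named (or unnamed) list of numeric samples, one per group;
#'   at least 2 groups of at least 2 observations each.
#' @return Data frame with `statistic` (F), `df1`, `df2`, `p_value`,
#'   `contrast`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); n <- length(values)
  within_var <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  means <- vapply(groups, mean, 0)
  if (within_var == 0 && max(means) == min(means)) {
    f <- 0; p <- 1
  } else {
    tst <- stats::oneway.test(values ~ g, var.equal = TRUE)
    f <- unname(tst$statistic); p <- tst$p.value
  }
  data.frame(statistic = f, df1 = k - 1, df2 = n - k, p_value = p,
             contrast = sprintf("one-way ANOVA, %d groups", k),
             stringsAsFactors = FALSE)
}

#' Two-tailed two-sample t-test
#'
#' Student's pooled-variance t-test by default (matching the convention of
#' reporting "Student's t-test (two-tailed)"); Welch's unequal-variance
#' variant by flag. Degenerate zero-variance inputs are handled explicitly:
#' equal means give t = 0, p = 1; unequal means give p = 0 in the limit,
#' flagged.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @param variance_assumption `"pooled"` (default) or `"welch"`.
#' @return Data frame with `statistic` (t), `df`, `p_value`, `contrast`,
#'   `degenerate`.
#' @export
t_test_two_tailed <- function(a, b,
                              variance_assumption = c("pooled", "welch")) {
  variance_assumption <- match.arg(variance_assumption)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  lab <- sprintf("two-tailed t-test (%s)", variance_assumption)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(data.frame(statistic = 0, df = length(a) + length(b) - 2,
                        p_value = 1, contrast = lab, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    warning("zero variance with unequal means: p reported as limiting 0")
    return(data.frame(statistic = Inf * sign(mean(a) - mean(b)),
                      df = length(a) + length(b) - 2, p_value = 0,
                      contrast = lab, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  tst <- stats::t.test(a, b, var.equal = variance_assumption == "pooled",
                       alternative = "two.sided")
  data.frame(statistic = unname(tst$statistic),
             df = unname(tst$parameter), p_value = tst$p.value,
             contrast = lab, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Asterisk annotation for a p-value
#'
#' Figure-caption convention: one to four asterisks at p < 0.05, 0.01,
#' 0.001, 0.0001 (strict inequalities; a p exactly at a threshold earns the
#' weaker annotation), `"ns"` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Multiple-testing adjustment for a contrast table
#'
#' Applies [stats::p.adjust()] to the p-values of a contrast table (as
#' produced by the pipeline's statistics stage), within each metric when a
#' `metric` column is present, and re-derives the asterisk annotation from
#' the adjusted values. Off by default throughout the package, matching
#' per-contrast reporting practice.
#'
#' @param tab Data frame with a `p_value` column (optionally `metric`).
#' @param method Adjustment method, default `"bonferroni"`;
#'   see [stats::p.adjust()].
#' @return `tab` with added `p_adjusted` and `stars_adjusted` columns.
#' @export
adjust_contrasts <- function(tab, method = "bonferroni") {
  if (!"p_value" %in% names(tab)) stop("`tab` must have a p_value column")
  if ("metric" %in% names(tab)) {
    tab$p_adjusted <- stats::ave(tab$p_value, tab$metric,
                                 FUN = function(p) stats::p.adjust(p, method))
  } else {
    tab$p_adjusted <- stats::p.adjust(tab$p_value, method)
  }
  tab$stars_adjusted <- significance_stars(tab$p_adjusted)
  tab
}
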