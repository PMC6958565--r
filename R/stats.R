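#' Exclude aberrant values by the mean +/- 1.5 IQR rule
#'
#' Single-pass exclusion of values strictly outside
#' `[mean - 1.5 * IQR, mean + 1.5 * IQR]`, the boxplot-screening rule used
#' for cohort metrics. Note the interval is centred on the *mean* (not the
#' Tukey median/quartile fences); `tukey = TRUE` switches to the classical
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` fences. Quartiles use the linear
#' interpolation convention (`stats::quantile` type 7).
#'
#' @param values numeric vector, n >= 4; NAs are ignored (never excluded).
#' @param k fence multiplier (default 1.5).
#' @param tukey use quartile-centred fences instead of the mean-centred ones.
#' @return List with `kept` (values inside the fences), `excluded` (integer
#'   indices into `values`) and `bounds` (lower, upper).
#' @export
exclude_outliers <- function(values, k = 1.5, tukey = FALSE) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  v <- values[ok]
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0 && length(unique(v)) > 1L) {
    warning("zero IQR with spread values; excluding nothing")
    return(list(kept = v, excluded = integer(0), bounds = c(-Inf, Inf)))
  }
  bounds <- if (tukey) c(q[1] - k * iqr, q[2] + k * iqr)
            else mean(v) + c(-1, 1) * k * iqr
  out <- which(ok)[v < bounds[1] | v > bounds[2]]
  keep <- setdiff(which(ok), out)
  list(kept = values[keep], excluded = out, bounds = bounds)
}

significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

# Shapiro-gated two-sample test on prepared vectors.
gated_test <- function(x, y, paired) {
  if (length(x) < 3L || (!is.null(y) && length(y) < 3L))
    stop("need at least 3 observations per sample")
  normal <- function(v) {
    if (length(unique(v)) == 1L) return(FALSE)   # degenerate: not testable
    stats::shapiro.test(v)$p.value > 0.05
  }
  both_normal <- normal(x) && normal(y)
  if (paired && all(x == y)) {
    # zero differences everywhere: no effect, tests degenerate
    return(list(test = "t", statistic = 0, p = 1, normal = both_normal))
  }
  if (both_normal) {
    ht <- stats::t.test(x, y, paired = paired)
    list(test = "t", statistic = unname(ht$statistic), p = ht$p.value,
         normal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                              exact = FALSE))
    list(test = if (paired) "Wilcoxon" else "Mann-Whitney",
         statistic = unname(ht$statistic), p = ht$p.value, normal = FALSE)
  }
}

#' Normality-gated two-group or paired comparison
#'
#' Shapiro-Wilk normality at 0.05 on each sample decides the branch: both
#' normal gives the parametric test (independent or paired Student t),
#' otherwise Mann-Whitney (independent) or Wilcoxon signed-rank (paired).
#' Two-sided throughout, significance threshold 0.05.
#'
#' Independent design compares `parameter` between the two `group` levels;
#' paired design compares `parameter` against `parameter2` within the rows
#' of one group (e.g. extracranial vs intracranial value of the same
#' quantity per subject).
#'
#' @param table cohort `data.frame` with a `group` column.
#' @param parameter metric column name.
#' @param design `"independent"` or `"paired"`.
#' @param parameter2 second metric column (paired design).
#' @param group group level to restrict to (paired design).
#' @return An object of class `comparison_result`: parameter(s), design,
#'   test used, statistic, p-value, significance stars, sample sizes.
#' @export
compare_groups <- function(table, parameter,
                           design = c("independent", "paired"),
                           parameter2 = NULL, group = NULL) {
  design <- match.arg(design)
  if (design == "independent") {
    lv <- unique(table$group)
    if (length(lv) != 2L) stop("independent design needs exactly 2 groups")
    x <- table[[parameter]][table$group == lv[1]]
    y <- table[[parameter]][table$group == lv[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    res <- gated_test(x, y, paired = FALSE)
    n <- c(length(x), length(y))
    desc <- sprintf("%s: %s vs %s", parameter, lv[1], lv[2])
  } else {
    if (is.null(parameter2)) stop("paired design needs parameter2")
    rows <- if (is.null(group)) rep(TRUE, nrow(table)) else table$group == group
    x <- table[[parameter]][rows]
    y <- table[[parameter2]][rows]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    res <- gated_test(x, y, paired = TRUE)
    n <- length(x)
    desc <- sprintf("%s vs %s%s", parameter, parameter2,
                    if (is.null(group)) "" else paste0(" (", group, ")"))
  }
  structure(list(parameter = desc, design = design, test = res$test,
                 statistic = res$statistic, p = res$p,
                 stars = significance_stars(res$p), n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s [%s, %s]: stat = %.3g, p = %.3g %s\n",
              x$parameter, x$design, x$test, x$statistic, x$p, x$stars))
  invisible(x)
}

#' Classify a correlation coefficient's strength
#'
#' Bands on |r|: below 0.30 "below-weak", 0.30-0.49 "weak", 0.50-0.69
#' "moderate", 0.70-0.89 "strong", 0.90 and above "very strong". The bands
#' are exhaustive and mutually exclusive over [-1, 1].
#'
#' @param r correlation coefficient.
#' @return Character strength class.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  if (a > 1) stop("|r| > 1")
  if (a >= 0.90) "very strong"
  else if (a >= 0.70) "strong"
  else if (a >= 0.50) "moderate"
  else if (a >= 0.30) "weak"
  else "below-weak"
}

#' Pearson correlation with strength classification
#'
#' Two-sided Pearson correlation between two metric columns, rows with a
#' missing value in either column dropped pairwise.
#'
#' @param table cohort `data.frame`.
#' @param x,y metric column names.
#' @param group optional group level to restrict to.
#' @return An object of class `correlation_result`: `pair`, `r`, `p`, `n`,
#'   `strength`.
#' @export
correlate <- function(table, x, y, group = NULL) {
  rows <- if (is.null(group)) rep(TRUE, nrow(table)) else table$group == group
  xv <- table[[x]][rows]; yv <- table[[y]][rows]
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in one of the variables")
  ht <- stats::cor.test(xv, yv, method = "pearson")
  r <- unname(ht$estimate)
  structure(list(pair = paste(x, "~", y,
                              if (is.null(group)) "" else paste0("(", group, ")")),
                 r = r, p = ht$p.value, n = length(xv),
                 strength = correlation_strength(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: r = %.3f (%s), p = %.3g, n = %d\n",
              x$pair, x$r, x$strength, x$p, x$n))
  invisible(x)
}
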