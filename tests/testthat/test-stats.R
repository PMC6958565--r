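test_that("outlier rule excludes values outside mean +/- 1.5 IQR", {
  vals <- c(1, 2, 3, 4, 5, 100)
  # brute-force type-7 quantile oracle
  q7 <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  iqr <- q7(vals, 0.75) - q7(vals, 0.25)
  bounds <- mean(vals) + c(-1.5, 1.5) * iqr
  res <- exclude_outliers(vals)
  expect_equal(res$bounds, bounds)
  # the mean-centred fence is dragged towards the outlier: on this skewed
  # fixture the verbatim rule excludes every value (the outlier included)
  expect_true(6L %in% res$excluded)
  expect_equal(res$excluded, which(vals < bounds[1] | vals > bounds[2]))
  # the Tukey variant isolates just the aberrant value
  tk <- exclude_outliers(vals, tukey = TRUE)
  expect_equal(tk$excluded, 6L)
  expect_equal(tk$kept, c(1, 2, 3, 4, 5))
  # single pass is idempotent on the Tukey output here
  expect_length(exclude_outliers(tk$kept, tukey = TRUE)$excluded, 0)
  # well-behaved data: only the implanted outlier is excluded
  vals2 <- c(10, 11, 12, 13, 14, 15, 16, 22)
  res2 <- exclude_outliers(vals2)
  expect_equal(res2$excluded, 8L)
  expect_length(exclude_outliers(res2$kept)$excluded, 0)
})

test_that("outlier rule edge cases behave as documented", {
  expect_length(exclude_outliers(rep(7, 6))$excluded, 0)
  expect_warning(res <- exclude_outliers(c(5, 5, 5, 5, 5, 100)), "zero IQR")
  expect_length(res$excluded, 0)
  vals <- c(-2, -1, 0, 1, 2)
  expect_length(exclude_outliers(vals)$excluded, 0)   # symmetric, all inside
  expect_error(exclude_outliers(c(1, 2, 3)), "at least 4")
  # Tukey variant centres fences on the quartiles
  tk <- exclude_outliers(c(1, 2, 3, 4, 5, 100), tukey = TRUE)
  expect_equal(tk$excluded, 6L)
})

test_that("identical paired samples are non-significant", {
  tab <- data.frame(group = rep("HYV", 6), a = 1:6, b = 1:6)
  res <- compare_groups(tab, "a", "paired", "b", group = "HYV")
  expect_gte(res$p, 0.99)
  expect_equal(res$stars, "ns")
})

test_that("normality gate routes heavy-tailed data to nonparametric tests", {
  set.seed(77)
  x <- stats::rcauchy(16); y <- stats::rcauchy(19)
  expect_lt(stats::shapiro.test(x)$p.value, 0.05)   # fixture sanity
  tab <- data.frame(group = c(rep("HYV", 16), rep("HEV", 19)), v = c(x, y))
  res <- compare_groups(tab, "v", "independent")
  expect_equal(res$test, "Mann-Whitney")
  set.seed(78)
  b <- c(seq(-1, 1, length.out = 15), 25)      # hard outlier: not normal
  expect_lt(stats::shapiro.test(b)$p.value, 0.05)
  tab2 <- data.frame(group = rep("HYV", 16), a = stats::rnorm(16), b = b)
  res2 <- compare_groups(tab2, "a", "paired", "b", group = "HYV")
  expect_equal(res2$test, "Wilcoxon")
})

test_that("two normal samples one SD apart are detected with adequate power", {
  n1 <- 16L; n2 <- 19L; d <- 1
  # analytic oracle: noncentral t power for the two-sided 0.05 test
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  df <- n1 + n2 - 2
  tcrit <- stats::qt(0.975, df)
  power_analytic <- 1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
  expect_gte(power_analytic, 0.8)
  set.seed(501)
  hits <- 0L; reps <- 500L
  for (i in seq_len(reps)) {
    tab <- data.frame(group = c(rep("HYV", n1), rep("HEV", n2)),
                      v = c(stats::rnorm(n1, 0), stats::rnorm(n2, d)))
    hits <- hits + (compare_groups(tab, "v", "independent")$p < 0.05)
  }
  power_sim <- hits / reps
  mc_se <- sqrt(power_analytic * (1 - power_analytic) / reps)
  expect_lt(abs(power_sim - power_analytic), 3 * mc_se)
})

test_that("correlation strength bands are exhaustive and exclusive", {
  expect_equal(correlation_strength(0.73), "strong")
  expect_equal(correlation_strength(0.50), "moderate")
  expect_equal(correlation_strength(-0.95), "very strong")
  expect_equal(correlation_strength(0.29), "below-weak")
  expect_equal(correlation_strength(0.30), "weak")
  classes <- c("below-weak", "weak", "moderate", "strong", "very strong")
  for (r in seq(-1, 1, by = 0.005)) {
    cl <- correlation_strength(r)
    expect_length(cl, 1)
    expect_true(cl %in% classes)
  }
})

test_that("correlate reports Pearson r with classification", {
  tab <- data.frame(group = rep("HYV", 8), x = 1:8, y = 2 * (1:8) + 3)
  res <- correlate(tab, "x", "y")
  expect_equal(res$r, 1)
  expect_equal(res$strength, "very strong")
  tab$y[3] <- NA
  expect_equal(correlate(tab, "x", "y")$n, 7)     # pairwise deletion
  expect_error(correlate(data.frame(group = rep("HYV", 5), x = 1:5,
                                    y = rep(2, 5)), "x", "y"), "zero variance")
  expect_error(correlate(data.frame(group = rep("HYV", 3), x = 1:3, y = 1:3),
                         "x", "y"), "at least 4")
})
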