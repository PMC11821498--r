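test_that("normality gate routes by Shapiro-Wilk in both groups", {
  set.seed(14)
  # Normal samples are parametric with probability about 0.95^2
  hits <- replicate(200, {
    normality_gate(rnorm(50), rnorm(50)) == "parametric"
  })
  expect_gt(mean(hits), 0.82)
  expect_lt(mean(hits), 0.98)
  # heavy skew forces the nonparametric route
  hits_exp <- replicate(100, {
    normality_gate(rexp(50), rexp(50)) == "nonparametric"
  })
  expect_gt(mean(hits_exp), 0.95)
  expect_error(normality_gate(1:2, rnorm(10)), "n >= 3")
  expect_error(normality_gate(rep(1, 10), rnorm(10)), "constant")
})

test_that("group comparison matches an exact permutation oracle", {
  low <- c(1, 2, 3, 4); high <- c(5, 6, 7, 8)
  # oracle: all 70 assignments of 8 values into two groups of 4
  pooled <- c(low, high)
  t_obs <- abs(t.test(low, high, var.equal = TRUE)$statistic)
  u_obs <- wilcox.test(low, high, exact = TRUE)$statistic
  combs <- combn(8, 4)
  t_perm <- apply(combs, 2, function(ix) {
    abs(t.test(pooled[ix], pooled[-ix], var.equal = TRUE)$statistic)
  })
  p_t_perm <- mean(t_perm >= t_obs - 1e-12)
  cmp_t <- compare_groups(low, high, route = "parametric")
  # complete separation: permutation p = 2/70; Student p is smaller but the
  # statistic must match the classical computation
  expect_equal(p_t_perm, 2 / 70)
  expect_equal(cmp_t$statistic,
               unname(t.test(low, high, var.equal = TRUE)$statistic))
  cmp_u <- compare_groups(low, high, route = "nonparametric")
  expect_equal(cmp_u$test, "mann-whitney")
  # exact Mann-Whitney two-sided p for complete separation = 2/70
  expect_equal(cmp_u$p_value, 2 / 70)
  expect_equal(cmp_u$statistic, unname(u_obs))
})

test_that("comparisons are symmetric and null on identical groups", {
  x <- c(2, 4, 4.5, 5, 7)
  cmp <- compare_groups(x, x, route = "parametric")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(compare_groups(a, b, route = "parametric")$p_value,
               compare_groups(b, a, route = "parametric")$p_value)
  expect_equal(compare_groups(a, b, route = "nonparametric")$p_value,
               compare_groups(b, a, route = "nonparametric")$p_value)
  expect_error(compare_groups(1, c(2, 3)), "n >= 2")
})

test_that("correlations match closed forms and handle ties", {
  x <- 1:10
  expect_equal(correlate(x, x, "parametric")$estimate, 1)
  expect_equal(correlate(x, -2 * x + 3, "parametric")$estimate, -1)
  expect_equal(correlate(x, x^3, "nonparametric")$estimate, 1)
  # tied ranks: brute-force rank formula with tie correction
  a <- c(1, 2, 2, 3, 4, 5)
  b <- c(2, 1, 3, 3, 5, 6)
  expect_equal(correlate(a, b, "nonparametric")$estimate,
               unname(cor(rank(a), rank(b))))
  expect_error(correlate(rep(1, 6), 1:6, "parametric"), "variance")
  expect_error(correlate(1:3, 1:3), "n >= 4")
})

test_that("the report has the study's shape and routing rules", {
  co <- make_cohort(seed = 4)
  rep <- build_report(co)
  expect_s3_class(rep, "t2_report")
  expect_equal(nrow(rep$comparisons), 4)
  expect_setequal(rep$comparisons$outcome,
                  c("t2_mono_ms", "t2s_ms", "t2l_ms", "f_pct"))
  expect_true(all(rep$comparisons$p_value >= 0 & rep$comparisons$p_value <= 1))
  expect_true(all(rep$comparisons$test %in% c("t", "mann-whitney")))
  # NPI correlations are always Spearman
  npi_rows <- rep$correlations[rep$correlations$covariate == "npi", ]
  expect_true(all(npi_rows$type == "spearman"))
  expect_true(all(abs(rep$correlations$estimate) <= 1))
  # relabeling specimen ids does not change the statistics
  co2 <- co; co2$specimen_id <- rev(co2$specimen_id)
  expect_equal(build_report(co2)$comparisons$p_value,
               rep$comparisons$p_value)
  # tidy / glance accessors
  td <- tidy(rep)
  expect_true(all(c("contrast", "outcome", "p_value") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_low, 11)
  expect_equal(gl$n_high, 9)
  expect_error(build_report(co[, setdiff(names(co), "f_pct")]), "missing")
})

test_that("two identical groups produce no significant contrasts", {
  set.seed(15)
  vals <- rnorm(11, 75, 8)
  co <- tibble::tibble(
    specimen_id = sprintf("S%02d", 1:22),
    group = factor(rep(c("low", "high"), each = 11), c("low", "high")),
    t2_mono_ms = rep(vals, 2), t2s_ms = rep(vals * 0.8, 2),
    t2l_ms = rep(vals * 2, 2), f_pct = rep(vals / 2, 2))
  rep <- build_report(co)
  expect_true(all(!rep$comparisons$significant))
  expect_true(all(rep$comparisons$p_value > 0.99))
})

test_that("pipeline power rises with the generating mean difference", {
  gp <- cohort_defaults()
  power_at <- function(shift, n_rep = 400, seed = 30) {
    set.seed(seed)
    mean(replicate(n_rep, {
      lo <- rnorm(11, 73.30, 11.30)
      hi <- rnorm(9, 73.30 + shift, 7.38)
      compare_groups(lo, hi)$p_value < 0.05
    }))
  }
  p0 <- power_at(0); p1 <- power_at(5); p2 <- power_at(10.25)
  expect_lt(p0, 0.12)
  expect_gt(p2, p1)
  expect_gt(p1, p0)
})
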