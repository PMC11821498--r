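sched <- echo_schedule()

test_that("noiseless phantom parameters are recovered by the sampler", {
  ph <- make_phantom(shape = c(12, 12, 1), snr = Inf, seed = 3)
  fit <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, sched,
                            bi_fit_config(n_iterations = 600, n_burnin = 300,
                                          seed = 1))
  m <- truth_vs_fit(ph, fit)
  expect_lt(max(abs(m$f.fit - m$f.true)), 0.01)
  expect_lt(max(abs(m$t2s.fit / m$t2s.true - 1)), 0.01)
  expect_lt(max(abs(m$t2l.fit / m$t2l.true - 1)), 0.01)
})

test_that("sampler output is bit-reproducible for a fixed seed", {
  ph <- benchmark_phantom(shape = c(10, 10, 1), snr = 40, seed = 2)
  cfg <- bi_fit_config(n_iterations = 300, n_burnin = 150, seed = 7)
  a <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, sched, cfg)
  b <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, sched, cfg)
  expect_identical(a$f_map, b$f_map)
  expect_identical(a$t2s_map, b$t2s_map)
  expect_identical(a$accept_map, b$accept_map)
})

test_that("compartment ordering and ranges hold everywhere in the maps", {
  ph <- benchmark_phantom(shape = c(12, 12, 1), snr = 25, seed = 4)
  fit <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, sched,
                            bi_fit_config(n_iterations = 400, n_burnin = 200,
                                          seed = 2))
  inmask <- ph$tumour_mask > 0
  expect_true(all(fit$t2s_map[inmask] <= fit$t2l_map[inmask]))
  expect_true(all(fit$f_map[inmask] > 0 & fit$f_map[inmask] < 1))
  expect_true(all(fit$s0_map[inmask] > 0))
  expect_true(all(fit$accept_map[inmask] >= 0 & fit$accept_map[inmask] <= 1))
  # posterior spread maps are nonnegative and present
  expect_true(all(fit$f_sd_map[inmask] >= 0))
})

test_that("with the spatial prior off the fit stays at the NLLS solution on noiseless data", {
  ph <- make_phantom(shape = c(8, 8, 1), snr = Inf, seed = 5)
  fit <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, sched,
                            bi_fit_config(n_iterations = 400, n_burnin = 200,
                                          spatial = FALSE, seed = 3))
  nlls <- fit_bi_image(ph$signal, ph$tumour_mask, sched, seed = 3)
  m <- dplyr::inner_join(tidy(fit), tidy(nlls), by = c("x", "y", "z"),
                         suffix = c(".b", ".n"))
  expect_lt(max(abs(m$f.b - m$f.n)), 0.02)
  expect_lt(max(abs(m$t2s.b / m$t2s.n - 1)), 0.02)
})

test_that("map and posterior-median estimators are available", {
  ph <- benchmark_phantom(shape = c(8, 8, 1), snr = 40, seed = 6)
  for (est in c("map", "posterior_median")) {
    fit <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, sched,
                              bi_fit_config(n_iterations = 300, n_burnin = 150,
                                            estimator = est, seed = 1))
    inmask <- ph$tumour_mask > 0
    expect_true(all(is.finite(fit$f_map[inmask])))
    expect_true(all(fit$t2s_map[inmask] <= fit$t2l_map[inmask]))
  }
})

test_that("config validation catches inconsistent settings", {
  expect_error(bi_fit_config(n_iterations = 100, n_burnin = 100), "n_burnin")
  expect_error(bi_fit_config(tau = -1))
  expect_error(fit_bi_bayes_image(array(1, c(4, 4, 1, 10)), schedule = sched,
                                  config = bi_fit_config()), "echo")
  ph <- make_phantom(shape = c(6, 6, 1), snr = Inf, seed = 1)
  expect_error(fit_bi_bayes_image(ph$signal, array(FALSE, c(6, 6, 1)), sched,
                                  bi_fit_config()), "mask")
})

test_that("chain diagnostics separate mixed from divergent segments", {
  # identical segments: statistic exactly 1
  x <- cbind(rep(1.5, 100), rep(1.5, 100))
  expect_equal(chain_diagnostics(x)$rhat, 1)
  # independent draws from one distribution: statistic near 1
  set.seed(8)
  y <- matrix(rnorm(4000), ncol = 4)
  d <- chain_diagnostics(y)
  expect_lt(d$rhat, 1.02)
  expect_false(d$flagged)
  expect_gt(d$ess, 1000)
  # shifted segments: statistic above the 1.1 threshold
  z <- cbind(rnorm(200), rnorm(200) + 3)
  expect_gt(chain_diagnostics(z)$rhat, 1.1)
  expect_true(chain_diagnostics(z)$flagged)
  expect_error(chain_diagnostics(matrix(1:10, ncol = 1)), "segments")
})
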