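test_that("noiseless mono data is recovered essentially exactly", {
  sched <- echo_schedule()
  set.seed(11)
  for (i in 1:10) {
    s0 <- runif(1, 20, 300)
    t2 <- runif(1, 20, 400)
    fit <- fit_mono_voxel(mono_signal(s0, t2, sched), sched)
    expect_true(fit$converged)
    expect_equal(fit$t2, t2, tolerance = 1e-6)
    expect_equal(fit$s0, s0, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12 * s0^2)
  }
})

test_that("mono fit of bi-exponential data lands between the two T2s", {
  sched <- echo_schedule()
  y <- bi_signal(100, 0.4, 65, 150, sched)
  fit <- fit_mono_voxel(y, sched)
  expect_gt(fit$t2, 65)
  expect_lt(fit$t2, 150)
  # brute-force 1-D profile search confirms the NLLS minimum
  grid_t2 <- seq(66, 149, by = 0.25)
  rss_grid <- vapply(grid_t2, function(t2) {
    u <- exp(-echo_times(sched) / t2)
    sum((y - sum(y * u) / sum(u * u) * u)^2)
  }, numeric(1))
  t2_star <- grid_t2[which.min(rss_grid)]
  expect_equal(fit$t2, t2_star, tolerance = 0.3 / t2_star)
  expect_lte(fit$rss, min(rss_grid) + 1e-9)
})

test_that("mono estimates are unbiased under gaussian noise", {
  sched <- echo_schedule()
  clean <- mono_signal(100, 80, sched)
  set.seed(21)
  est <- replicate(400, {
    fit_mono_voxel(clean + rnorm(24, 0, 2), sched)$t2
  })
  expect_equal(mean(est), 80, tolerance = 0.02)
})

test_that("degenerate voxels are flagged, never silently fitted", {
  sched <- echo_schedule()
  expect_false(fit_mono_voxel(rep(0, 24), sched)$converged)
  expect_false(fit_mono_voxel(c(NA, rnorm(23)), sched)$converged)
  expect_true(is.na(fit_mono_voxel(rep(0, 24), sched)$t2))
  expect_error(fit_mono_voxel(1:10, sched), "length")
})

test_that("image-level fit equals the voxel-level fit and honours masks", {
  sched <- echo_schedule()
  ph <- make_phantom(shape = c(8, 8, 1), snr = 40, seed = 6)
  fit <- fit_mono_image(ph$signal, ph$tumour_mask, sched)
  n_vox <- prod(dim(ph$tumour_mask))
  idx <- which(ph$tumour_mask > 0)
  # naive per-voxel oracle loop
  for (v in idx[c(1, 5, length(idx))]) {
    ref <- fit_mono_voxel(ph$signal[v + (seq_len(24) - 1) * n_vox], sched)
    expect_identical(fit$t2_map[v], ref$t2)
    expect_identical(fit$rss_map[v], ref$rss)
  }
  # masked-out voxels are invalid
  expect_true(all(is.na(fit$t2_map[ph$tumour_mask == 0])))
  expect_true(all(!fit$converged_mask[ph$tumour_mask == 0]))
  # echo mismatch errors
  expect_error(fit_mono_image(ph$signal[, , , 1:10, drop = FALSE],
                              ph$tumour_mask, sched), "echo")
})

test_that("uniform noiseless phantom yields a constant T2 map", {
  sched <- echo_schedule()
  regs <- list(phantom_disk(c(6.5, 6.5), 4, f = 1, t2s = 90, t2l = 90))
  ph <- make_phantom(c(12, 12, 1), regions = regs, snr = Inf, seed = 1)
  fit <- fit_mono_image(ph$signal, ph$tumour_mask, sched)
  vals <- fit$t2_map[ph$tumour_mask > 0]
  expect_equal(vals, rep(90, length(vals)), tolerance = 1e-6)
})
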