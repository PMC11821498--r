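test_that("noiseless phantom signal equals the closed-form prediction", {
  ph <- make_phantom(shape = c(16, 16, 1), snr = Inf, seed = 3)
  expect_identical(ph$signal, ph$clean)
  n_vox <- prod(dim(ph$tumour_mask))
  idx <- which(ph$tumour_mask > 0)
  for (v in idx[c(1, length(idx) %/% 2, length(idx))]) {
    pred <- bi_signal(ph$truth$s0[v], ph$truth$f[v], ph$truth$t2s[v],
                      ph$truth$t2l[v], ph$schedule)
    expect_equal(ph$clean[v + (seq_len(24) - 1) * n_vox], pred)
  }
  # outside the tumour the signal is zero
  first_echo <- ph$signal[seq_len(n_vox)]
  expect_true(all(first_echo[ph$tumour_mask == 0] == 0))
})

test_that("phantoms are bit-reproducible for a fixed seed", {
  a <- make_phantom(shape = c(12, 12, 1), snr = 40, seed = 9)
  b <- make_phantom(shape = c(12, 12, 1), snr = 40, seed = 9)
  expect_identical(a$signal, b$signal)
  expect_identical(a$truth, b$truth)
  c <- make_phantom(shape = c(12, 12, 1), snr = 40, seed = 10)
  expect_false(identical(a$signal, c$signal))
})

test_that("first-echo SNR is realized within sampling error", {
  ph <- make_phantom(shape = c(64, 64, 1), snr = 50, seed = 5)
  n_vox <- prod(dim(ph$tumour_mask))
  first_noisy <- ph$signal[seq_len(n_vox)]
  first_clean <- ph$clean[seq_len(n_vox)]
  inmask <- ph$tumour_mask > 0
  # sigma definition: mean in-mask first-echo clean signal / snr
  expect_equal(ph$sigma, mean(first_clean[inmask]) / 50)
  # empirical noise SD close to sigma at high first-echo signal
  dev <- first_noisy[inmask] - first_clean[inmask]
  expect_equal(sd(dev), ph$sigma, tolerance = 0.06)
  expect_equal(mean(first_clean[inmask]) / sd(dev), 50, tolerance = 0.06)
})

test_that("noise models behave as specified", {
  clean <- array(100, dim = c(20, 20, 1, 4))
  # very large snr: output approaches clean
  out <- add_noise(clean, snr = 1e6, noise_model = "rician", seed = 1)
  expect_lt(max(abs(out$signal - clean)), 1e-3 * 100)
  # zero image with explicit sigma: Rayleigh mean sigma * sqrt(pi/2)
  z <- array(0, dim = c(50, 50, 1, 8))
  out <- add_noise(z, snr = 1, noise_model = "rician", seed = 2, sigma = 3)
  expect_equal(mean(out$signal), 3 * sqrt(pi / 2), tolerance = 0.01)
  # rician floor: rician mean at low signal exceeds gaussian mean
  low <- array(1, dim = c(50, 50, 1, 4))
  r <- add_noise(low, snr = 1, noise_model = "rician", seed = 3, sigma = 2)
  g <- add_noise(low, snr = 1, noise_model = "gaussian", seed = 3, sigma = 2)
  expect_gt(mean(r$signal), mean(g$signal))
  expect_true(all(r$signal >= 0))
  # determinism
  r2 <- add_noise(low, snr = 1, noise_model = "rician", seed = 3, sigma = 2)
  expect_identical(r$signal, r2$signal)
  expect_error(add_noise(low, snr = -1), "snr")
})

test_that("overlapping regions and invalid necrosis are rejected", {
  regs <- list(phantom_disk(c(8, 8), 4), phantom_disk(c(9, 8), 4))
  expect_error(make_phantom(c(16, 16, 1), regions = regs, seed = 1), "overlap")
  expect_error(
    make_phantom(c(16, 16, 1), regions = list(phantom_disk(c(8, 8), 4)),
                 necrosis = list(center = c(1, 1), radius = 1), seed = 1),
    "necrotic")
})

test_that("necrotic core lies inside the tumour and alters its parameters", {
  ph <- make_phantom(c(24, 24, 1), regions = list(phantom_disk(c(12, 12), 9)),
                     necrosis = list(center = c(12, 12), radius = 3),
                     snr = Inf, seed = 2)
  expect_true(all(ph$tumour_mask[ph$necrosis_mask > 0] == 1))
  expect_gt(sum(ph$necrosis_mask), 0)
  # long-T2, low-f necrotic tissue
  expect_true(all(ph$truth$t2l[ph$necrosis_mask > 0] >
                    max(ph$truth$t2l[ph$tumour_mask > 0 & ph$necrosis_mask == 0])))
})

test_that("phantom round-trips through NIfTI + YAML", {
  dir <- tempfile("ph_")
  ph <- make_phantom(shape = c(10, 10, 1), snr = 30, seed = 4)
  write_phantom(ph, dir)
  ph2 <- read_phantom(dir)
  expect_equal(ph2$signal, ph$signal, tolerance = 1e-7)
  expect_equal(ph2$tumour_mask, ph$tumour_mask)
  expect_equal(ph2$truth$f, ph$truth$f, tolerance = 1e-7)
  expect_equal(ph2$schedule$n_echoes, ph$schedule$n_echoes)
  expect_error(read_phantom(tempfile()), "phantom")
})
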