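shape <- c(10, 10, 1)
tumour <- array(FALSE, shape); tumour[3:8, 3:8, 1] <- TRUE
necrosis <- array(FALSE, shape); necrosis[5:6, 5:6, 1] <- TRUE

test_that("roi_mean averages exactly over tumour minus necrosis", {
  m <- array(7, shape)
  expect_equal(roi_mean(m, tumour, necrosis), 7)
  # value only inside necrosis does not contribute
  m2 <- array(0, shape); m2[necrosis] <- 1
  expect_equal(roi_mean(m2, tumour, necrosis), 0)
  # random map equals a brute-force loop over eligible voxels
  set.seed(5)
  m3 <- array(runif(prod(shape)), shape)
  acc <- c()
  for (i in 1:10) for (j in 1:10) {
    if (tumour[i, j, 1] && !necrosis[i, j, 1]) acc <- c(acc, m3[i, j, 1])
  }
  expect_equal(roi_mean(m3, tumour, necrosis), mean(acc))
  # invalid voxels excluded
  m4 <- m3; m4[3, 3, 1] <- NaN
  acc4 <- acc[-1]
  expect_equal(roi_mean(m4, tumour, necrosis), mean(acc4))
  expect_error(roi_mean(m3, array(FALSE, shape)), "empty")
})

test_that("roi_mean is invariant outside the ROI and monotone inside", {
  set.seed(6)
  m <- array(runif(prod(shape)), shape)
  base <- roi_mean(m, tumour, necrosis)
  m_out <- m; m_out[!tumour] <- 99
  expect_equal(roi_mean(m_out, tumour, necrosis), base)
  m_up <- m; m_up[tumour] <- m_up[tumour] + 1
  expect_gt(roi_mean(m_up, tumour, necrosis), base)
})

test_that("volume ratio is 100 times the mean intra-cellular fraction", {
  f <- array(0.5, shape)
  expect_equal(volume_ratio(f, tumour, necrosis), 50)
  expect_equal(volume_ratio(array(0, shape), tumour, necrosis), 0)
})

test_that("Ki-67 dichotomization is strict at 14 percent", {
  expect_equal(classify_ki67(49.18), "high")
  expect_equal(classify_ki67(4.96), "low")
  expect_equal(classify_ki67(14.0), "low")
  expect_equal(classify_ki67(14.0001), "high")
  expect_equal(classify_ki67(c(10, 20)), c("low", "high"))
  expect_error(classify_ki67(120), "0, 100")
  expect_error(classify_ki67(-1), "0, 100")
})

test_that("specimen summary recovers ground truth on a noiseless phantom", {
  sched <- echo_schedule()
  ph <- make_phantom(shape = c(16, 16, 1), snr = Inf, seed = 12)
  mono <- fit_mono_image(ph$signal, ph$tumour_mask, sched)
  bi <- fit_bi_image(ph$signal, ph$tumour_mask, sched, n_starts = 3, seed = 1)
  rec <- summarize_specimen(mono, bi, ph$tumour_mask, ph$necrosis_mask,
                            specimen_id = "S01",
                            clinical = list(ki67_pct = 20, diameter_mm = 25,
                                            npi = 4.4))
  tr <- tidy(ph)
  expect_equal(rec$t2s_ms, mean(tr$t2s), tolerance = 0.01)
  expect_equal(rec$t2l_ms, mean(tr$t2l), tolerance = 0.01)
  expect_equal(rec$f_pct, 100 * mean(tr$f), tolerance = 0.01)
  expect_equal(as.character(rec$group), "high")
  expect_lt(rec$t2s_ms, rec$t2l_ms)
})
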