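# Shared fixtures for the simulation-based tests.

# Two-band piecewise-constant phantom with well-separated compartments
# (short/long T2 ratio >= 3.5, cohort-plausible values): the layout used by
# the recovery and robustness benchmarks.
benchmark_phantom <- function(shape = c(24, 24, 1), snr = 50, seed = 1,
                              noise_model = "rician") {
  regs <- banded_regions(shape, data.frame(
    f = c(0.50, 0.45), t2s = c(45, 50), t2l = c(185, 175)))
  make_phantom(shape = shape, regions = regs, snr = snr,
               noise_model = noise_model, seed = seed)
}

# join ground truth and fitted values voxel by voxel
truth_vs_fit <- function(phantom, fit) {
  dplyr::inner_join(tidy(phantom), tidy(fit), by = c("x", "y", "z"),
                    suffix = c(".true", ".fit"))
}

region_recovery <- function(phantom, fit) {
  m <- truth_vs_fit(phantom, fit)
  dplyr::summarise(
    dplyr::group_by(m, .data$f.true, .data$t2s.true, .data$t2l.true),
    f.hat = mean(.data$f.fit), t2s.hat = mean(.data$t2s.fit),
    t2l.hat = mean(.data$t2l.fit), .groups = "drop")
}

rmse_by_param <- function(phantom, fit, clamp = FALSE) {
  m <- truth_vs_fit(phantom, fit)
  vals <- list(f = m$f.fit, t2s = m$t2s.fit, t2l = m$t2l.fit)
  if (clamp) {
    vals$f <- pmin(pmax(vals$f, 0), 1)
    vals$t2s <- pmin(pmax(vals$t2s, 1), 1000)
    vals$t2l <- pmin(pmax(vals$t2l, 1), 1000)
  }
  c(f = sqrt(mean((vals$f - m$f.true)^2)),
    t2s = sqrt(mean((vals$t2s - m$t2s.true)^2)),
    t2l = sqrt(mean((vals$t2l - m$t2l.true)^2)))
}
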