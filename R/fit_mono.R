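#' Fit the single-compartment model to one voxel
#'
#' Non-linear least squares estimation of `(s0, t2)` for the
#' mono-exponential decay [mono_signal()]. Initialization is ordinary least
#' squares on the log-signal over echoes above `max(signal) * 1e-3`
#' (the log of the model is affine in TE with slope `-1/t2`); the estimate
#' is then refined by Levenberg-Marquardt with box bounds on `t2`. The
#' refined fit never ends with a higher residual sum of squares than its
#' initializer (the better of the two is returned).
#'
#' @param signal Numeric vector of echo magnitudes (one per echo).
#' @param schedule An [echo_schedule()] or echo-time vector (ms).
#' @param t2_bounds Length-2 bounds on `t2` in ms; default `c(1, 1000)`.
#' @return A list: `s0`, `t2` (ms), `rss`, `converged`. Degenerate signals
#'   (non-finite, all-zero, or fewer than 3 usable echoes) are flagged
#'   `converged = FALSE` with `NA` estimates, never silently zero.
#' @export
#' @examples
#' y <- mono_signal(100, 80, echo_schedule())
#' fit_mono_voxel(y, echo_schedule())
fit_mono_voxel <- function(signal, schedule, t2_bounds = c(1, 1000)) {
  te <- as_echo_times(schedule)
  bad <- list(s0 = NA_real_, t2 = NA_real_, rss = NA_real_, converged = FALSE)
  if (length(signal) != length(te)) {
    stop("signal length does not match the echo schedule", call. = FALSE)
  }
  if (any(!is.finite(signal)) || all(signal == 0)) return(bad)

  use <- signal > max(signal) * 1e-3
  if (sum(use) < 3) return(bad)
  ols <- stats::lm.fit(cbind(1, te[use]), log(signal[use]))
  slope <- ols$coefficients[2]
  t2_init <- if (is.finite(slope) && slope < 0) -1 / slope else mean(te)
  t2_init <- min(max(t2_init, t2_bounds[1]), t2_bounds[2])
  s0_init <- max(exp(ols$coefficients[1]), .Machine$double.eps)
  rss_init <- sum((signal - s0_init * exp(-te / t2_init))^2)

  resid_fn <- function(par) signal - par[1] * exp(-te / par[2])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(s0_init, t2_init), fn = resid_fn,
      lower = c(0, t2_bounds[1]), upper = c(Inf, t2_bounds[2]),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(s0 = s0_init, t2 = t2_init, rss = rss_init, converged = FALSE))
  }
  rss_fit <- sum(resid_fn(fit$par)^2)
  if (rss_fit <= rss_init) {
    list(s0 = fit$par[1], t2 = fit$par[2], rss = rss_fit,
         converged = fit$info %in% 1:4)
  } else {
    list(s0 = s0_init, t2 = t2_init, rss = rss_init, converged = TRUE)
  }
}

#' Fit the single-compartment model voxel-wise over an image
#'
#' Applies [fit_mono_voxel()] independently at every in-mask voxel of a 4-D
#' multi-echo image, producing the overall transverse relaxation time map
#' (T2,MONO). The fit is deterministic; voxels outside the mask, and voxels
#' whose fit fails, are `NA` in the maps and `FALSE` in `converged_mask`.
#'
#' @param signal4d 4-D array `(x, y, z, echo)`.
#' @param mask 3-D 0/1 or logical array (`NULL` fits every voxel).
#' @param schedule An [echo_schedule()].
#' @param t2_bounds Bounds on `t2` in ms.
#' @return A `mono_fit` object: list of 3-D arrays `t2_map`, `s0_map`,
#'   `rss_map`, `converged_mask`, plus `schedule` and `mask`.
#' @export
fit_mono_image <- function(signal4d, mask = NULL, schedule = echo_schedule(),
                           t2_bounds = c(1, 1000)) {
  dm <- dim(signal4d)
  stopifnot(length(dm) == 4)
  if (dm[4] != schedule$n_echoes) {
    stop("image echo count does not match the schedule", call. = FALSE)
  }
  shape <- dm[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (!identical(dim(mask), shape)) {
    stop("mask shape does not match the image grid", call. = FALSE)
  }
  mask <- array(as.logical(mask), shape)

  t2_map <- s0_map <- rss_map <- array(NA_real_, shape)
  converged <- array(FALSE, shape)
  n_vox <- prod(shape)
  idx <- which(mask)
  sig_mat <- matrix(signal4d, nrow = n_vox)[idx, , drop = FALSE]
  for (i in seq_along(idx)) {
    res <- fit_mono_voxel(sig_mat[i, ], schedule, t2_bounds)
    v <- idx[i]
    t2_map[v] <- res$t2
    s0_map[v] <- res$s0
    rss_map[v] <- res$rss
    converged[v] <- res$converged
  }
  structure(
    list(t2_map = t2_map, s0_map = s0_map, rss_map = rss_map,
         converged_mask = converged, schedule = schedule, mask = mask * 1L),
    class = "mono_fit"
  )
}

#' @export
print.mono_fit <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("<mono_fit> %d voxels fitted, %d converged; median T2 = %.1f ms\n",
              n, sum(x$converged_mask),
              stats::median(x$t2_map[x$converged_mask], na.rm = TRUE)))
  invisible(x)
}

#' Tidy voxel-wise fit results into a long tibble
#'
#' @param x A `mono_fit` or `bi_fit`.
#' @param ... Unused.
#' @return One row per in-mask voxel with coordinates, parameter estimates
#'   and diagnostics.
#' @export
tidy.mono_fit <- function(x, ...) {
  idx <- which(x$mask > 0, arr.ind = TRUE)
  out <- tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3])
  out$s0 <- x$s0_map[idx]
  out$t2 <- x$t2_map[idx]
  out$rss <- x$rss_map[idx]
  out$converged <- x$converged_mask[idx]
  out
}

#' One-row fit summary
#'
#' @param x A `mono_fit` or `bi_fit`.
#' @param ... Unused.
#' @return A one-row tibble of convergence and map summaries.
#' @export
glance.mono_fit <- function(x, ...) {
  ok <- x$converged_mask & (x$mask > 0)
  tibble::tibble(
    n_voxels = sum(x$mask > 0),
    n_converged = sum(ok),
    t2_median = stats::median(x$t2_map[ok]),
    rss_total = sum(x$rss_map[ok])
  )
}
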