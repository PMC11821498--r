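#' Transform between natural and unconstrained two-compartment parameters
#'
#' The two-compartment parameters are sampled and optimized on an
#' unconstrained scale that enforces their invariants by construction:
#' `eta = (log s0, logit f, log t2s, log(t2l - t2s))`, so that `s0 > 0`,
#' `f` in (0, 1) and `t2s < t2l` hold for every real-valued `eta`.
#'
#' @param eta Numeric length-4 vector (or 4-column matrix) on the
#'   unconstrained scale.
#' @return `bi_from_eta()`: natural-scale `(s0, f, t2s, t2l)`;
#'   `bi_to_eta()`: the inverse.
#' @keywords internal
bi_from_eta <- function(eta) {
  if (is.matrix(eta)) {
    t2s <- exp(eta[, 3])
    cbind(s0 = exp(eta[, 1]), f = stats::plogis(eta[, 2]),
          t2s = t2s, t2l = t2s + exp(eta[, 4]))
  } else {
    t2s <- exp(eta[3])
    c(s0 = exp(eta[1]), f = stats::plogis(eta[2]),
      t2s = t2s, t2l = t2s + exp(eta[4]))
  }
}

#' @rdname bi_from_eta
#' @param s0,f,t2s,t2l Natural-scale parameters.
#' @keywords internal
bi_to_eta <- function(s0, f, t2s, t2l) {
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  gap <- pmax(t2l - t2s, 1e-6)
  c(log(s0), stats::qlogis(f), log(t2s), log(gap))
}

#' Fit the two-compartment model to one voxel by multistart NLLS
#'
#' Independent-voxel baseline for the two-compartment decay model: best of
#' `n_starts` Levenberg-Marquardt fits on the unconstrained scale of
#' [bi_from_eta()], which enforces `f` in (0, 1) and `t2s < t2l` by
#' construction. The first start is derived deterministically from the
#' mono-exponential fit of the same voxel; the rest are seeded jitters of
#' it. Bi-exponential least squares has flat cost valleys when the two
#' compartments are barely distinguishable, so near-degenerate solutions
#' (`f` near 0 or 1, or `t2l/t2s < 1.05`) are flagged `identifiable = FALSE`
#' rather than masked out.
#'
#' @param signal Numeric vector of echo magnitudes (>= 5 echoes).
#' @param schedule An [echo_schedule()] or echo-time vector.
#' @param n_starts Number of local fits (>= 1).
#' @param seed Integer seed for the jittered starts (deterministic output).
#' @return List: `s0`, `f`, `t2s`, `t2l`, `rss`, `converged`,
#'   `identifiable`. Degenerate input signals give `converged = FALSE` and
#'   `NA` estimates.
#' @export
#' @examples
#' y <- bi_signal(100, 0.4, 65, 150, echo_schedule())
#' fit_bi_voxel(y, echo_schedule())
fit_bi_voxel <- function(signal, schedule, n_starts = 5, seed = 1L) {
  te <- as_echo_times(schedule)
  bad <- list(s0 = NA_real_, f = NA_real_, t2s = NA_real_, t2l = NA_real_,
              rss = NA_real_, converged = FALSE, identifiable = FALSE)
  if (length(signal) != length(te)) {
    stop("signal length does not match the echo schedule", call. = FALSE)
  }
  if (length(te) < 5) {
    stop("two-compartment fit needs at least 5 echoes", call. = FALSE)
  }
  if (any(!is.finite(signal)) || all(signal == 0)) return(bad)

  mono <- fit_mono_voxel(signal, schedule)
  if (!is.finite(mono$t2)) return(bad)
  eta_base <- bi_to_eta(max(mono$s0, .Machine$double.eps), 0.5,
                        0.7 * mono$t2, 1.6 * mono$t2)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  starts <- list(eta_base)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- eta_base + stats::rnorm(4, 0, c(0.1, 1.0, 0.4, 0.6))
    }
  }

  resid_fn <- function(eta) {
    th <- bi_from_eta(eta)
    signal - th[1] * (th[2] * exp(-te / th[3]) + (1 - th[2]) * exp(-te / th[4]))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(eta = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) return(bad)
  th <- bi_from_eta(best$eta)
  identifiable <- th["f"] > 0.01 && th["f"] < 0.99 &&
    th["t2l"] / th["t2s"] > 1.05
  list(s0 = unname(th["s0"]), f = unname(th["f"]),
       t2s = unname(th["t2s"]), t2l = unname(th["t2l"]),
       rss = best$rss, converged = best$info %in% 1:4,
       identifiable = unname(identifiable))
}

#' Fit the two-compartment model voxel-wise with independent NLLS
#'
#' Applies [fit_bi_voxel()] at every in-mask voxel; no information is shared
#' between voxels. This is the baseline against which the spatially
#' regularized Bayesian fit ([fit_bi_bayes_image()]) is compared.
#'
#' @inheritParams fit_mono_image
#' @param n_starts,seed Passed to [fit_bi_voxel()]; the per-voxel seed is
#'   derived deterministically from `seed` and the voxel index.
#' @return A `bi_fit` object: 3-D arrays `s0_map`, `f_map`, `t2s_map`,
#'   `t2l_map`, `rss_map`, `converged_mask`, `identifiable_mask`, plus
#'   `schedule`, `mask` and `method = "nlls"`.
#' @export
fit_bi_image <- function(signal4d, mask = NULL, schedule = echo_schedule(),
                         n_starts = 5, seed = 1L) {
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
  maps <- replicate(5, array(NA_real_, shape), simplify = FALSE)
  names(maps) <- c("s0", "f", "t2s", "t2l", "rss")
  converged <- identifiable <- array(FALSE, shape)
  n_vox <- prod(shape)
  idx <- which(mask)
  sig_mat <- matrix(signal4d, nrow = n_vox)[idx, , drop = FALSE]
  for (i in seq_along(idx)) {
    res <- fit_bi_voxel(sig_mat[i, ], schedule, n_starts = n_starts,
                        seed = seed + i)
    v <- idx[i]
    maps$s0[v] <- res$s0; maps$f[v] <- res$f
    maps$t2s[v] <- res$t2s; maps$t2l[v] <- res$t2l
    maps$rss[v] <- res$rss
    converged[v] <- res$converged
    identifiable[v] <- res$identifiable
  }
  structure(
    list(s0_map = maps$s0, f_map = maps$f, t2s_map = maps$t2s,
         t2l_map = maps$t2l, rss_map = maps$rss,
         converged_mask = converged, identifiable_mask = identifiable,
         schedule = schedule, mask = mask * 1L, method = "nlls"),
    class = "bi_fit"
  )
}

#' @export
print.bi_fit <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf(
    "<bi_fit method=%s> %d voxels; median f = %.2f, T2S = %.1f ms, T2L = %.1f ms\n",
    x$method, n,
    stats::median(x$f_map[x$mask > 0], na.rm = TRUE),
    stats::median(x$t2s_map[x$mask > 0], na.rm = TRUE),
    stats::median(x$t2l_map[x$mask > 0], na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidy.mono_fit
#' @export
tidy.bi_fit <- function(x, ...) {
  idx <- which(x$mask > 0, arr.ind = TRUE)
  out <- tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3])
  out$s0 <- x$s0_map[idx]
  out$f <- x$f_map[idx]
  out$t2s <- x$t2s_map[idx]
  out$t2l <- x$t2l_map[idx]
  if (!is.null(x$rss_map)) out$rss <- x$rss_map[idx]
  if (!is.null(x$converged_mask)) out$converged <- x$converged_mask[idx]
  if (!is.null(x$f_sd_map)) {
    out$f_sd <- x$f_sd_map[idx]
    out$t2s_sd <- x$t2s_sd_map[idx]
    out$t2l_sd <- x$t2l_sd_map[idx]
  }
  out
}

#' @rdname glance.mono_fit
#' @export
glance.bi_fit <- function(x, ...) {
  inmask <- x$mask > 0
  tibble::tibble(
    method = x$method,
    n_voxels = sum(inmask),
    f_median = stats::median(x$f_map[inmask], na.rm = TRUE),
    t2s_median = stats::median(x$t2s_map[inmask], na.rm = TRUE),
    t2l_median = stats::median(x$t2l_map[inmask], na.rm = TRUE)
  )
}
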