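#' Default per-group generating parameters for the synthetic cohort
#'
#' Group means and standard deviations for each relaxometry outcome
#' (low/high Ki-67 proliferative-activity groups), together with Ki-67,
#' tumour-diameter and NPI generating distributions. The relaxometry values
#' are the group statistics of the 20-specimen breast-tumour cohort this
#' package emulates; diameter and NPI follow that cohort's demography.
#'
#' @return A nested list with elements `low` and `high`, each holding
#'   `mean`/`sd` pairs for `t2_mono_ms`, `t2s_ms`, `t2l_ms`, `f_pct`, plus
#'   `ki67_range`, `diameter` and `npi` specs.
#' @export
cohort_defaults <- function() {
  list(
    low = list(
      t2_mono_ms = c(mean = 73.30, sd = 11.30),
      t2s_ms     = c(mean = 61.30, sd = 14.01),
      t2l_ms     = c(mean = 156.56, sd = 19.16),
      f_pct      = c(mean = 41.65, sd = 10.08),
      ki67_range = c(1, 14),
      diameter   = c(mean = 24.1, sd = 6.6),
      npi        = c(mean = 4.0, sd = 0.6),
      p_grade2   = 8 / 11
    ),
    high = list(
      t2_mono_ms = c(mean = 83.55, sd = 7.38),
      t2s_ms     = c(mean = 73.52, sd = 10.92),
      t2l_ms     = c(mean = 147.38, sd = 8.84),
      f_pct      = c(mean = 33.64, sd = 8.33),
      ki67_range = c(15, 60),
      diameter   = c(mean = 25.9, sd = 4.7),
      npi        = c(mean = 4.5, sd = 0.4),
      p_grade2   = 2 / 9
    )
  )
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  out[out < lower] <- lower
  out[out > upper] <- upper
  out
}

#' Generate a synthetic specimen cohort
#'
#' Draws per-specimen ground-truth ROI-level relaxometry (`t2_mono_ms`,
#' `t2s_ms`, `t2l_ms`, `f_pct`) from group-specific Normal distributions
#' truncated to physical ranges, Ki-67 percentages consistent with the
#' 14 % dichotomization (low <= 14 < high), tumour diameters and NPI values.
#' Defaults reproduce the study conditions: 11 low / 9 high specimens with
#' the group means and SDs of [cohort_defaults()]. Within each specimen the
#' compartment ordering `t2s_ms <= t2l_ms` is enforced by redrawing.
#'
#' @param n_low,n_high Group sizes (each >= 2). Defaults 11 and 9.
#' @param group_params Generating parameters as from [cohort_defaults()];
#'   SDs must be positive.
#' @param seed Integer seed.
#' @return A tibble with one row per specimen: `specimen_id`, `group`
#'   (factor low/high), `ki67_pct`, `diameter_mm`, `npi`, `grade`,
#'   `t2_mono_ms`, `t2s_ms`, `t2l_ms`, `f_pct`.
#' @export
#' @examples
#' make_cohort(seed = 1)
make_cohort <- function(n_low = 11, n_high = 9,
                        group_params = cohort_defaults(), seed = 1L) {
  stopifnot(n_low >= 2, n_high >= 2)
  for (g in c("low", "high")) {
    for (p in c("t2_mono_ms", "t2s_ms", "t2l_ms", "f_pct")) {
      if (group_params[[g]][[p]][["sd"]] <= 0) {
        stop("generating SDs must be positive", call. = FALSE)
      }
    }
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  draw_group <- function(n, gp, group) {
    t2s <- rnorm_trunc(n, gp$t2s_ms["mean"], gp$t2s_ms["sd"], 1, 1000)
    t2l <- rnorm_trunc(n, gp$t2l_ms["mean"], gp$t2l_ms["sd"], 1, 1000)
    swap <- t2l < t2s
    guard <- 0L
    while (any(swap) && guard < 1000L) {
      t2s[swap] <- rnorm_trunc(sum(swap), gp$t2s_ms["mean"], gp$t2s_ms["sd"], 1, 1000)
      t2l[swap] <- rnorm_trunc(sum(swap), gp$t2l_ms["mean"], gp$t2l_ms["sd"], 1, 1000)
      swap <- t2l < t2s
      guard <- guard + 1L
    }
    tibble::tibble(
      group = group,
      ki67_pct = stats::runif(n, gp$ki67_range[1], gp$ki67_range[2]),
      diameter_mm = rnorm_trunc(n, gp$diameter["mean"], gp$diameter["sd"], 15, 60),
      npi = rnorm_trunc(n, gp$npi["mean"], gp$npi["sd"], 2.08, 6.8),
      grade = ifelse(stats::runif(n) < gp$p_grade2, 2L, 3L),
      t2_mono_ms = rnorm_trunc(n, gp$t2_mono_ms["mean"], gp$t2_mono_ms["sd"], 1, 1000),
      t2s_ms = t2s,
      t2l_ms = t2l,
      f_pct = rnorm_trunc(n, gp$f_pct["mean"], gp$f_pct["sd"], 0, 100)
    )
  }

  cohort <- dplyr::bind_rows(
    draw_group(n_low, group_params$low, "low"),
    draw_group(n_high, group_params$high, "high")
  )
  cohort <- dplyr::mutate(
    cohort,
    specimen_id = sprintf("S%02d", dplyr::row_number()),
    group = factor(.data$group, levels = c("low", "high")),
    .before = 1
  )
  stopifnot(all(classify_ki67(cohort$ki67_pct) == as.character(cohort$group)))
  cohort
}

#' Write / read a phantom as NIfTI volumes plus metadata
#'
#' The 4-D noisy signal, 3-D ground-truth parameter maps and 0/1 masks are
#' written as NIfTI-1 files sharing one affine; the schedule, noise settings
#' and seed go to a YAML sidecar. `read_phantom()` round-trips the object
#' (the noiseless signal is recomputed from the truth maps).
#'
#' @param phantom A `t2_phantom`.
#' @param dir Output directory (created if needed).
#' @return `write_phantom()` returns `dir` invisibly; `read_phantom()`
#'   returns a `t2_phantom`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "t2_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- rep(phantom$voxel_mm, 3)
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- c(pd, rep(1, length(dim(arr)) - 3))
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(phantom$signal, "signal")
  wr(phantom$tumour_mask, "tumour_mask")
  wr(phantom$necrosis_mask, "necrosis_mask")
  for (p in names(phantom$truth)) wr(phantom$truth[[p]], paste0("truth_", p))
  meta <- list(
    schedule = list(n_echoes = phantom$schedule$n_echoes,
                    te_initial = phantom$schedule$te_initial,
                    te_spacing = phantom$schedule$te_spacing),
    snr = if (is.infinite(phantom$snr)) ".inf" else phantom$snr,
    noise_model = phantom$noise_model,
    sigma = phantom$sigma,
    seed = phantom$seed,
    voxel_mm = phantom$voxel_mm
  )
  yaml::write_yaml(meta, file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta_path <- file.path(dir, "phantom.yaml")
  if (!file.exists(meta_path)) {
    stop("not a phantom directory (phantom.yaml missing): ", dir, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  # NIfTI readers drop trailing singleton dimensions; restore them
  as_3d <- function(arr) {
    d <- dim(arr)
    if (length(d) == 2) dim(arr) <- c(d, 1L)
    arr
  }
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    arr <- as.array(RNifti::readNifti(path))
    attributes(arr) <- list(dim = dim(arr))
    arr
  }
  tumour_mask <- (as_3d(rd("tumour_mask")) != 0) * 1L
  necrosis_mask <- (as_3d(rd("necrosis_mask")) != 0) * 1L
  truth <- lapply(lapply(c(s0 = "truth_s0", f = "truth_f",
                           t2s = "truth_t2s", t2l = "truth_t2l"), rd), as_3d)
  shape <- dim(tumour_mask)
  signal <- rd("signal")
  if (length(dim(signal)) == 3 && all(dim(signal)[1:2] == shape[1:2]) &&
      shape[3] == 1L) {
    dim(signal) <- c(shape, dim(signal)[3])
  }
  if (!identical(dim(signal)[1:3], shape) ||
      !identical(dim(necrosis_mask), shape)) {
    stop("signal and mask volumes disagree in shape", call. = FALSE)
  }
  schedule <- echo_schedule(meta$schedule$n_echoes, meta$schedule$te_initial,
                            meta$schedule$te_spacing)
  if (dim(signal)[4] != schedule$n_echoes) {
    stop("signal echo count does not match the stored schedule", call. = FALSE)
  }
  snr <- if (identical(meta$snr, ".inf")) Inf else meta$snr
  te <- echo_times(schedule)
  idx <- which(tumour_mask > 0)
  clean <- array(0, dim = dim(signal))
  n_vox <- prod(shape)
  pred <- truth$s0[idx] * (
    truth$f[idx] * exp(-outer(1 / truth$t2s[idx], te)) +
      (1 - truth$f[idx]) * exp(-outer(1 / truth$t2l[idx], te)))
  for (k in seq_len(schedule$n_echoes)) {
    slice <- array(0, shape)
    slice[idx] <- pred[, k]
    clean[(k - 1L) * n_vox + seq_len(n_vox)] <- slice
  }
  structure(
    list(truth = truth, tumour_mask = array(tumour_mask, shape),
         necrosis_mask = array(necrosis_mask, shape),
         signal = signal, clean = clean, schedule = schedule,
         snr = snr, noise_model = meta$noise_model, sigma = meta$sigma,
         seed = as.integer(meta$seed), voxel_mm = meta$voxel_mm),
    class = "t2_phantom"
  )
}
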