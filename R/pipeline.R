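# deterministic sub-stream seeds: one global seed fans out to stages/specimens
derive_seed <- function(seed, stage, i = 0L) {
  as.integer((as.numeric(seed) * 7919 + stage * 101 + i) %% 2147483629)
}

#' Build one specimen's phantom from a cohort record
#'
#' Realizes a cohort row as a digital specimen: a disk tumour whose
#' two-compartment parameters are the record's ground-truth ROI values
#' (`f_pct / 100`, `t2s_ms`, `t2l_ms`), optionally split into bands with
#' parameter jitter to mimic within-tumour heterogeneity, and optionally
#' carrying a necrotic core.
#'
#' @param record One-row tibble from [make_cohort()].
#' @param shape Image grid. Default `c(24, 24, 1)`.
#' @param snr First-echo SNR (`Inf` for noiseless).
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param n_regions Number of bands (1 = homogeneous tumour).
#' @param jitter SD of the band-level parameter jitter (ms for T2s,
#'   absolute for f); 0 keeps every band at the record values.
#' @param necrosis Logical; add a small necrotic core.
#' @param schedule An [echo_schedule()].
#' @param seed Integer seed.
#' @return A `t2_phantom`.
#' @export
specimen_phantom <- function(record, shape = c(24, 24, 1), snr = 50,
                             noise_model = "rician", n_regions = 1,
                             jitter = 0, necrosis = FALSE,
                             schedule = echo_schedule(), seed = 1L) {
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  cx <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2
  radius <- 0.4 * min(shape[1], shape[2])
  f0 <- record$f_pct / 100
  regions <- lapply(seq_len(n_regions), function(i) {
    f_i <- min(max(f0 + stats::rnorm(1, 0, jitter / 100), 0.01), 0.99)
    t2s_i <- max(record$t2s_ms + stats::rnorm(1, 0, jitter), 5)
    t2l_i <- max(record$t2l_ms + stats::rnorm(1, 0, jitter), t2s_i + 1)
    reg <- phantom_disk(c(cx, cy), radius, s0 = 100, f = f_i,
                        t2s = t2s_i, t2l = t2l_i)
    reg$band <- c((i - 1) / n_regions, i / n_regions)
    class(reg) <- c("phantom_band", "phantom_region")
    reg
  })
  nec <- if (necrosis) list(center = c(cx, cy), radius = radius / 4) else NULL
  make_phantom(shape = shape, regions = regions, necrosis = nec,
               schedule = schedule, snr = snr, noise_model = noise_model,
               seed = derive_seed(seed, 1L))
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all pipeline artifacts.
#' @param n_low,n_high Cohort group sizes.
#' @param shape Per-specimen image grid.
#' @param snr First-echo SNR (`Inf` disables noise).
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param bi_method `"bayes"` (spatially regularized sampler) or `"nlls"`
#'   (independent-voxel baseline).
#' @param n_iterations,n_burnin Sweeps for the Bayesian fit.
#' @param necrosis Add a necrotic core to each specimen.
#' @param seed Global seed; per-stage and per-specimen seeds are derived
#'   from it deterministically.
#' @param schedule An [echo_schedule()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("t2relax_run_"),
                       n_low = 11, n_high = 9,
                       shape = c(24, 24, 1), snr = 50,
                       noise_model = "rician",
                       bi_method = c("bayes", "nlls"),
                       n_iterations = 2000, n_burnin = 1000,
                       necrosis = FALSE, seed = 1L,
                       schedule = echo_schedule()) {
  bi_method <- match.arg(bi_method)
  structure(
    list(out_dir = out_dir, n_low = n_low, n_high = n_high, shape = shape,
         snr = snr, noise_model = noise_model, bi_method = bi_method,
         n_iterations = n_iterations, n_burnin = n_burnin,
         necrosis = necrosis, seed = as.integer(seed), schedule = schedule),
    class = "run_config")
}

#' Run the full relaxometry pipeline
#'
#' Orchestrates simulate -> fit-mono -> fit-bi -> summarize -> stats:
#' generates a synthetic cohort and one phantom per specimen, fits the
#' single-compartment map and the two-compartment maps, summarizes each
#' specimen's ROI, and produces the group-comparison/correlation report.
#' All artifacts (cohort and records CSVs, report CSVs, manifest JSON) are
#' written under `config$out_dir`; a stage whose output file already exists
#' is skipped when `resume = TRUE`. The run is deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @param resume Reuse existing stage outputs instead of recomputing.
#' @return List with `cohort`, `records` (tibbles), `report`
#'   (`t2_report`) and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  records_path <- file.path(config$out_dir, "records.csv")
  report_path <- file.path(config$out_dir, "report.csv")

  # stage 1: simulate the cohort table
  if (resume && file.exists(cohort_path)) {
    cohort <- tibble::as_tibble(utils::read.csv(cohort_path))
    cohort$group <- factor(cohort$group, levels = c("low", "high"))
  } else {
    cohort <- make_cohort(config$n_low, config$n_high,
                          seed = derive_seed(config$seed, 1L))
    utils::write.csv(cohort, cohort_path, row.names = FALSE)
  }

  # stages 2-4: per-specimen phantom, fits, ROI summary
  if (resume && file.exists(records_path)) {
    records <- tibble::as_tibble(utils::read.csv(records_path))
    records$group <- factor(records$group, levels = c("low", "high"))
  } else {
    records <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      rec <- cohort[i, ]
      ph <- specimen_phantom(
        rec, shape = config$shape, snr = config$snr,
        noise_model = config$noise_model, necrosis = config$necrosis,
        schedule = config$schedule, seed = derive_seed(config$seed, 2L, i))
      mono <- fit_mono_image(ph$signal, ph$tumour_mask, ph$schedule)
      bi <- if (config$bi_method == "bayes") {
        fit_bi_bayes_image(
          ph$signal, ph$tumour_mask, ph$schedule,
          bi_fit_config(n_iterations = config$n_iterations,
                        n_burnin = config$n_burnin,
                        seed = derive_seed(config$seed, 3L, i)))
      } else {
        fit_bi_image(ph$signal, ph$tumour_mask, ph$schedule,
                     seed = derive_seed(config$seed, 3L, i))
      }
      summarize_specimen(mono, bi, ph$tumour_mask, ph$necrosis_mask,
                         specimen_id = rec$specimen_id, clinical = rec)
    })
    utils::write.csv(records, records_path, row.names = FALSE)
  }

  # stage 5: statistics report
  report <- build_report(records)
  write_report(report, report_path)

  manifest <- list(
    package = "t2relax",
    version = as.character(utils::packageVersion("t2relax")),
    seed = config$seed,
    n_low = config$n_low, n_high = config$n_high,
    shape = config$shape, snr = if (is.infinite(config$snr)) "Inf" else config$snr,
    noise_model = config$noise_model, bi_method = config$bi_method,
    n_iterations = config$n_iterations,
    files = list(cohort = cohort_path, records = records_path,
                 report = report_path)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(cohort = cohort, records = records, report = report,
       manifest = manifest)
}
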