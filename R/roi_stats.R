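#' ROI mean of a parameter map with necrosis exclusion
#'
#' Arithmetic mean of a voxel-wise map over the effective region of
#' interest: tumour mask minus necrotic regions minus voxels with invalid
#' (non-finite or non-converged) fits. This is the whole-tumour summary
#' used for every relaxometry outcome.
#'
#' @param map 3-D numeric array.
#' @param tumour_mask 3-D 0/1 or logical array on the map's grid.
#' @param necrosis_mask Optional 3-D mask of necrotic voxels to exclude.
#' @param valid_mask Optional 3-D mask of voxels whose fit is valid
#'   (e.g. a `converged_mask`); non-finite map values are always excluded.
#' @return A scalar mean; errors if the effective ROI is empty.
#' @export
roi_mean <- function(map, tumour_mask, necrosis_mask = NULL,
                     valid_mask = NULL) {
  stopifnot(identical(dim(map), dim(tumour_mask)))
  eff <- as.logical(tumour_mask)
  if (!is.null(necrosis_mask)) {
    stopifnot(identical(dim(necrosis_mask), dim(map)))
    eff <- eff & !as.logical(necrosis_mask)
  }
  if (!is.null(valid_mask)) {
    stopifnot(identical(dim(valid_mask), dim(map)))
    eff <- eff & as.logical(valid_mask)
  }
  eff <- eff & is.finite(map)
  if (!any(eff)) stop("effective ROI is empty", call. = FALSE)
  mean(map[eff])
}

#' Whole-tumour volume ratio (intra-cellular fraction, percent)
#'
#' The volume ratio is the intra-cellular volume against the combined
#' intra- and extra-cellular volumes. Per voxel this is exactly the signal
#' fraction `f` of the two-compartment fit, so the whole-tumour value is
#' 100 times the ROI mean of the `f` map over the effective ROI.
#'
#' @param f_map 3-D array of per-voxel intra-cellular fractions in \[0, 1\].
#' @inheritParams roi_mean
#' @return Percent in \[0, 100\].
#' @export
volume_ratio <- function(f_map, tumour_mask, necrosis_mask = NULL,
                         valid_mask = NULL) {
  100 * roi_mean(f_map, tumour_mask, necrosis_mask, valid_mask)
}

#' Dichotomize Ki-67 proliferation index
#'
#' Tumours with strictly more than 14 % of cell nuclei staining positive
#' for Ki-67 are classed as high proliferative activity; 14 % exactly is
#' low.
#'
#' @param ki67_pct Numeric vector of Ki-67 percentages in \[0, 100\].
#' @return Character vector, `"low"` or `"high"`.
#' @export
#' @examples
#' classify_ki67(c(4.96, 14, 49.18))
classify_ki67 <- function(ki67_pct) {
  if (any(!is.finite(ki67_pct)) || any(ki67_pct < 0) || any(ki67_pct > 100)) {
    stop("`ki67_pct` must lie in [0, 100]", call. = FALSE)
  }
  ifelse(ki67_pct > 14, "high", "low")
}

#' Summarize one specimen's fitted maps into a record row
#'
#' Collapses a mono fit and a two-compartment fit into the per-specimen
#' ROI summary: mean T2,MONO, T2S, T2L (ms) and the volume ratio (percent)
#' over the tumour with necrosis and failed-fit voxels excluded, joined
#' with the clinical covariates and the Ki-67 group label. The number of
#' excluded voxels is recorded.
#'
#' @param mono A `mono_fit` for the specimen.
#' @param bi A `bi_fit` for the specimen.
#' @param tumour_mask,necrosis_mask Masks on the image grid.
#' @param specimen_id Identifier string.
#' @param clinical Optional one-row data frame / list with `ki67_pct` and
#'   optionally `diameter_mm`, `npi`, `grade`.
#' @return A one-row tibble (a `SpecimenRecord`): `specimen_id`,
#'   `t2_mono_ms`, `t2s_ms`, `t2l_ms`, `f_pct`, clinical columns, `group`,
#'   and `n_excluded` (voxels dropped from the ROI mean).
#' @export
summarize_specimen <- function(mono, bi, tumour_mask, necrosis_mask = NULL,
                               specimen_id = "S01", clinical = NULL) {
  stopifnot(inherits(mono, "mono_fit"), inherits(bi, "bi_fit"))
  valid_mono <- mono$converged_mask
  valid_bi <- if (is.null(bi$converged_mask)) NULL else bi$converged_mask
  eff <- as.logical(tumour_mask)
  if (!is.null(necrosis_mask)) eff <- eff & !as.logical(necrosis_mask)
  n_excluded <- sum(eff) - sum(eff & valid_mono & is.finite(mono$t2_map))

  rec <- tibble::tibble(
    specimen_id = specimen_id,
    t2_mono_ms = roi_mean(mono$t2_map, tumour_mask, necrosis_mask, valid_mono),
    t2s_ms = roi_mean(bi$t2s_map, tumour_mask, necrosis_mask, valid_bi),
    t2l_ms = roi_mean(bi$t2l_map, tumour_mask, necrosis_mask, valid_bi),
    f_pct = volume_ratio(bi$f_map, tumour_mask, necrosis_mask, valid_bi),
    n_excluded = n_excluded
  )
  if (!is.null(clinical)) {
    clin <- tibble::as_tibble(as.list(clinical)[
      intersect(c("ki67_pct", "diameter_mm", "npi", "grade"),
                names(clinical))])
    rec <- dplyr::bind_cols(rec, clin)
    if (!is.null(clin$ki67_pct)) {
      rec$group <- factor(classify_ki67(clin$ki67_pct),
                          levels = c("low", "high"))
    }
  }
  rec
}
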