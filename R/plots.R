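map_tibble <- function(map, mask, value_name) {
  idx <- which(mask > 0, arr.ind = TRUE)
  tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                 value = map[idx], parameter = value_name)
}

#' Plot fitted parameter maps
#'
#' Raster view of the in-mask voxel estimates of a fit (one facet per
#' parameter, first slice by default).
#'
#' @param object A `mono_fit` or `bi_fit`.
#' @param slice Slice (z index) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bi_fit <- function(object, slice = 1, ...) {
  df <- dplyr::bind_rows(
    map_tibble(object$f_map, object$mask, "f"),
    map_tibble(object$t2s_map, object$mask, "T2S (ms)"),
    map_tibble(object$t2l_map, object$mask, "T2L (ms)")
  )
  df <- dplyr::filter(df, .data$z == slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Two-compartment maps (%s)", object$method),
                  x = NULL, y = NULL)
}

#' @rdname autoplot.bi_fit
#' @export
autoplot.mono_fit <- function(object, slice = 1, ...) {
  df <- dplyr::filter(map_tibble(object$t2_map, object$mask, "T2,MONO (ms)"),
                      .data$z == slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Overall T2 map", fill = "T2 (ms)",
                  x = NULL, y = NULL)
}

#' Plot the group comparison of a statistics report
#'
#' One panel per relaxometry outcome: specimen values by Ki-67 group with
#' the group mean +/- SD overlaid, the layout used to present the group
#' contrasts.
#'
#' @param object A `t2_report`.
#' @param records The specimen records the report was built from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t2_report <- function(object, records, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(records, "group", dplyr::all_of(OUTCOMES)),
    -"group", names_to = "outcome", values_to = "value")
  long$outcome <- factor(outcome_labels[long$outcome],
                         levels = unname(outcome_labels))
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$outcome, .data$group),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "Ki-67 group", y = NULL)
}
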