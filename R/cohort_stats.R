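OUTCOMES <- c("t2_mono_ms", "t2s_ms", "t2l_ms", "f_pct")

outcome_labels <- c(
  t2_mono_ms = "T2,MONO (ms)", t2s_ms = "T2S (ms)",
  t2l_ms = "T2L (ms)", f_pct = "f (%)"
)

#' Normality gate for the two-group comparison
#'
#' Shapiro-Wilk test applied to each group separately; the comparison is
#' routed to the parametric branch (t-test, Pearson) only when both groups
#' are compatible with normality at `alpha`, otherwise to the
#' nonparametric branch (Mann-Whitney U, Spearman).
#'
#' @param low,high Numeric vectors (each n >= 3, non-constant).
#' @param alpha Gate level. Default 0.05.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(low, high, alpha = 0.05) {
  for (g in list(low, high)) {
    if (length(g) < 3) stop("each group needs n >= 3 for the normality gate",
                            call. = FALSE)
    if (stats::sd(g) == 0) stop("constant-valued group: normality undefined",
                                call. = FALSE)
  }
  p_low <- stats::shapiro.test(low)$p.value
  p_high <- stats::shapiro.test(high)$p.value
  if (p_low >= alpha && p_high >= alpha) "parametric" else "nonparametric"
}

#' Two-group comparison routed by the normality gate
#'
#' Independent-sample Student t-test (pooled variance) on the parametric
#' route, Mann-Whitney U on the nonparametric route; always two-sided.
#' The Mann-Whitney p-value is exact for combined n <= 25 without ties,
#' with the normal approximation and tie correction otherwise.
#'
#' @param low,high Numeric vectors (each n >= 2).
#' @param route `"parametric"`, `"nonparametric"`, or `NULL` to apply
#'   [normality_gate()].
#' @param welch Use the Welch (unequal-variance) t-test instead of Student.
#' @return A one-row tibble: `test` ("t" or "mann-whitney"), `statistic`,
#'   `p_value`, `route`.
#' @export
compare_groups <- function(low, high, route = NULL, welch = FALSE) {
  if (length(low) < 2 || length(high) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (is.null(route)) route <- normality_gate(low, high)
  route <- match.arg(route, c("parametric", "nonparametric"))
  if (route == "parametric") {
    ht <- stats::t.test(low, high, var.equal = !welch)
    tibble::tibble(test = "t", statistic = unname(ht$statistic),
                   p_value = ht$p.value, route = route)
  } else {
    exact <- (length(low) + length(high)) <= 25
    ht <- suppressWarnings(
      stats::wilcox.test(low, high, exact = exact, correct = !exact))
    tibble::tibble(test = "mann-whitney", statistic = unname(ht$statistic),
                   p_value = ht$p.value, route = route)
  }
}

#' Correlation of an outcome against a clinical covariate
#'
#' Pearson's r on the parametric route, Spearman's rank rho on the
#' nonparametric route. In the study design this package follows,
#' correlations against tumour diameter are routed by normality of the
#' outcome, while correlations against NPI are always Spearman.
#'
#' @param outcome,covariate Paired numeric vectors (n >= 4, non-constant).
#' @param route `"parametric"` (Pearson) or `"nonparametric"` (Spearman).
#' @return One-row tibble: `type` ("pearson"/"spearman"), `estimate`,
#'   `p_value`.
#' @export
correlate <- function(outcome, covariate,
                      route = c("parametric", "nonparametric")) {
  route <- match.arg(route)
  if (length(outcome) != length(covariate)) {
    stop("`outcome` and `covariate` must be paired", call. = FALSE)
  }
  if (length(outcome) < 4) stop("need n >= 4 pairs", call. = FALSE)
  if (stats::sd(outcome) == 0 || stats::sd(covariate) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  method <- if (route == "parametric") "pearson" else "spearman"
  ht <- suppressWarnings(
    stats::cor.test(outcome, covariate, method = method, exact = FALSE))
  tibble::tibble(type = method, estimate = unname(ht$estimate),
                 p_value = ht$p.value)
}

#' Build the relaxometry statistics report
#'
#' The full statistics stage over a table of specimen records: for each of
#' the four relaxometry outcomes (volume ratio f, T2,MONO, T2L, T2S),
#' group mean +/- SD per Ki-67 group, a normality-gated two-group test, and
#' normality-routed correlations against tumour diameter plus Spearman
#' correlations against NPI. No multiple-testing correction is applied
#' (each test is read at `alpha`), matching the design this package
#' reproduces.
#'
#' @param records Tibble of specimen records with columns `group`
#'   (low/high) and the four outcomes; `diameter_mm` and `npi` enable the
#'   correlation block.
#' @param alpha Significance level. Default 0.05.
#' @param welch Use Welch instead of Student t-tests.
#' @return A `t2_report` object holding two tibbles: `comparisons` (one
#'   row per outcome: group means/SDs, test, p-value, significance flag)
#'   and `correlations` (one row per outcome x covariate).
#' @export
#' @examples
#' build_report(make_cohort(seed = 1))
build_report <- function(records, alpha = 0.05, welch = FALSE) {
  missing_cols <- setdiff(c("group", OUTCOMES), names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  grp <- as.character(records$group)
  if (sum(grp == "low") < 2 || sum(grp == "high") < 2) {
    stop("need >= 2 specimens per group", call. = FALSE)
  }

  comparisons <- purrr::map_dfr(OUTCOMES, function(oc) {
    lo <- records[[oc]][grp == "low"]
    hi <- records[[oc]][grp == "high"]
    # groups too small for the Shapiro-Wilk gate go down the rank-based route
    route <- if (length(lo) < 3 || length(hi) < 3) "nonparametric" else {
      normality_gate(lo, hi, alpha)
    }
    cmp <- compare_groups(lo, hi, route = route, welch = welch)
    tibble::tibble(
      outcome = oc, label = outcome_labels[[oc]],
      low_mean = mean(lo), low_sd = stats::sd(lo),
      high_mean = mean(hi), high_sd = stats::sd(hi),
      test = cmp$test, statistic = cmp$statistic,
      p_value = cmp$p_value, significant = cmp$p_value < alpha
    )
  })

  correlations <- NULL
  covars <- intersect(c("diameter_mm", "npi"), names(records))
  if (length(covars) > 0) {
    correlations <- purrr::map_dfr(OUTCOMES, function(oc) {
      purrr::map_dfr(covars, function(cv) {
        if (cv == "npi") {
          route <- "nonparametric"  # NPI correlations are always Spearman
        } else {
          sw <- stats::shapiro.test(records[[oc]])$p.value
          route <- if (sw >= alpha) "parametric" else "nonparametric"
        }
        ct <- correlate(records[[oc]], records[[cv]], route)
        tibble::tibble(outcome = oc, covariate = cv, type = ct$type,
                       estimate = ct$estimate, p_value = ct$p_value,
                       significant = ct$p_value < alpha)
      })
    })
  }

  structure(list(comparisons = comparisons, correlations = correlations,
                 alpha = alpha,
                 n_low = sum(grp == "low"), n_high = sum(grp == "high")),
            class = "t2_report")
}

#' @export
print.t2_report <- function(x, ...) {
  cat(sprintf("Relaxometry report (n = %d low / %d high Ki-67, alpha = %g)\n\n",
              x$n_low, x$n_high, x$alpha))
  cm <- x$comparisons
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  %-12s low %6.2f +/- %5.2f | high %6.2f +/- %5.2f | %s p = %.3f%s\n",
                cm$label[i], cm$low_mean[i], cm$low_sd[i],
                cm$high_mean[i], cm$high_sd[i], cm$test[i], cm$p_value[i],
                ifelse(cm$significant[i], " *", "")))
  }
  if (!is.null(x$correlations)) {
    cat("\n  correlations:\n")
    cr <- x$correlations
    for (i in seq_len(nrow(cr))) {
      cat(sprintf("  %-12s vs %-11s %s = %+.2f, p = %.3f%s\n",
                  outcome_labels[[cr$outcome[i]]], cr$covariate[i],
                  ifelse(cr$type[i] == "pearson", "r", "rho"),
                  cr$estimate[i], cr$p_value[i],
                  ifelse(cr$significant[i], " *", "")))
    }
  }
  invisible(x)
}

#' Tidy a statistics report
#'
#' @param x A `t2_report`.
#' @param ... Unused.
#' @return A tibble combining the group-comparison and correlation rows
#'   (`contrast` column distinguishes them).
#' @export
tidy.t2_report <- function(x, ...) {
  cmp <- dplyr::mutate(x$comparisons, contrast = "ki67_group", .before = 1)
  if (is.null(x$correlations)) return(cmp)
  cor_rows <- dplyr::transmute(
    x$correlations,
    contrast = paste0("cor_", .data$covariate), outcome = .data$outcome,
    test = .data$type, statistic = .data$estimate,
    p_value = .data$p_value, significant = .data$significant)
  dplyr::bind_rows(cmp, cor_rows)
}

#' @rdname tidy.t2_report
#' @export
glance.t2_report <- function(x, ...) {
  tibble::tibble(
    n_low = x$n_low, n_high = x$n_high, alpha = x$alpha,
    n_outcomes = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant),
    min_p = min(x$comparisons$p_value)
  )
}

#' Write a report to CSV files
#'
#' @param x A `t2_report`.
#' @param path Output CSV path for the comparison table; correlations (if
#'   present) go to `<path stem>_correlations.csv`.
#' @return `path` invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "t2_report"))
  utils::write.csv(x$comparisons, path, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cor_path <- sub("\\.csv$", "_correlations.csv", path)
    utils::write.csv(x$correlations, cor_path, row.names = FALSE)
  }
  invisible(path)
}
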