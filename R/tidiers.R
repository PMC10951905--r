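#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted pipeline: bins and targets
#'
#' @param x A `cpie_model`.
#' @param ... Unused.
#' @return Tibble with one row per bin: interval bounds and target T1 (ms).
#' @method tidy cpie_model
#' @export
tidy.cpie_model <- function(x, ...) {
  brk <- x$partition$breaks
  tibble::tibble(
    bin = seq_len(x$partition$n_bins),
    lower = c(-Inf, brk),
    upper = c(brk, Inf),
    target_ms = x$per_bin_targets
  )
}

#' @rdname tidy.cpie_model
#' @method glance cpie_model
#' @export
glance.cpie_model <- function(x, ...) {
  s <- x$setting
  tibble::tibble(
    regression_type = s$regression_type, y_type = s$y_type, mode = s$mode,
    n_bins = s$n_bins, cluster_type = s$cluster_type, seed = s$seed,
    n_cps = length(x$cps),
    n_train_records = x$training_fingerprint$n_records %||% NA_integer_,
    n_train_pixels = x$training_fingerprint$n_pixels %||% NA_integer_,
    n_uncovered_notes = length(x$uncovered)
  )
}

#' Tidy a grid-search report: one row per evaluated setting
#'
#' @param x A `grid_search_report`.
#' @param ... Unused.
#' @method tidy grid_search_report
#' @export
tidy.grid_search_report <- function(x, ...) dplyr::bind_rows(x$stage1, x$stage2)

#' @rdname tidy.grid_search_report
#' @method glance grid_search_report
#' @export
glance.grid_search_report <- function(x, ...) {
  b <- x$bpsp
  tibble::tibble(
    n_stage1 = nrow(x$stage1), n_stage2 = nrow(x$stage2),
    n_settings = nrow(x$stage1) + nrow(x$stage2),
    baseline_cov = x$baseline_cov,
    bpsp_cov = if (is.null(b)) NA_real_ else b$cov,
    bpsp_regression_type = if (is.null(b)) NA_character_ else b$setting$regression_type,
    bpsp_y_type = if (is.null(b)) NA_character_ else b$setting$y_type,
    bpsp_mode = if (is.null(b)) NA_character_ else b$setting$mode,
    bpsp_n_bins = if (is.null(b)) NA_integer_ else b$setting$n_bins,
    bpsp_cluster_type = if (is.null(b)) NA_character_ else b$setting$cluster_type
  )
}

#' Tidy an ROC result: the full curve
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, sensitivity = x$sensitivity,
                 specificity = x$specificity, auc = x$auc, evidence = x$evidence,
                 n_negative = x$n_negative, n_positive = x$n_positive)
}

#' Tidy a cohort comparison: pairwise results
#'
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @method tidy cohort_comparison
#' @export
tidy.cohort_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.cohort_comparison
#' @method glance cohort_comparison
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble::tibble(route = x$route, omnibus_p = x$omnibus_p, alpha = x$alpha,
                 n_groups = length(x$shapiro_p))
}

#' Plot COV against pipeline setting for a grid search
#'
#' Mirrors the usual presentation: COV (percent) per evaluated setting over
#' the number of bins, with the unstandardised baseline as a horizontal
#' line; everything above the line worsened the healthy test-set spread.
#'
#' @param object A `grid_search_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grid_search_report
#' @export
autoplot.grid_search_report <- function(object, ...) {
  tab <- tidy(object) |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::mutate(setting = paste(.data$regression_type, .data$y_type, sep = "/"))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_bins, y = 100 * .data$cov,
                                         colour = .data$setting, shape = .data$mode)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 100 * object$baseline_cov, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = sort(unique(tab$n_bins))) +
    ggplot2::labs(x = "bins", y = "COV of mean T1 in healthy test set [%]",
                  colour = "regression/y-type", shape = "mode",
                  title = "Pipeline grid search",
                  subtitle = "dashed line: unstandardised baseline COV")
  if (!is.null(object$bpsp)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 * object$bpsp$cov,
                                 colour = "darkgreen", linetype = "dotted")
  }
  p
}

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  cv <- dplyr::arrange(object$curve, dplyr::desc(.data$threshold))
  ggplot2::ggplot(cv, ggplot2::aes(x = 100 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = 100 - object$specificity, y = object$sensitivity,
                      colour = "darkgreen", size = 3) +
    ggplot2::labs(x = "100 - specificity [%]", y = "sensitivity [%]",
                  title = sprintf("ROC: AUC %.3f, threshold %.1f ms", object$auc, object$threshold))
}

#' Before/after progression plot of standardisation results
#'
#' Per-map mean T1 before and after standardisation, connected per map and
#' summarised per cohort with boxplots.
#'
#' @param results List of `standardisation_result` objects.
#' @return A ggplot object.
#' @export
plot_progression <- function(results) {
  tab <- purrr::map_dfr(results, function(r) {
    tibble::tibble(map_id = r$map_id, cohort = r$cohort,
                   before = r$mean_before, after = r$mean_after)
  }) |>
    tidyr::pivot_longer(c("before", "after"), names_to = "phase", values_to = "mean_t1") |>
    dplyr::mutate(phase = factor(.data$phase, levels = c("before", "after")))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$phase, y = .data$mean_t1)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$map_id, colour = .data$cohort), alpha = 0.4) +
    ggplot2::geom_boxplot(ggplot2::aes(fill = .data$cohort), alpha = 0.4, width = 0.3,
                          outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "mean segmented T1 [ms]",
                  title = "Standardisation progression")
}
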