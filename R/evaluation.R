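#' Summary statistics with a 95% confidence interval
#'
#' Mean, sample standard deviation, coefficient of variation and a
#' two-sided t-based confidence interval of the mean.
#'
#' @param values Numeric vector, n >= 2.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `n`, `mean`, `sd`, `cov`, `ci_low`, `ci_high`.
#' @export
summarise_values <- function(values, conf_level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) abort_input("summarise_values needs n >= 2 NA-free values")
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  tibble::tibble(n = n, mean = m, sd = s, cov = coef_variation(values),
                 ci_low = m - half, ci_high = m + half)
}

#' Compare cohorts with normality-routed tests
#'
#' Every group is checked with the Shapiro-Wilk test; if all groups are
#' normal at `alpha`, the parametric route is taken (pairwise independent
#' t-tests and an ANOVA omnibus), otherwise the nonparametric route
#' (pairwise Mann-Whitney-U and a Kruskal-Wallis omnibus). A pair counts as
#' significantly different only if both its pairwise p-value and the omnibus
#' p-value are at or below `alpha`. Constant groups (where the normality
#' test is undefined) route the comparison to the nonparametric tests with a
#' warning.
#'
#' @param groups Named list of at least two numeric vectors, each n >= 3.
#' @param alpha Significance level (default 0.05).
#' @return A `cohort_comparison` with the route, omnibus p-value and a
#'   tibble of pairwise results.
#' @export
compare_cohorts <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) abort_input("groups must be a list of >= 2 cohorts")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  lens <- lengths(groups)
  if (any(lens < 3)) abort_input("every cohort needs n >= 3")

  shapiro_p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) NA_real_ else stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (anyNA(shapiro_p)) {
    warning("constant cohort: normality test undefined; using nonparametric tests", call. = FALSE)
  }
  parametric <- !anyNA(shapiro_p) && all(shapiro_p > alpha)

  stacked <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lens), levels = names(groups))
  )
  omnibus_p <- if (parametric) {
    summary(stats::aov(value ~ group, data = stacked))[[1]][["Pr(>F)"]][1]
  } else {
    stats::kruskal.test(value ~ group, data = stacked)$p.value
  }

  pairs <- utils::combn(names(groups), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- if (parametric) {
      stats::t.test(groups[[a]], groups[[b]], var.equal = TRUE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(groups[[a]], groups[[b]])$p.value)
    }
    tibble::tibble(group1 = a, group2 = b, p_value = p,
                   significant = p <= alpha && omnibus_p <= alpha)
  })

  structure(
    list(route = if (parametric) "parametric" else "nonparametric",
         shapiro_p = shapiro_p, omnibus_p = omnibus_p, pairwise = pairwise,
         alpha = alpha),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison> route: ", x$route,
      ", omnibus p = ", signif(x$omnibus_p, 3), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' ROC analysis with Youden-optimal threshold and the 150% evidence rule
#'
#' A value is classified positive when it is at or above the threshold
#' (disease raises native T1). Candidate thresholds are the midpoints
#' between consecutive sorted pooled unique values, plus -Inf and +Inf; the
#' reported threshold maximises Youden's J = sensitivity + specificity -
#' 100%, with ties resolved to the lowest threshold. The AUC uses the
#' rank-sum (Mann-Whitney) formulation with ties counted one half. Evidence
#' for diagnostic discrimination is assumed when sensitivity + specificity
#' reaches 150% or more.
#'
#' @param negative,positive Nonempty numeric vectors (positives expected
#'   higher).
#' @return A `roc_result`: `threshold` (ms), `sensitivity` and `specificity`
#'   (percent), `auc` (fraction), `evidence` (logical) and the full `curve`
#'   tibble.
#' @export
roc_analysis <- function(negative, positive) {
  negative <- as.numeric(negative); positive <- as.numeric(positive)
  if (length(negative) == 0 || length(positive) == 0) {
    abort_input("both negative and positive samples must be nonempty")
  }
  u <- sort(unique(c(negative, positive)))
  thr <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) 100 * mean(positive >= t), numeric(1)),
    specificity = vapply(thr, function(t) 100 * mean(negative < t), numeric(1))
  )
  curve$youden_j <- curve$sensitivity + curve$specificity - 100
  best <- which(curve$youden_j == max(curve$youden_j))[1]  # thresholds ascending: first = lowest

  r <- rank(c(negative, positive))  # average ranks: ties count 1/2
  n0 <- length(negative); n1 <- length(positive)
  auc <- (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)

  structure(
    list(threshold = curve$threshold[best],
         sensitivity = curve$sensitivity[best],
         specificity = curve$specificity[best],
         auc = auc,
         evidence = (curve$sensitivity[best] + curve$specificity[best]) >= 150,
         curve = curve, n_negative = n0, n_positive = n1),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> threshold ", round(x$threshold, 2), " ms: sensitivity ",
      sprintf("%.2f%%", x$sensitivity), ", specificity ", sprintf("%.2f%%", x$specificity),
      ", AUC ", round(x$auc, 4), ", evidence (>=150%): ", x$evidence, "\n", sep = "")
  invisible(x)
}

#' Intra-subject progression of COV before and after standardisation
#'
#' For subjects measured in several CP environments, the COV over the
#' subject's per-map mean T1 values quantifies how far the repeated
#' acquisitions spread; standardisation should concentrate them.
#'
#' @param results List of `standardisation_result` objects (or a tibble with
#'   columns `subject_id`, `map_id`, `mean_before`, `mean_after`).
#' @return A tibble per subject: `n_maps`, `cov_before`, `cov_after`;
#'   subjects with a single map are excluded and listed in the
#'   `excluded` attribute.
#' @export
intra_subject_progression <- function(results) {
  tab <- if (inherits(results, "data.frame")) {
    tibble::as_tibble(results)
  } else {
    purrr::map_dfr(results, function(r) {
      tibble::tibble(subject_id = r$subject_id, map_id = r$map_id,
                     mean_before = r$mean_before, mean_after = r$mean_after)
    })
  }
  per <- tab |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_maps = dplyr::n(),
                     cov_before = if (dplyr::n() >= 2) coef_variation(.data$mean_before) else NA_real_,
                     cov_after = if (dplyr::n() >= 2) coef_variation(.data$mean_after) else NA_real_,
                     .groups = "drop")
  excluded <- per$subject_id[per$n_maps < 2]
  out <- dplyr::filter(per, .data$n_maps >= 2)
  attr(out, "excluded") <- excluded
  out
}
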