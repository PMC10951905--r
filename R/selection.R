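#' Coefficient of variation
#'
#' COV = sigma / mu with the sample (n-1) standard deviation. Used as the
#' inter-subject variability measure when ranking pipeline settings: the
#' lower the COV of per-map mean T1 across the healthy test set, the better
#' the harmonisation.
#'
#' @param values Nonempty numeric vector with nonzero mean.
#' @return COV as a fraction (multiply by 100 for percent).
#' @export
#' @examples
#' coef_variation(c(1000, 1100, 1200)) # 0.0909...
coef_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) abort_computation("COV needs nonempty, NA-free values")
  m <- mean(values)
  if (m == 0) abort_computation("COV undefined: mean is zero")
  stats::sd(values) / m
}

#' Evaluate a fitted pipeline by COV on a held-out healthy test set
#'
#' Standardises every test map and returns the COV of the per-map mean
#' standardised T1 values. With `per_subject = TRUE` the per-map means are
#' first averaged within subject, so the COV is across subjects.
#'
#' @param model A fitted `cpie_model`.
#' @param test Nonempty list of [t1_map] records.
#' @param per_subject Average per-map means within subject first?
#' @return COV (fraction).
#' @export
evaluate_pipeline <- function(model, test, per_subject = FALSE) {
  if (length(test) == 0) abort_input("test set is empty")
  results <- standardise(model, test)
  means <- vapply(results, `[[`, numeric(1), "mean_after")
  if (per_subject) {
    subj <- vapply(test, `[[`, character(1), "subject_id")
    means <- tapply(means, subj, mean)
  }
  coef_variation(as.numeric(means))
}

baseline_cov <- function(test, per_subject = FALSE) {
  means <- vapply(test, function(r) mean(segmented_values(r)), numeric(1))
  if (per_subject) {
    subj <- vapply(test, `[[`, character(1), "subject_id")
    means <- tapply(means, subj, mean)
  }
  coef_variation(as.numeric(means))
}

#' Enumerate the settings of the two-step pipeline grid
#'
#' Stage 1 fixes bins at one (so the cluster type has no effect) and crosses
#' all regression types, y types and modes: 4 x 2 x 3 = 24 settings. Stage 2
#' crosses the top-performing stage-1 settings with bins 2-10 and all eight
#' cluster types: 3 x 9 x 8 = 216 further settings, 240 in total.
#'
#' @param regression_types,y_types,modes,bins,clusters Option sets; defaults
#'   are the full grid.
#' @return `grid_stage1_plan()`: a tibble of stage-1 settings in enumeration
#'   order (regression type, then y type, then mode). `grid_stage2_plan()`:
#'   the stage-2 tibble for the given top settings.
#' @export
grid_stage1_plan <- function(regression_types = c("linear", "lsvr", "rfr", "etr"),
                             y_types = c("absolute", "relative"),
                             modes = c("individual", "cascaded", "ensemble")) {
  tidyr::expand_grid(regression_type = regression_types, y_type = y_types, mode = modes) |>
    dplyr::mutate(n_bins = 1L, cluster_type = "equal_distant", stage = 1L)
}

#' @rdname grid_stage1_plan
#' @param top Tibble of settings (rows of a stage-1 plan) to refine.
#' @export
grid_stage2_plan <- function(top, bins = 2:10, clusters = cluster_types()) {
  grid <- tidyr::expand_grid(idx = seq_len(nrow(top)), n_bins = as.integer(bins),
                             cluster_type = clusters)
  tibble::tibble(
    regression_type = top$regression_type[grid$idx],
    y_type = top$y_type[grid$idx], mode = top$mode[grid$idx],
    n_bins = grid$n_bins, cluster_type = grid$cluster_type, stage = 2L
  )
}

#' Two-step grid search for the best performing standardisation pipeline
#'
#' Fits and evaluates every setting of the two-step grid (24 stage-1
#' settings at one bin; the top `top_n` of them crossed with bins 2-10 and
#' all eight cluster types, 216 stage-2 settings by default). The best
#' performing standardisation pipeline (BPSP) is the setting with the lowest
#' COV of per-map mean T1 on the held-out healthy test set. Settings whose
#' fit or evaluation fails (e.g. an ensemble model facing an unseen
#' category) are flagged and excluded from ranking rather than aborting the
#' sweep; stage-1 ties are broken by enumeration order.
#'
#' @param train,test Healthy training and test record lists.
#' @param cps CP definitions.
#' @param cp_order,seed Passed to every [pipeline_setting()].
#' @param regression_types,y_types,modes,bins,clusters Option sets (defaults:
#'   the full 240-setting grid).
#' @param top_n Number of stage-1 settings refined in stage 2.
#' @param per_subject Passed to [evaluate_pipeline()].
#' @param keep_bpsp_model Refit nothing: the winning fitted model is kept on
#'   the report (`$bpsp_model`).
#' @return A `grid_search_report`: tibbles `stage1` and `stage2` (setting
#'   fields, COV, status, worsened-vs-baseline flag), `baseline_cov`, `bpsp`
#'   (winning setting + COV) and `bpsp_model`.
#' @export
grid_search <- function(train, test, cps = default_cps(), cp_order = NULL, seed = 1L,
                        regression_types = c("linear", "lsvr", "rfr", "etr"),
                        y_types = c("absolute", "relative"),
                        modes = c("individual", "cascaded", "ensemble"),
                        bins = 2:10, clusters = cluster_types(),
                        top_n = 3L, per_subject = FALSE, keep_bpsp_model = TRUE) {
  cps <- validate_cp_set(cps)
  base_cov <- baseline_cov(test, per_subject)
  pooled <- pixel_frame(train)$value
  part_cache <- new.env(parent = emptyenv())
  get_partition <- function(n_bins, cluster_type) {
    if (n_bins == 1L) return(fit_partition(pooled, 1L, cluster_type, seed))
    key <- paste(n_bins, cluster_type)
    if (is.null(part_cache[[key]])) {
      part_cache[[key]] <- fit_partition(pooled, n_bins, cluster_type, seed)
    }
    part_cache[[key]]
  }

  best <- list(cov = Inf, setting = NULL, model = NULL)
  run_plan <- function(plan) {
    rows <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      s <- pipeline_setting(plan$regression_type[i], plan$y_type[i], plan$mode[i],
                            n_bins = plan$n_bins[i], cluster_type = plan$cluster_type[i],
                            cp_order = cp_order, seed = seed)
      res <- tryCatch({
        part <- get_partition(s$n_bins, s$cluster_type)
        model <- fit_pipeline(train, s, cps, partition = part)
        cov <- evaluate_pipeline(model, test, per_subject)
        if (cov < best$cov) best <<- list(cov = cov, setting = s,
                                          model = if (keep_bpsp_model) model else NULL)
        list(cov = cov, status = "ok", note = NA_character_)
      }, error = function(e) list(cov = NA_real_, status = "failed", note = conditionMessage(e)))
      rows[[i]] <- tibble::tibble(
        regression_type = s$regression_type, y_type = s$y_type, mode = s$mode,
        n_bins = s$n_bins, cluster_type = s$cluster_type, stage = plan$stage[i],
        cov = res$cov, status = res$status,
        worsened = !is.na(res$cov) & res$cov > base_cov, note = res$note)
    }
    dplyr::bind_rows(rows)
  }

  stage1 <- run_plan(grid_stage1_plan(regression_types, y_types, modes))
  ok1 <- dplyr::filter(stage1, .data$status == "ok")
  if (nrow(ok1) < top_n) {
    warning("fewer than ", top_n, " stage-1 settings succeeded; stage 2 is truncated",
            call. = FALSE)
  }
  top <- dplyr::slice_head(dplyr::arrange(ok1, .data$cov), n = min(top_n, nrow(ok1)))
  stage2 <- if (nrow(top) > 0 && length(bins) > 0) {
    run_plan(grid_stage2_plan(top, bins, clusters))
  } else {
    stage1[0, ]
  }

  structure(
    list(stage1 = stage1, stage2 = stage2, baseline_cov = base_cov,
         bpsp = if (is.finite(best$cov)) list(setting = best$setting, cov = best$cov) else NULL,
         bpsp_model = best$model, top_settings = top, seed = seed),
    class = "grid_search_report"
  )
}

#' @export
print.grid_search_report <- function(x, ...) {
  cat("<grid_search_report> ", nrow(x$stage1), " stage-1 + ", nrow(x$stage2),
      " stage-2 settings\n", sep = "")
  cat("  baseline COV: ", sprintf("%.2f%%", 100 * x$baseline_cov), "\n", sep = "")
  if (!is.null(x$bpsp)) {
    cat("  BPSP: ", setting_label(x$bpsp$setting), " with COV ",
        sprintf("%.2f%%", 100 * x$bpsp$cov), "\n", sep = "")
  }
  invisible(x)
}

#' Write a grid-search report to disk
#'
#' One CSV row per evaluated setting plus a JSON summary naming the BPSP.
#'
#' @param report A `grid_search_report`.
#' @param csv_path Output CSV path.
#' @param json_path Optional output JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
write_grid_report <- function(report, csv_path, json_path = NULL) {
  tab <- generics::tidy(report)
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- list(baseline_cov = report$baseline_cov,
                 n_settings = nrow(tab),
                 bpsp = if (is.null(report$bpsp)) NULL else c(
                   report$bpsp$setting[c("regression_type", "y_type", "mode",
                                         "n_bins", "cluster_type")],
                   list(cov = report$bpsp$cov)))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
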