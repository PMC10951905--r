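#' T1 map records
#'
#' A `t1_map` bundles one parametric T1 map: the rescaled pixel grid in ms,
#' the same-grid binary myocardium mask, the extracted confounder values and
#' identifying metadata. The pixel grid is row-major with origin top-left;
#' masks must share the grid exactly (no resampling is performed).
#'
#' @param map_id,subject_id,cohort Identifiers; `cohort` is a free label
#'   (e.g. `"healthy"`, `"HCM"`, `"AMY"`).
#' @param pixels Numeric matrix of T1 values in ms.
#' @param mask Binary matrix of the same shape (nonzero = myocardium), or
#'   `NULL` if not yet attached.
#' @param cp_values Named list of confounder values, or `NULL`.
#' @param source_meta Named list of raw DICOM attributes kept for
#'   traceability.
#' @return An object of class `t1_map`.
#' @export
t1_map <- function(map_id, subject_id = map_id, cohort = NA_character_,
                   pixels, mask = NULL, cp_values = NULL, source_meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) abort_input("pixels must be a numeric matrix")
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !identical(dim(mask), dim(pixels))) {
      abort_input(paste0("mask shape (", paste(dim(mask), collapse = "x"),
                         ") must equal pixel shape (", paste(dim(pixels), collapse = "x"), ")"))
    }
    mask <- (mask != 0) * 1L
  }
  structure(
    list(map_id = as.character(map_id), subject_id = as.character(subject_id),
         cohort = as.character(cohort), pixels = pixels, mask = mask,
         cp_values = cp_values, source_meta = source_meta),
    class = "t1_map"
  )
}

#' @export
print.t1_map <- function(x, ...) {
  cat("<t1_map> ", x$map_id, " (subject ", x$subject_id, ", cohort ", x$cohort, "): ",
      nrow(x$pixels), "x", ncol(x$pixels), " px, ",
      if (is.null(x$mask)) "no mask" else paste0(sum(x$mask), " segmented px"), "\n", sep = "")
  if (!is.null(x$cp_values)) {
    cat("  CPs: ", paste(names(x$cp_values), unlist(lapply(x$cp_values, as.character)),
                         sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Segmented pixel values of a record
#'
#' @param record A [t1_map] with a mask.
#' @return Numeric vector of masked T1 values (ms).
#' @export
segmented_values <- function(record) {
  if (is.null(record$mask)) abort_input(paste0("record '", record$map_id, "' has no mask"))
  v <- record$pixels[record$mask != 0]
  if (length(v) == 0) abort_input(paste0("record '", record$map_id, "' has an empty mask"))
  if (!all(is.finite(v)) || any(v <= 0)) {
    abort_input(paste0("record '", record$map_id, "' has non-finite or non-positive segmented values"))
  }
  v
}

#' Read a parametric T1 map from a DICOM file
#'
#' Pixel values are rescaled to ms as `stored * RescaleSlope +
#' RescaleIntercept`; absent rescale attributes default to slope 1 and
#' intercept 0. The full metadata element set is retained in `source_meta`.
#'
#' @param dicom_path Path to a single-frame DICOM file.
#' @param map_id Identifier; defaults to the file name without extension.
#' @return A [t1_map] record (without mask, cohort and CP values).
#' @export
read_t1_map <- function(dicom_path, map_id = NULL) {
  d <- read_dicom(dicom_path)
  if (length(dim(d$pixels)) != 2L) abort_input(paste0("non-2-D pixel data in ", dicom_path))
  slope <- d$meta[["0028,1053"]] %||% 1
  intercept <- d$meta[["0028,1052"]] %||% 0
  pixels <- d$pixels * as.numeric(slope[1]) + as.numeric(intercept[1])
  id <- map_id %||% sub("\\.[^.]*$", "", basename(dicom_path))
  subj <- d$meta[["0010,0020"]] %||% id
  t1_map(map_id = id, subject_id = subj[1], pixels = pixels, source_meta = d$meta)
}

#' Read a binary segmentation mask from a PNG file
#'
#' The mask must be a lossless single-channel raster on exactly the same grid
#' as the T1 map; any nonzero sample is myocardium.
#'
#' @param mask_path Path to a PNG file.
#' @param target_shape Integer vector `c(rows, cols)` the mask must match.
#' @return Binary integer matrix (1 = myocardium).
#' @export
read_mask <- function(mask_path, target_shape) {
  if (!file.exists(mask_path)) abort_input(paste0("mask file does not exist: ", mask_path))
  img <- png::readPNG(mask_path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (!identical(as.integer(dim(img)), as.integer(target_shape))) {
    abort_input(paste0("mask shape (", paste(dim(img), collapse = "x"),
                       ") does not match target shape (",
                       paste(target_shape, collapse = "x"), "): ", mask_path))
  }
  (img != 0) * 1L
}

#' Load a cohort directory of DICOM maps and PNG masks
#'
#' Expects `<id>.dcm` + `<id>_mask.png` pairs, and optionally a `labels.csv`
#' with columns `map_id`, `subject_id`, `cohort`. CP vectors are extracted
#' from the DICOM metadata; records failing extraction are excluded with a
#' warning unless `strict = TRUE`, in which case the first failure aborts.
#'
#' @param dir Directory path.
#' @param cps CP definitions, see [default_cps()].
#' @param strict Abort on the first extraction failure?
#' @return List of [t1_map] records with masks and CP values attached.
#' @export
load_cohort <- function(dir, cps = default_cps(), strict = FALSE) {
  cps <- validate_cp_set(cps)
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) abort_input(paste0("no .dcm files in ", dir))
  labels <- NULL
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    labels <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  }
  out <- list()
  for (f in files) {
    id <- sub("\\.dcm$", "", basename(f))
    rec <- tryCatch({
      r <- read_t1_map(f, map_id = id)
      mp <- file.path(dir, paste0(id, "_mask.png"))
      if (file.exists(mp)) r$mask <- read_mask(mp, dim(r$pixels))
      if (!is.null(labels) && id %in% labels$map_id) {
        row <- labels[labels$map_id == id, , drop = FALSE][1, ]
        if ("subject_id" %in% names(row)) r$subject_id <- as.character(row$subject_id)
        if ("cohort" %in% names(row)) r$cohort <- as.character(row$cohort)
      }
      r$cp_values <- extract_cp_vector(r, cps)
      r
    }, t1stand_extraction_error = function(e) {
      if (strict) rlang::abort(conditionMessage(e), class = "t1stand_extraction_error")
      warning("excluding map '", id, "': ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(rec)) out[[id]] <- rec
  }
  out
}

#' Tabulate standardisation results
#'
#' One row per map: CP values, mean before, per-CP mean bias components and
#' mean after standardisation.
#'
#' @param results List of `standardisation_result` objects (see
#'   [standardise_map()]).
#' @return A tibble.
#' @export
result_table <- function(results) {
  if (length(results) == 0) abort_input("results must be nonempty")
  purrr::map_dfr(results, function(r) {
    row <- tibble::tibble(map_id = r$map_id, subject_id = r$subject_id,
                          cohort = r$cohort, n_pixels = length(r$values_original),
                          mean_before = r$mean_before)
    for (nm in names(r$cp_values)) row[[paste0("cp_", nm)]] <- as.character(r$cp_values[[nm]])
    for (nm in names(r$bias_components)) {
      row[[paste0("bias_", nm)]] <- mean(r$bias_components[[nm]])
    }
    row$mean_after <- r$mean_after
    row
  })
}

#' Write standardisation results to disk
#'
#' Writes a CSV table (one row per map, see [result_table()]) and a
#' machine-readable JSON container holding, per map, the CP values, the
#' original segmented pixel values, the per-CP bias components in CP order
#' and the standardised pixel values.
#'
#' @param results Nonempty list of `standardisation_result` objects.
#' @param csv_path Output CSV path.
#' @param container_path Optional output JSON container path.
#' @return `csv_path`, invisibly.
#' @export
write_result_table <- function(results, csv_path, container_path = NULL) {
  tab <- result_table(results)
  ok <- try(utils::write.csv(tab, csv_path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) abort_io(paste0("cannot write result table: ", csv_path))
  if (!is.null(container_path)) {
    container <- lapply(results, function(r) {
      list(map_id = r$map_id,
           cp_values = r$cp_values,
           values_original = r$values_original,
           bias_components = r$bias_components,
           values_standardised = r$values_standardised)
    })
    names(container) <- vapply(results, `[[`, character(1), "map_id")
    ok <- try(jsonlite::write_json(container, container_path, auto_unbox = TRUE, digits = NA),
              silent = TRUE)
    if (inherits(ok, "try-error")) abort_io(paste0("cannot write result container: ", container_path))
  }
  invisible(csv_path)
}

#' Read a serialized result container back
#'
#' @param container_path Path written by [write_result_table()].
#' @return Named list per map with numeric vectors `values_original`,
#'   `values_standardised` and named `bias_components`.
#' @export
read_result_container <- function(container_path) {
  x <- jsonlite::read_json(container_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(x, function(r) {
    r$values_original <- as.numeric(r$values_original)
    r$values_standardised <- as.numeric(r$values_standardised)
    r$bias_components <- lapply(r$bias_components, as.numeric)
    r
  })
}
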