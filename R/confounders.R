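#' Define a confounding parameter
#'
#' A confounding parameter (CP) is any subject-specific or technical factor
#' that biases apparent T1 values: age, sex, scanner, acquisition sequence and
#' the like. Each CP is defined by where its value lives in the DICOM
#' metadata, whether it is numerical or categorical, and the reference value
#' assumed bias-free. Standardisation transforms values into the reference CP
#' environment.
#'
#' @param name CP name, unique within a CP set.
#' @param source DICOM tag as `"GGGG,EEEE"` (uppercase hex). For multi-value
#'   tags, `value_index` selects a fixed component (stable multiplicity is
#'   assumed), so each value dimension is its own CP.
#' @param representation `"numerical"` or `"categorical"`.
#' @param reference_value Value of the CP assumed free of bias; for numerical
#'   CPs a finite number.
#' @param extractor_rules Optional data frame / tibble with columns `pattern`
#'   and `label`: the raw attribute string is matched case-insensitively
#'   against the regex patterns in order and the first match's label becomes
#'   the CP value (used e.g. for sequence variants parsed from the series
#'   description).
#' @param value_map Optional named character vector recoding raw attribute
#'   values to CP labels (e.g. `c(M = "male", F = "female")`).
#' @param value_index Optional 1-based component index for multi-value tags.
#' @return An object of class `cp_def`.
#' @export
#' @examples
#' cp_def("age", "0010,1010", "numerical", 18)
cp_def <- function(name, source, representation = c("numerical", "categorical"),
                   reference_value, extractor_rules = NULL, value_map = NULL,
                   value_index = NULL) {
  representation <- match.arg(representation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!grepl("^[0-9A-Fa-f]{4},[0-9A-Fa-f]{4}$", source)) {
    abort_config(paste0("CP '", name, "': source must be a DICOM tag 'GGGG,EEEE', got '", source, "'"))
  }
  if (representation == "numerical" && !is_scalar_number(reference_value)) {
    abort_config(paste0("CP '", name, "': numerical CPs need a finite numeric reference value"))
  }
  if (!is.null(extractor_rules)) {
    extractor_rules <- tibble::as_tibble(extractor_rules)
    if (!all(c("pattern", "label") %in% names(extractor_rules)) || nrow(extractor_rules) == 0) {
      abort_config(paste0("CP '", name, "': extractor_rules needs nonempty columns pattern, label"))
    }
  }
  structure(
    list(name = name, source = toupper(source), representation = representation,
         reference_value = reference_value, extractor_rules = extractor_rules,
         value_map = value_map, value_index = value_index),
    class = "cp_def"
  )
}

#' @export
print.cp_def <- function(x, ...) {
  cat("<cp_def> ", x$name, " [", x$representation, "] tag ", x$source,
      if (!is.null(x$value_index)) paste0("[", x$value_index, "]") else "",
      ", reference = ", as.character(x$reference_value), "\n", sep = "")
  invisible(x)
}

validate_cp_set <- function(cps) {
  if (!is.list(cps) || !all(vapply(cps, inherits, logical(1), "cp_def"))) {
    abort_config("cps must be a list of cp_def objects")
  }
  nm <- vapply(cps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort_config("CP names must be unique within a CP set")
  stats::setNames(cps, nm)
}

#' Default sequence-variant extraction rules
#'
#' First-match-wins, case-insensitive regex rules mapping a series
#' description to a sequence-variant label. The defaults recognise the labels
#' the synthetic generator writes, plus the common clinical spellings of the
#' MOLLI 5(3)3 scheme.
#'
#' @return A tibble with columns `pattern` and `label`.
#' @export
default_sequence_rules <- function() {
  tibble::tibble(
    pattern = c("MOLLI\\s*5\\(3\\)3|MOLLI533", "MOLLI\\s*3\\(3\\)5|MOLLI335", "SASHA"),
    label = c("MOLLI533b", "MOLLI335b", "SASHA")
  )
}

#' Default confounding-parameter set
#'
#' Four CPs covering subject and technical factors: age (numerical, reference
#' 18 years), sex (reference male), scanner (reference the 3T reference
#' scanner label) and sequence variant (reference the MOLLI 5(3)3 breathhold
#' scheme), with the sequence parsed from the series description by
#' [default_sequence_rules()].
#'
#' @param scanner_reference,sequence_reference Reference category labels.
#' @param sequence_rules Extraction rules for the sequence CP.
#' @return Named list of [cp_def()] objects.
#' @export
default_cps <- function(scanner_reference = "3.0T-REF",
                        sequence_reference = "MOLLI533b",
                        sequence_rules = default_sequence_rules()) {
  validate_cp_set(list(
    cp_def("age", "0010,1010", "numerical", 18),
    cp_def("sex", "0010,0040", "categorical", "male",
           value_map = c(M = "male", F = "female", male = "male", female = "female")),
    cp_def("scanner", "0008,1090", "categorical", scanner_reference),
    cp_def("sequence", "0008,103E", "categorical", sequence_reference,
           extractor_rules = sequence_rules)
  ))
}

#' Parse a DICOM age string to years
#'
#' Accepts the DICOM `"nnnY"` convention (e.g. `"018Y"` is 18 years) or a
#' plain number. Month/week/day suffixes are rejected: the method targets
#' adult cohorts.
#'
#' @param x Character or numeric scalar.
#' @return Age in years (numeric scalar).
#' @export
#' @examples
#' parse_dicom_age("018Y") # 18
parse_dicom_age <- function(x) {
  if (is.numeric(x) && is_scalar_number(x)) return(as.numeric(x))
  s <- trimws(as.character(x)[1])
  if (grepl("^[0-9]+$", s)) return(as.numeric(s))
  if (grepl("^[0-9]{1,3}Y$", s, ignore.case = TRUE)) {
    return(as.numeric(substr(s, 1, nchar(s) - 1L)))
  }
  if (grepl("^[0-9]{1,3}[MWD]$", s, ignore.case = TRUE)) {
    abort_extraction(paste0("age '", s, "' uses a sub-year unit; only adult ages in years are supported"))
  }
  abort_extraction(paste0("cannot parse age value '", s, "'"))
}

#' Derive a label from a series description via extraction rules
#'
#' Case-insensitive regex matching; the first matching rule wins.
#'
#' @param series_description Raw series-description string.
#' @param rules Data frame with columns `pattern`, `label`.
#' @return The matched label.
#' @export
parse_sequence_variant <- function(series_description, rules) {
  rules <- tibble::as_tibble(rules)
  if (nrow(rules) == 0) abort_config("extraction rules must be nonempty")
  s <- paste(as.character(series_description), collapse = " ")
  for (i in seq_len(nrow(rules))) {
    if (grepl(rules$pattern[i], s, ignore.case = TRUE)) return(rules$label[i])
  }
  abort_extraction(paste0("no extraction rule matches series description '", s, "'"),
                   description = s)
}

extract_one_cp <- function(cp, source_meta, map_id = "?") {
  raw <- source_meta[[cp$source]]
  if (is.null(raw)) {
    abort_extraction(paste0("CP '", cp$name, "': DICOM tag ", cp$source,
                            " missing in map '", map_id, "'"))
  }
  if (!is.null(cp$value_index)) {
    if (length(raw) < cp$value_index) {
      abort_extraction(paste0("CP '", cp$name, "': tag ", cp$source, " has ", length(raw),
                              " values, need index ", cp$value_index, " (map '", map_id, "')"))
    }
    raw <- raw[[cp$value_index]]
  } else {
    raw <- raw[[1]]
  }
  if (!is.null(cp$extractor_rules)) {
    raw <- parse_sequence_variant(raw, cp$extractor_rules)
  }
  if (cp$representation == "numerical") {
    if (cp$name == "age" || grepl("^[0-9]{1,3}[YMWDymwd]$", trimws(as.character(raw)[1]))) {
      return(parse_dicom_age(raw))
    }
    v <- suppressWarnings(as.numeric(raw))
    if (!is_scalar_number(v)) {
      abort_extraction(paste0("CP '", cp$name, "': value '", raw,
                              "' is not numeric (map '", map_id, "')"))
    }
    return(v)
  }
  lbl <- as.character(raw)
  if (!is.null(cp$value_map)) {
    if (lbl %in% names(cp$value_map)) lbl <- unname(cp$value_map[[lbl]])
  }
  lbl
}

#' Extract the confounder vector of a T1 map from its DICOM metadata
#'
#' Resolves each CP's DICOM tag (honouring multi-value indices), applies
#' string-extraction rules and value maps, and parses numerical values
#' (DICOM age strings included). The result is independent of the order in
#' which the CPs are listed.
#'
#' @param record A [t1_map] record with populated `source_meta`.
#' @param cps List of [cp_def()] objects.
#' @return Named list CP name -> value.
#' @export
extract_cp_vector <- function(record, cps) {
  cps <- validate_cp_set(cps)
  vals <- lapply(cps, extract_one_cp, source_meta = record$source_meta,
                 map_id = record$map_id)
  vals[order(match(names(vals), names(cps)))]
}

# does this record sit at the reference value for every CP in `which`?
cp_at_reference <- function(record, cps, which = names(cps)) {
  all(vapply(which, function(nm) {
    cp <- cps[[nm]]
    v <- record$cp_values[[nm]]
    if (is.null(v)) return(FALSE)
    if (cp$representation == "numerical") {
      isTRUE(abs(as.numeric(v) - as.numeric(cp$reference_value)) < 1e-9)
    } else {
      identical(as.character(v), as.character(cp$reference_value))
    }
  }, logical(1)))
}
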