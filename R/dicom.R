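#' Minimal single-frame DICOM reading and writing
#'
#' The package ships its own small DICOM layer covering exactly what a
#' parametric T1 map needs: part-10 files with explicit-VR little-endian
#' transfer syntax, a single monochrome 16-bit frame and plain (non-sequence)
#' metadata elements. Enhanced/multi-frame objects, sequences with undefined
#' length and other transfer syntaxes are rejected with an input error.
#'
#' Element values are returned in a named list keyed by `"GGGG,EEEE"`
#' (uppercase hex). String-valued elements are split at the DICOM `\`
#' multi-value delimiter; `DS`/`IS` elements are parsed to numeric; binary
#' numeric VRs (`US`, `UL`, `SS`, `SL`, `FL`, `FD`) are decoded to numeric
#' vectors. Pixel data are returned as a stored-value integer matrix in
#' row-major order (origin top-left), before any rescale is applied.
#'
#' @param path Path to a DICOM file.
#' @return `read_dicom()`: a list with elements `meta` (named list of element
#'   values), `pixels` (integer matrix of stored values) and `path`.
#' @keywords internal
read_dicom <- function(path) {
  if (!file.exists(path)) abort_input(paste0("DICOM file does not exist: ", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    abort_input(paste0("not a part-10 DICOM file (missing DICM marker): ", path))
  }
  pos <- 133L
  meta <- list()
  pixels <- NULL
  pixel_raw <- NULL
  ts_checked <- FALSE

  u16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2L, signed = FALSE, endian = "little")
  u32 <- function(i) {
    v <- readBin(raw[i:(i + 3L)], "integer", size = 4L, endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  string_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST", "TM", "UI", "UT")
  # decode raw bytes to string, dropping padding NULs and trailing spaces
  raw_str <- function(v) sub(" +$", "", rawToChar(v[v != as.raw(0)]))

  while (TRUE) {
    if (pos + 7L > length(raw)) break
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      vpos <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vpos <- pos + 8L
    }
    if (len == 4294967295) {
      abort_input(paste0("undefined-length element (unsupported) in ", path))
    }
    if (vpos + len - 1L > length(raw)) {
      abort_input(paste0("truncated DICOM element in ", path))
    }
    key <- sprintf("%04X,%04X", group, elem)
    vraw <- if (len > 0) raw[vpos:(vpos + len - 1L)] else raw(0)

    if (group == 0x0002 && elem == 0x0010) {
      ts <- raw_str(vraw)
      if (ts != "1.2.840.10008.1.2.1") {
        abort_input(paste0("unsupported transfer syntax ", ts, " in ", path,
                           " (only explicit-VR little-endian is supported)"))
      }
      ts_checked <- TRUE
    }

    if (group == 0x7FE0 && elem == 0x0010) {
      pixel_raw <- vraw
    } else if (vr == "SQ") {
      # skipped: sequence contents are not needed by this package
    } else if (vr %in% string_vrs) {
      s <- raw_str(vraw)
      meta[[key]] <- if (nzchar(s)) strsplit(s, "\\", fixed = TRUE)[[1]] else ""
    } else if (vr %in% c("DS", "IS")) {
      s <- raw_str(vraw)
      meta[[key]] <- if (nzchar(s)) as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]]) else numeric(0)
    } else if (vr == "US") {
      meta[[key]] <- readBin(vraw, "integer", n = len / 2L, size = 2L, signed = FALSE, endian = "little")
    } else if (vr == "SS") {
      meta[[key]] <- readBin(vraw, "integer", n = len / 2L, size = 2L, signed = TRUE, endian = "little")
    } else if (vr %in% c("UL", "SL")) {
      meta[[key]] <- readBin(vraw, "integer", n = len / 4L, size = 4L, endian = "little")
    } else if (vr == "FL") {
      meta[[key]] <- readBin(vraw, "numeric", n = len / 4L, size = 4L, endian = "little")
    } else if (vr == "FD") {
      meta[[key]] <- readBin(vraw, "numeric", n = len / 8L, size = 8L, endian = "little")
    } else {
      meta[[key]] <- vraw
    }
    pos <- vpos + len
  }

  if (!ts_checked) abort_input(paste0("missing transfer syntax UID in ", path))
  if (is.null(pixel_raw)) abort_input(paste0("DICOM file lacks pixel data: ", path))
  rows <- meta[["0028,0010"]]; cols <- meta[["0028,0011"]]
  if (is.null(rows) || is.null(cols)) {
    abort_input(paste0("DICOM file lacks Rows/Columns: ", path))
  }
  n <- as.integer(rows) * as.integer(cols)
  if (length(pixel_raw) < 2L * n) abort_input(paste0("pixel data shorter than Rows x Columns in ", path))
  stored <- readBin(pixel_raw, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
  pixels <- matrix(stored, nrow = as.integer(rows), ncol = as.integer(cols), byrow = TRUE)
  list(meta = meta, pixels = pixels, path = path)
}

# ---- writer ----------------------------------------------------------------

le16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
le32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

pad_even <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, pad)
  r
}

dicom_element <- function(group, elem, vr, value_raw) {
  head <- c(le16(group), le16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), le32(length(value_raw)), value_raw)
  } else {
    c(head, le16(length(value_raw)), value_raw)
  }
}

str_element <- function(group, elem, vr, value) {
  pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")  # UIs pad with NUL
  dicom_element(group, elem, vr, pad_even(as.character(value), pad))
}

us_element <- function(group, elem, value) dicom_element(group, elem, "US", le16(value))

synthetic_uid <- function(tag) {
  # deterministic study-agnostic UID under a test-range root
  h <- object_md5(tag)
  digits <- gsub("[a-f]", "", h)
  paste0("1.2.826.0.1.3680043.8.498.", substr(paste0(digits, "0000000000"), 1, 10))
}

#' Write a T1 map as a single-frame DICOM file
#'
#' Stores pixel values in milliseconds as 16-bit unsigned integers together
#' with a rescale slope/intercept so that `stored * slope + intercept`
#' recovers ms. Metadata carries the confounder-relevant attributes (patient
#' age/sex, scanner model string, series description).
#'
#' @param path Output file path.
#' @param pixels_ms Numeric matrix of pixel values in ms.
#' @param patient_id,patient_age,patient_sex Subject attributes; `patient_age`
#'   must be a DICOM age string such as `"042Y"`, `patient_sex` `"M"`/`"F"`.
#' @param scanner Scanner label stored as ManufacturerModelName (0008,1090).
#' @param series_description Series description (0008,103E); sequence-variant
#'   parsing operates on this string.
#' @param slope,intercept Rescale applied at read time; stored values are
#'   `round((ms - intercept) / slope)`.
#' @return `path`, invisibly.
#' @export
write_t1_dicom <- function(path, pixels_ms, patient_id, patient_age, patient_sex,
                           scanner, series_description, slope = 0.1, intercept = 0) {
  if (!is.matrix(pixels_ms) || !is.numeric(pixels_ms)) {
    abort_input("pixels_ms must be a numeric matrix")
  }
  stored <- round((pixels_ms - intercept) / slope)
  if (any(stored < 0 | stored > 65535)) {
    abort_input("pixel values out of the 16-bit stored range for the given slope/intercept")
  }
  rows <- nrow(pixels_ms); cols <- ncol(pixels_ms)
  # row-major serialisation, origin top-left
  stored_vec <- as.integer(t(stored))
  pix_raw <- writeBin(stored_vec, raw(), size = 2L, endian = "little")
  if (length(pix_raw) %% 2L == 1L) pix_raw <- c(pix_raw, as.raw(0))

  sop_class <- "1.2.840.10008.5.1.4.1.1.4"
  sop_inst <- synthetic_uid(paste(patient_id, basename(path)))

  meta_body <- c(
    str_element(0x0002, 0x0002, "UI", sop_class),
    str_element(0x0002, 0x0003, "UI", sop_inst),
    str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  file_meta <- c(dicom_element(0x0002, 0x0000, "UL", le32(length(meta_body))), meta_body)

  ds_fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  body <- c(
    str_element(0x0008, 0x0016, "UI", sop_class),
    str_element(0x0008, 0x0018, "UI", sop_inst),
    str_element(0x0008, 0x0060, "CS", "MR"),
    str_element(0x0008, 0x103E, "LO", series_description),
    str_element(0x0008, 0x1090, "LO", scanner),
    str_element(0x0010, 0x0010, "PN", patient_id),
    str_element(0x0010, 0x0020, "LO", patient_id),
    str_element(0x0010, 0x0040, "CS", patient_sex),
    str_element(0x0010, 0x1010, "AS", patient_age),
    us_element(0x0028, 0x0002, 1L),
    str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    us_element(0x0028, 0x0010, rows),
    us_element(0x0028, 0x0011, cols),
    us_element(0x0028, 0x0100, 16L),
    us_element(0x0028, 0x0101, 16L),
    us_element(0x0028, 0x0102, 15L),
    us_element(0x0028, 0x0103, 0L),
    str_element(0x0028, 0x1052, "DS", ds_fmt(intercept)),
    str_element(0x0028, 0x1053, "DS", ds_fmt(slope)),
    dicom_element(0x7FE0, 0x0010, "OW", pix_raw)
  )

  out <- c(raw(128), charToRaw("DICM"), file_meta, body)
  ok <- try(writeBin(out, path), silent = TRUE)
  if (inherits(ok, "try-error")) abort_io(paste0("cannot write DICOM file: ", path))
  invisible(path)
}
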