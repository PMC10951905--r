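test_that("DICOM write/read round-trips pixel values within quantisation", {
  px <- matrix(seq(900, 1400, length.out = 64), 8, 8)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_t1_dicom(f, px, patient_id = "P1", patient_age = "042Y", patient_sex = "F",
                 scanner = "3.0T-REF", series_description = "T1 Map MOLLI533b",
                 slope = 0.1)
  rec <- read_t1_map(f)
  expect_equal(dim(rec$pixels), dim(px))
  expect_lt(max(abs(rec$pixels - px)), 0.05 + 1e-9)  # half the 0.1 ms slope
  expect_identical(rec$source_meta[["0010,1010"]], "042Y")
  expect_identical(rec$source_meta[["0010,0040"]], "F")
  expect_identical(rec$source_meta[["0008,1090"]], "3.0T-REF")
})

test_that("rescale slope and intercept are applied, defaulting to 1/0", {
  px <- matrix(1100, 4, 4)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_t1_dicom(f, px, "P1", "018Y", "M", "sc", "desc", slope = 2, intercept = 0)
  rec <- read_t1_map(f)
  expect_equal(rec$pixels[1, 1], 1100)          # stored 550 * slope 2
  expect_equal(rec$source_meta[["0028,1053"]], 2)

  # file without rescale attributes: stored values pass through unchanged
  raw_els <- c(
    t1stand:::str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    t1stand:::us_element(0x0028, 0x0010, 2L),
    t1stand:::us_element(0x0028, 0x0011, 2L),
    t1stand:::dicom_element(0x7FE0, 0x0010, "OW",
                            writeBin(c(1100L, 1100L, 1100L, 1100L), raw(),
                                     size = 2L, endian = "little"))
  )
  meta_body <- t1stand:::str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  out <- c(raw(128), charToRaw("DICM"),
           t1stand:::dicom_element(0x0002, 0x0000, "UL", t1stand:::le32(length(meta_body))),
           meta_body,
           t1stand:::us_element(0x0028, 0x0010, 2L),
           t1stand:::us_element(0x0028, 0x0011, 2L),
           t1stand:::dicom_element(0x7FE0, 0x0010, "OW",
                                   writeBin(rep(1100L, 4), raw(), size = 2L, endian = "little")))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(out, f2)
  rec2 <- read_t1_map(f2)
  expect_equal(rec2$pixels, matrix(1100, 2, 2))
})

test_that("malformed DICOM inputs raise input errors naming the file", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(1:64), f)
  expect_error(read_t1_map(f), "DICM", class = "t1stand_input_error")

  # valid header but no pixel data element
  meta_body <- t1stand:::str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  out <- c(raw(128), charToRaw("DICM"),
           t1stand:::dicom_element(0x0002, 0x0000, "UL", t1stand:::le32(length(meta_body))),
           meta_body,
           t1stand:::us_element(0x0028, 0x0010, 2L),
           t1stand:::us_element(0x0028, 0x0011, 2L))
  f3 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(out, f3)
  expect_error(read_t1_map(f3), "pixel data", class = "t1stand_input_error")
  expect_error(read_t1_map(file.path(tempdir(), "absent.dcm")), class = "t1stand_input_error")
})

test_that("written DICOM files are readable by an independent implementation", {
  px <- matrix(1234.5, 6, 6)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_t1_dicom(f, px, "P9", "030Y", "M", "1.5T-ALT", "T1 Map SASHA", slope = 0.1)
  script <- paste(
    "import pydicom, sys",
    sprintf("ds = pydicom.dcmread(r'%s')", f),
    "print(ds.PatientAge, ds.PatientSex, ds.ManufacturerModelName)",
    "print(float(ds.pixel_array.mean()) * float(ds.RescaleSlope))",
    sep = "\n")
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_identical(out[1], "030Y M 1.5T-ALT")
  expect_equal(as.numeric(out[2]), 1234.5, tolerance = 1e-6)
})
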