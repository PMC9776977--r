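# Construct a single-frame explicit-VR little-endian DICOM file byte by byte
# (independently of the package's reader, following the Part-10 layout).
write_test_dicom <- function(path, m, spacing = c(0.78, 0.78), slope = 1,
                             intercept = 0) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  el_short <- function(group, elem, vr, payload) {
    w16(c(group, elem))
    writeBin(charToRaw(vr), con)
    w16(length(payload))
    writeBin(payload, con)
  }
  el_long <- function(group, elem, vr, payload) {
    w16(c(group, elem))
    writeBin(charToRaw(vr), con)
    w16(0L)
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    writeBin(payload, con)
  }
  us <- function(v) writeBin(as.integer(v), raw(), size = 2,
                             endian = "little")
  txt <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  el_short(0x0002, 0x0010, "UI", txt("1.2.840.10008.1.2.1"))
  el_short(0x0028, 0x0010, "US", us(nrow(m)))
  el_short(0x0028, 0x0011, "US", us(ncol(m)))
  el_short(0x0028, 0x0030, "DS", txt(paste(spacing, collapse = "\\")))
  el_short(0x0028, 0x0100, "US", us(16L))
  el_short(0x0028, 0x0103, "US", us(0L))
  el_short(0x0028, 0x1052, "DS", txt(as.character(intercept)))
  el_short(0x0028, 0x1053, "DS", txt(as.character(slope)))
  px <- as.integer(t(m))
  px[px > 32767L] <- px[px > 32767L] - 65536L
  el_long(0x7FE0, 0x0010, "OW",
          writeBin(px, raw(), size = 2, endian = "little"))
  invisible(path)
}

test_that("domain containers enforce their invariants", {
  expect_error(adc_image(matrix(1, 5, 5)), "9 x 9")
  expect_error(adc_image(matrix(-1, 10, 10)), "non-negative")
  expect_error(adc_image(matrix(NA_real_, 10, 10)), "finite")
  expect_error(adc_image(matrix(1, 10, 10), pixel_spacing = c(0, 1)),
               "positive")
  expect_error(roi_mask(matrix(0, 5, 5)), "empty ROI")
  img <- flat_image()
  bad <- roi_mask(matrix(TRUE, 10, 10), "gland")
  expect_error(check_alignment(img, bad), "does not match")
  expect_true(check_alignment(img, full_gland()))
})

test_that("lesion pixels outside the gland are clipped with a warning", {
  gland <- matrix(FALSE, 20, 20); gland[5:15, 5:15] <- TRUE
  lesion <- matrix(FALSE, 20, 20); lesion[12:18, 12:18] <- TRUE
  g <- roi_mask(gland, "gland"); l <- roi_mask(lesion, "lesion", "L1")
  expect_warning(cl <- clip_lesion_to_gland(l, g), "clipped")
  expect_true(all(g$mask[cl$mask]))
  expect_equal(sum(cl$mask), sum(lesion & gland))
  # lesion fully inside: untouched, no warning
  inner <- roi_mask(gland & lesion, "lesion")
  expect_silent(clip_lesion_to_gland(inner, g))
})

test_that("TIFF 16-bit round-trip is bit-exact and matches tifffile", {
  set.seed(42)
  m <- matrix(sample.int(40000L, 15 * 12), 15, 12)
  p <- tempfile(fileext = ".tif")
  write_tiff16(m, p)
  expect_identical(read_tiff16(p), m + 0)
  img <- read_adc(p, pixel_spacing = c(0.5, 0.5))
  expect_equal(img$pixels, m + 0)
  expect_equal(img$pixel_spacing, c(0.5, 0.5))
  skip_if_not(python_ok(), "python not on PATH")
  out <- tempfile(fileext = ".txt")
  r <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile, numpy; a = tifffile.imread('%s'); numpy.savetxt('%s', a, fmt='%%d')",
    p, out))))
  expect_identical(r, 0L)
  ref <- as.matrix(read.table(out))
  dimnames(ref) <- NULL
  expect_equal(ref, m + 0)   # tifffile reads rows x cols like our writer
})

test_that("NIfTI-1 round-trip preserves values and matches nibabel", {
  set.seed(7)
  m <- matrix(round(runif(14 * 11, 0, 3000)), 14, 11)
  p <- tempfile(fileext = ".nii")
  write_nifti(m, p, pixel_spacing = c(0.6, 0.9))
  got <- read_nifti(p)
  expect_equal(got$pixels, m)          # integers are float32-exact
  expect_equal(got$spacing, c(0.6, 0.9), tolerance = 1e-6)
  img <- read_adc(p)
  expect_equal(img$pixel_spacing, c(0.6, 0.9), tolerance = 1e-6)
  skip_if_not(python_ok(), "python not on PATH")
  out <- tempfile(fileext = ".txt")
  r <- system2("python", c("-c", shQuote(sprintf(
    "import nibabel, numpy; a = numpy.asanyarray(nibabel.load('%s').dataobj); numpy.savetxt('%s', a, fmt='%%.1f')",
    p, out))))
  expect_identical(r, 0L)
  ref <- as.matrix(read.table(out))
  dimnames(ref) <- NULL
  expect_equal(ref, m)                 # same (row-fastest) axis convention
})

test_that("DICOM reader applies rescale slope/intercept", {
  m <- matrix(500L, 10, 12); m[3, 4] <- 700L
  p <- tempfile(fileext = ".dcm")
  write_test_dicom(p, m, spacing = c(0.78, 0.82), slope = 2, intercept = 0)
  got <- read_dicom(p)
  expect_equal(got$pixels[3, 4], 1400)
  expect_equal(got$pixels[1, 1], 1000)
  expect_equal(got$spacing, c(0.78, 0.82))
  img <- read_adc(p)                    # magic-byte dispatch
  expect_equal(img$pixels, m * 2)
  # negative pixels after rescale are rejected for ADC data
  p2 <- tempfile(fileext = ".dcm")
  write_test_dicom(p2, m, slope = 1, intercept = -600)
  expect_error(read_dicom(p2), "negative")
})

test_that("PNG masks binarize, split labels, and reject empty ROIs", {
  m <- matrix(0L, 12, 12); m[2:4, 2:4] <- 1L; m[8:10, 8:10] <- 2L
  p <- tempfile(fileext = ".png")
  write_mask(m, p)
  msk <- read_mask(p, "lesion")
  expect_true(is.logical(msk$mask))
  expect_equal(sum(msk$mask), 18)
  parts <- read_lesion_masks(p)
  expect_length(parts, 2)
  expect_equal(vapply(parts, function(x) sum(x$mask), 0), c(9, 9))
  expect_equal(vapply(parts, function(x) x$lesion_id, ""), c("1", "2"))
  empty <- tempfile(fileext = ".png")
  write_mask(matrix(0L, 5, 5) + 0, empty)
  expect_error(read_mask(empty, "gland"), "empty ROI")
})

test_that("lesion label table is validated and csPCa derived", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("lesion_id,patient_id,gg,pirads",
               "L1,P1,2,3", "L2,P1,4,5"), p)
  tab <- read_lesion_table(p)
  expect_equal(tab$cspca, c(FALSE, TRUE))
  writeLines(c("lesion_id,patient_id,gg,pirads", "L1,P1,7,3"), p)
  expect_error(read_lesion_table(p), "gg")
})

test_that("colormap export paints the gland and overlays the contour", {
  map <- matrix(NA_real_, 20, 20)
  gl <- matrix(FALSE, 20, 20); gl[5:16, 5:16] <- TRUE
  map[gl] <- 1                            # constant map
  les <- matrix(FALSE, 20, 20); les[8:12, 8:12] <- TRUE
  p <- tempfile(fileext = ".png")
  export_colormap(map, roi_mask(les, "lesion"), p)
  arr <- png::readPNG(p)
  inside <- arr[6, 6, ]; outside <- arr[1, 1, ]
  expect_equal(outside, c(0, 0, 0))       # undefined pixels black
  expect_false(all(inside == 0))
  # all inside-gland non-contour pixels share one colour
  body <- gl & !les
  for (ch in 1:3) expect_equal(length(unique(round(arr[, , ch][body], 3))), 1)
  # contour pixels differ from the body colour
  contour <- mask_contour(les)
  expect_false(isTRUE(all.equal(arr[8, 8, ], inside)))
  expect_true(all(contour[8, 8:12]))
  expect_error(export_colormap(matrix(NA_real_, 9, 9), NULL, p),
               "undefined")
})
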