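#' ADC image container
#'
#' Wraps a 2D grid of apparent diffusion coefficient values (conventionally
#' in units of 1e-6 mm^2/s) together with its pixel spacing and identifiers.
#' The grid convention is row-major thinking with `pixels[row, col]` and
#' 0-based window offsets internally; masks are boolean grids of the same
#' shape.
#'
#' @param pixels numeric matrix of non-negative, finite ADC values, at least
#'   9 x 9 so one local window fits.
#' @param pixel_spacing length-2 numeric, (row, col) spacing in mm.
#' @param patient_id,slice_id opaque identifier strings.
#' @return An object of class `adc_image`.
#' @export
adc_image <- function(pixels, pixel_spacing = c(1, 1), patient_id = "",
                      slice_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("ADC pixels must all be finite")
  if (any(pixels < 0)) stop("ADC pixels must be non-negative")
  if (nrow(pixels) < 9 || ncol(pixels) < 9) {
    stop("ADC image must be at least 9 x 9 pixels")
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be two positive numbers (row, col) in mm")
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         patient_id = as.character(patient_id),
         slice_id = as.character(slice_id)),
    class = "adc_image"
  )
}

#' @export
print.adc_image <- function(x, ...) {
  cat(sprintf("<adc_image> %d x %d px, spacing %.3g x %.3g mm, patient '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing[1],
              x$pixel_spacing[2], x$patient_id))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param mask logical (or coercible) matrix; any nonzero value is inside.
#' @param role `"gland"` or `"lesion"`.
#' @param lesion_id optional identifier for lesion masks.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, role = c("gland", "lesion"), lesion_id = NULL) {
  role <- match.arg(role)
  mask <- as.matrix(mask)
  mask <- !is.na(mask) & mask != 0
  if (!any(mask)) stop("empty ROI: mask has no nonzero pixels")
  structure(
    list(mask = mask, role = role,
         lesion_id = if (is.null(lesion_id)) NULL else as.character(lesion_id)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> role=%s%s, %d px of %d x %d\n", x$role,
              if (is.null(x$lesion_id)) "" else paste0(" id=", x$lesion_id),
              sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Check that a mask is aligned to an image grid
#'
#' Shape agreement is enforced before any feature computation.
#' @param image an [adc_image].
#' @param mask an [roi_mask].
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_alignment <- function(image, mask) {
  stopifnot(inherits(image, "adc_image"), inherits(mask, "roi_mask"))
  if (!identical(dim(image$pixels), dim(mask$mask))) {
    stop(sprintf("mask shape %d x %d does not match image shape %d x %d",
                 nrow(mask$mask), ncol(mask$mask),
                 nrow(image$pixels), ncol(image$pixels)))
  }
  invisible(TRUE)
}

#' Intersect a lesion mask with the gland mask
#'
#' Local maps are only defined within the gland, so lesion pixels falling
#' outside it are dropped with a warning (not an error).
#' @param lesion,gland [roi_mask] objects of equal shape.
#' @return The lesion mask restricted to the gland.
#' @export
clip_lesion_to_gland <- function(lesion, gland) {
  stopifnot(inherits(lesion, "roi_mask"), inherits(gland, "roi_mask"))
  if (!identical(dim(lesion$mask), dim(gland$mask))) {
    stop("lesion and gland masks have different shapes")
  }
  outside <- sum(lesion$mask & !gland$mask)
  if (outside > 0) {
    warning(sprintf("lesion '%s': %d pixel(s) outside the gland were clipped",
                    if (is.null(lesion$lesion_id)) "?" else lesion$lesion_id,
                    outside))
    lesion$mask <- lesion$mask & gland$mask
    if (!any(lesion$mask)) stop("lesion entirely outside the gland")
  }
  lesion
}

#' Lesion area in mm^2
#' @param mask an [roi_mask].
#' @param pixel_spacing (row, col) spacing in mm.
#' @return Scalar area.
#' @export
lesion_area_mm2 <- function(mask, pixel_spacing) {
  sum(mask$mask) * prod(pixel_spacing)
}

# ---- file format dispatch ---------------------------------------------------

#' Read an ADC image from DICOM, NIfTI-1 or 16-bit TIFF
#'
#' Format is chosen by extension (`.nii`, `.tif`/`.tiff`, `.dcm`) with a
#' magic-byte fallback. DICOM rescale slope/intercept are applied so the
#' returned pixels are in ADC units.
#'
#' @param path file path.
#' @param patient_id,slice_id identifiers stored on the result.
#' @param pixel_spacing fallback spacing for formats that do not carry one
#'   (TIFF); ignored when the file stores a spacing.
#' @return An [adc_image].
#' @export
read_adc <- function(path, patient_id = "", slice_id = "",
                     pixel_spacing = c(1, 1)) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw4 <- readBin(path, "raw", n = 160)
  fmt <- if (ext == "nii") "nifti"
    else if (ext %in% c("tif", "tiff")) "tiff"
    else if (ext %in% c("dcm", "dicom")) "dicom"
    else if (length(raw4) >= 132 &&
             rawToChar(raw4[129:132]) == "DICM") "dicom"
    else if (length(raw4) >= 2 && rawToChar(raw4[1:2]) %in% c("II", "MM"))
      "tiff"
    else "nifti"
  res <- switch(fmt,
    nifti = read_nifti(path),
    tiff  = list(pixels = read_tiff16(path), spacing = pixel_spacing),
    dicom = read_dicom(path)
  )
  adc_image(res$pixels, res$spacing, patient_id = patient_id,
            slice_id = slice_id)
}

#' Write an ADC image or parametric map to NIfTI-1 or 16-bit TIFF
#'
#' @param image an [adc_image] or a plain numeric matrix.
#' @param path destination; extension selects the format.
#' @param pixel_spacing used when `image` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_adc <- function(image, path, pixel_spacing = c(1, 1)) {
  if (inherits(image, "adc_image")) {
    m <- image$pixels
    pixel_spacing <- image$pixel_spacing
  } else {
    m <- as.matrix(image)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "nii") {
    write_nifti(m, path, pixel_spacing)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff16(m, path)
  } else {
    stop("unsupported output extension: .", ext)
  }
  invisible(path)
}

#' Read a binary ROI mask from a PNG (or NIfTI/TIFF) file
#'
#' Any nonzero pixel is inside the ROI.
#' @param path file path.
#' @param role `"gland"` or `"lesion"`.
#' @param lesion_id optional identifier.
#' @return An [roi_mask].
#' @export
read_mask <- function(path, role = c("gland", "lesion"), lesion_id = NULL) {
  role <- match.arg(role)
  m <- .read_gray(path)
  if (!any(m != 0)) stop("empty ROI: ", path)
  roi_mask(m != 0, role = role, lesion_id = lesion_id)
}

#' Split a label image into per-lesion masks
#'
#' Each distinct nonzero grey level becomes one lesion [roi_mask] whose
#' `lesion_id` is the label value.
#' @param path file path (PNG label image; 8-bit levels).
#' @return A list of [roi_mask] objects, one per label.
#' @export
read_lesion_masks <- function(path) {
  m <- .read_gray(path)
  labs <- sort(setdiff(unique(as.vector(m)), 0))
  if (length(labs) == 0) stop("empty ROI: ", path)
  lapply(labs, function(l) {
    roi_mask(m == l, role = "lesion", lesion_id = as.character(l))
  })
}

.read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    round(a * 255)
  } else if (ext %in% c("tif", "tiff")) {
    read_tiff16(path)
  } else if (ext == "nii") {
    read_nifti(path)$pixels
  } else {
    stop("unsupported mask format: .", ext)
  }
}

#' Write a binary or label mask as PNG
#' @param mask an [roi_mask], a logical matrix, or an integer label matrix
#'   (values 0..255).
#' @param path destination `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "roi_mask")) mask$mask * 255L else as.matrix(mask)
  storage.mode(m) <- "double"
  if (max(m) > 255 || min(m) < 0) stop("mask labels must be within 0..255")
  png::writePNG(m / 255, target = path)
  invisible(path)
}

#' Read a lesion label table
#'
#' CSV with columns `lesion_id, patient_id, gg, pirads`; the binary csPCa
#' class label is `gg >= 3`.
#' @param path CSV path.
#' @return data.frame with an added logical `cspca` column.
#' @export
read_lesion_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(lesion_id = "character",
                                 patient_id = "character"))
  need <- c("lesion_id", "patient_id", "gg", "pirads")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("lesion table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tab$gg %in% 1:5)) stop("gg must be an integer in 1..5")
  if (!all(tab$pirads %in% 3:5)) stop("pirads must be an integer in 3..5")
  tab$cspca <- tab$gg >= 3
  tab
}

#' Export a parametric map as a colorimetric PNG with the lesion contour
#'
#' Defined map values are mapped linearly onto a colour palette; pixels
#' outside the gland (undefined, `NA`) are black; the lesion ROI boundary is
#' overlaid in pink.
#'
#' @param map numeric matrix with `NA` outside the gland / undefined pixels.
#' @param lesion optional [roi_mask] whose contour is overlaid.
#' @param path destination `.png`.
#' @param palette a palette name understood by [grDevices::hcl.colors].
#' @return `path`, invisibly.
#' @export
export_colormap <- function(map, lesion = NULL, path,
                            palette = "viridis") {
  map <- as.matrix(map)
  def <- is.finite(map)
  if (!any(def)) stop("map is undefined everywhere")
  lo <- min(map[def]); hi <- max(map[def])
  idx <- matrix(NA_integer_, nrow(map), ncol(map))
  idx[def] <- if (hi > lo) {
    1L + as.integer(round(255 * (map[def] - lo) / (hi - lo)))
  } else 128L
  pal <- grDevices::hcl.colors(256, palette)
  rgbm <- grDevices::col2rgb(pal) / 255
  arr <- array(0, dim = c(nrow(map), ncol(map), 3))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(map), ncol(map))
    plane[def] <- rgbm[ch, idx[def]]
    arr[, , ch] <- plane
  }
  if (!is.null(lesion)) {
    contour <- mask_contour(lesion$mask)
    pink <- c(1, 0.3, 0.7)
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[contour] <- pink[ch]
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel is on the contour when at least one 4-neighbour (or the
#' image border) lies outside the mask.
#' @param mask logical matrix.
#' @return Logical matrix of contour pixels.
#' @export
mask_contour <- function(mask) {
  mask <- as.matrix(mask) != 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  inner <- pad(mask, 1, 0) & pad(mask, -1, 0) & pad(mask, 0, 1) &
    pad(mask, 0, -1)
  mask & !inner
}
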