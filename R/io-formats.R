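# Minimal readers/writers for the imaging formats the pipeline consumes.
# Deliberately restricted: single 2D frame, little-endian, uncompressed.
# No imaging I/O package ships with this R installation, so these follow the
# NIfTI-1 / TIFF 6.0 / DICOM PS3.10 layouts directly and are cross-checked
# against nibabel and tifffile in the test suite.

#' Write a matrix as a NIfTI-1 image (.nii, float32, uncompressed)
#'
#' Rows are the fastest-varying (first) NIfTI dimension, matching R's
#' column-major matrix storage, so `m[i, j]` lands at voxel (i-1, j-1).
#'
#' @param m numeric matrix.
#' @param path destination `.nii`.
#' @param pixel_spacing (row, col) spacing in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(m, path, pixel_spacing = c(1, 1)) {
  m <- as.matrix(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348L, 4)                              # sizeof_hdr
  writeBin(raw(36), con)                   # data_type..dim_info (unused)
  wi(c(2L, nrow(m), ncol(m), 1L, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0))                           # intent_p1..p3
  wi(0L, 2)                                # intent_code
  wi(16L, 2)                               # datatype = float32
  wi(32L, 2)                               # bitpix
  wi(0L, 2)                                # slice_start
  wf(c(1, pixel_spacing[1], pixel_spacing[2], 1, 1, 1, 1, 1))  # pixdim[8]
  wf(352)                                  # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0L, 2)                                # slice_end
  writeBin(as.raw(c(0L, 2L)), con)         # slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                        # cal_max..toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  wc("adcradiomics", 80)                   # descrip
  writeBin(raw(24), con)                   # aux_file
  wi(c(0L, 0L), 2)                         # qform_code, sform_code
  wf(rep(0, 6))                            # quatern b,c,d + qoffset xyz
  wf(c(pixel_spacing[1], 0, 0, 0))         # srow_x
  wf(c(0, pixel_spacing[2], 0, 0))         # srow_y
  wf(c(0, 0, 1, 0))                        # srow_z
  writeBin(raw(16), con)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)                    # extension flag
  writeBin(as.numeric(m), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image (.nii, uncompressed, little-endian)
#'
#' Supports int16/int32/float32/float64 single-slice 2D (or singleton-3D)
#' data; scl_slope/scl_inter are applied.
#'
#' @param path file path.
#' @return list with `pixels` (matrix) and `spacing` (row, col, mm).
#' @export
read_nifti <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  ri <- function(off, size, n = 1) readBin(raw[(off + 1):(off + size * n)],
                                           "integer", n = n, size = size,
                                           endian = "little")
  rf <- function(off, n = 1, size = 4) readBin(raw[(off + 1):(off + size * n)],
                                               "numeric", n = n, size = size,
                                               endian = "little")
  if (ri(0, 4) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dim <- ri(40, 2, 8)
  nd <- dim[1]
  extent <- dim[2:(nd + 1)]
  if (prod(extent) != prod(extent[1:2])) {
    stop("non-2D NIfTI data without a slice selector: ", path)
  }
  nr <- extent[1]; nc <- if (nd >= 2) extent[2] else 1L
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  n <- nr * nc
  off <- as.integer(vox_offset)
  vals <- switch(as.character(datatype),
    "4"  = ri(off, 2, n),
    "8"  = ri(off, 4, n),
    "16" = rf(off, n, 4),
    "64" = rf(off, n, 8),
    stop("unsupported NIfTI datatype: ", datatype)
  )
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  list(pixels = matrix(as.numeric(vals), nr, nc),
       spacing = c(pixdim[2], pixdim[3]))
}

#' Write a matrix as an uncompressed 16-bit grayscale TIFF
#'
#' Values are rounded to uint16; data are stored row-major in a single strip.
#' @param m numeric matrix with values in 0..65535.
#' @param path destination `.tif`.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(m, path) {
  m <- round(as.matrix(m))
  if (min(m) < 0 || max(m) > 65535) stop("TIFF16 values must be in 0..65535")
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3) { w16(value); w16(0L) } else w32(value)
  }
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)   # header, IFD at 8
  n_entries <- 10L
  data_off <- 8L + 2L + n_entries * 12L + 4L
  w16(n_entries)
  entry(256L, 3L, 1L, nc)                 # ImageWidth
  entry(257L, 3L, 1L, nr)                 # ImageLength
  entry(258L, 3L, 1L, 16L)                # BitsPerSample
  entry(259L, 3L, 1L, 1L)                 # Compression: none
  entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)           # StripOffsets
  entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
  entry(278L, 3L, 1L, nr)                 # RowsPerStrip
  entry(279L, 4L, 1L, nr * nc * 2L)       # StripByteCounts
  entry(339L, 3L, 1L, 1L)                 # SampleFormat: unsigned int
  w32(0L)                                 # next IFD: none
  vals <- as.integer(t(m))                # row-major pixel order
  vals[vals > 32767L] <- vals[vals > 32767L] - 65536L  # to signed for writeBin
  writeBin(vals, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an uncompressed 16-bit grayscale TIFF
#' @param path file path.
#' @return Numeric matrix.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw[1:2]) != "II") stop("only little-endian TIFF supported")
  r16 <- function(off, n = 1) readBin(raw[(off + 1):(off + 2 * n)], "integer",
                                      n = n, size = 2, signed = FALSE,
                                      endian = "little")
  r32 <- function(off, n = 1) readBin(raw[(off + 1):(off + 4 * n)], "integer",
                                      n = n, size = 4, endian = "little")
  ifd <- r32(4)
  n_entries <- r16(ifd)
  tags <- list()
  for (k in seq_len(n_entries)) {
    off <- ifd + 2L + (k - 1L) * 12L
    tag <- r16(off); type <- r16(off + 2); count <- r32(off + 4)
    val <- if (type == 3 && count == 1) r16(off + 8)
      else if (type == 4 && count == 1) r32(off + 8)
      else if (type == 3) r16(r32(off + 8), count)
      else if (type == 4) r32(r32(off + 8), count)
      else NA
    tags[[as.character(tag)]] <- val
  }
  need <- function(t, default = NULL) {
    v <- tags[[as.character(t)]]
    if (is.null(v)) default else v
  }
  nc <- need(256); nr <- need(257)
  if (is.null(nc) || is.null(nr)) stop("TIFF lacks image dimensions")
  if (!identical(need(259, 1L), 1L)) stop("compressed TIFF not supported")
  bits <- need(258, 1L)
  if (!all(bits == 16L)) stop("only 16-bit TIFF supported")
  offsets <- need(273); counts <- need(279, nr * nc * 2L)
  vals <- integer(0)
  for (s in seq_along(offsets)) {
    vals <- c(vals, r16(offsets[s], counts[s] / 2L))
  }
  if (length(vals) != nr * nc) stop("TIFF pixel data truncated")
  matrix(as.numeric(vals), nr, nc, byrow = TRUE)
}

#' Read a minimal single-frame DICOM MR image
#'
#' Supports Part-10 files in implicit or explicit VR little endian with
#' uncompressed 16-bit pixel data; RescaleSlope/RescaleIntercept are applied
#' per the DICOM standard so the returned values are in ADC units. Negative
#' pixels after rescale are an error for ADC data.
#'
#' @param path file path.
#' @return list with `pixels` (matrix) and `spacing` (row, col, mm).
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file: ", path)
  }
  r16 <- function(off, n = 1, signed = FALSE)
    readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            signed = signed, endian = "little")
  r32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  rstr <- function(off, len) {
    if (len == 0) return("")
    trimws(rawToChar(raw[(off + 1):(off + len)]))
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  pos <- 132L
  ts <- NULL
  explicit_data <- TRUE      # resolved from the transfer syntax UID below
  while (pos + 8 <= length(raw)) {
    group <- r16(pos); elem <- r16(pos + 2)
    # file meta group (0002) is always explicit VR little endian
    use_explicit <- if (group == 2L) TRUE else explicit_data
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 5):(pos + 6)])
      if (vr %in% long_vrs) {
        len <- r32(pos + 8); hdr <- 12L
      } else {
        len <- r16(pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- r32(pos + 4); hdr <- 8L
    }
    if (len < 0) stop("undefined-length DICOM element not supported")
    key <- sprintf("%04x,%04x", group, elem)
    elems[[key]] <- list(off = pos + hdr, len = len, vr = vr)
    if (key == "0002,0010") {
      ts <- gsub("[^0-9.]", "", rstr(pos + hdr, len))
      explicit_data <- ts != "1.2.840.10008.1.2"
    }
    pos <- pos + hdr + len
  }
  if (!is.null(ts) &&
      !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
    stop("unsupported DICOM transfer syntax: ", ts)
  }
  getel <- function(key) elems[[key]]
  nr_el <- getel("0028,0010"); nc_el <- getel("0028,0011")
  px_el <- getel("7fe0,0010")
  if (is.null(nr_el) || is.null(nc_el) || is.null(px_el)) {
    stop("DICOM file lacks Rows/Columns/PixelData")
  }
  nr <- r16(nr_el$off); nc <- r16(nc_el$off)
  if (px_el$len != nr * nc * 2L) {
    stop("non-2D or non-16-bit DICOM pixel data not supported")
  }
  rep_el <- getel("0028,0103")
  signed <- !is.null(rep_el) && r16(rep_el$off) == 1L
  vals <- r16(px_el$off, nr * nc, signed = signed)
  slope <- 1; inter <- 0
  sl <- getel("0028,1053"); ic <- getel("0028,1052")
  if (!is.null(sl)) slope <- as.numeric(rstr(sl$off, sl$len))
  if (!is.null(ic)) inter <- as.numeric(rstr(ic$off, ic$len))
  vals <- vals * slope + inter
  if (any(vals < 0)) stop("negative pixel values after DICOM rescale")
  spacing <- c(1, 1)
  sp <- getel("0028,0030")
  if (!is.null(sp)) {
    spacing <- as.numeric(strsplit(rstr(sp$off, sp$len), "\\\\")[[1]])
  }
  list(pixels = matrix(vals, nr, nc, byrow = TRUE), spacing = spacing)
}
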