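#' Names of the ten first-order statistics
#'
#' mean, median, kurtosis (Pearson, non-excess), skewness (moment), entropy
#' (Shannon, bits, fixed-bin histogram), uniformity (histogram energy),
#' interquartile range, coefficient of variation, standard deviation
#' (population) and median absolute deviation (unscaled).
#' @return Character vector of length 10.
#' @export
first_order_stats <- function() {
  c("mean", "median", "kurtosis", "skewness", "entropy", "uniformity",
    "iqr", "cv", "std", "mad")
}

#' Compute one first-order statistic of a pixel sample
#'
#' Definitions: mean; median; Pearson kurtosis m4/m2^2 (non-excess; 3 for a
#' constant sample by convention); moment skewness m3/m2^1.5 (0 for a
#' constant sample); Shannon entropy -sum(p*log2(p)) and uniformity sum(p^2)
#' over `n_bins` equal-width histogram bins spanning `bin_range`; IQR =
#' P75 - P25 with linear-interpolation (type 7) percentiles; cv = std/mean
#' (0 when the mean is 0); population standard deviation; MAD =
#' median(|x - median(x)|), unscaled.
#'
#' @param values numeric vector, at least 2 finite values.
#' @param stat_name one of [first_order_stats()].
#' @param n_bins histogram bin count for entropy/uniformity (default 32).
#' @param bin_range histogram support; defaults to `range(values)`. Local
#'   maps pass the gland-wide intensity range so all windows share bins.
#' @param sample_var use the n-1 (sample) variance instead of the population
#'   variance for std/cv.
#' @return Scalar statistic value.
#' @export
first_order_stat <- function(values, stat_name, n_bins = 32,
                             bin_range = range(values), sample_var = FALSE) {
  stat_name <- match.arg(stat_name, first_order_stats())
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values))) {
    stop("need at least 2 finite values")
  }
  res <- cpp_first_order(values, as.integer(n_bins), bin_range[1],
                         bin_range[2], isTRUE(sample_var))
  res[[stat_name]]
}

#' Compute one local (sliding-window) feature map
#'
#' Each gland pixel is assigned the statistic of the pixels of a
#' `window_size` x `window_size` window centred on it, restricted to window
#' pixels inside the gland. A pixel is undefined (NA) when fewer than
#' `min_support` of the window's pixels lie inside the gland (pixels beyond
#' the image border count as outside).
#'
#' @param image an [adc_image].
#' @param gland the gland [roi_mask].
#' @param stat_name one of [first_order_stats()].
#' @param window_size odd window side length, default 9.
#' @param min_support minimum in-gland fraction of the window (default 0.5).
#' @param n_bins entropy/uniformity bin count (bins span the gland-wide
#'   intensity range of this image, shared across windows).
#' @param sample_var see [first_order_stat()].
#' @return Numeric matrix (NA where undefined).
#' @export
compute_local_map <- function(image, gland, stat_name, window_size = 9,
                              min_support = 0.5, n_bins = 32,
                              sample_var = FALSE) {
  stat_name <- match.arg(stat_name, first_order_stats())
  maps <- compute_all_local_maps(image, gland, window_size = window_size,
                                 min_support = min_support, n_bins = n_bins,
                                 sample_var = sample_var)
  maps$maps[[stat_name]]
}

#' Compute all ten local feature maps over the gland
#'
#' @inheritParams compute_local_map
#' @return An object of class `parametric_maps`: list with `maps` (named list
#'   of 10 matrices), `defined` (logical matrix, shared support), plus the
#'   parameters used.
#' @export
compute_all_local_maps <- function(image, gland, window_size = 9,
                                   min_support = 0.5, n_bins = 32,
                                   sample_var = FALSE) {
  stopifnot(inherits(image, "adc_image"), inherits(gland, "roi_mask"))
  check_alignment(image, gland)
  if (window_size %% 2 == 0) stop("window_size must be odd")
  if (window_size > min(dim(image$pixels))) {
    stop("window does not fit in the image")
  }
  if (!any(gland$mask)) stop("gland mask is empty")
  gl_vals <- image$pixels[gland$mask]
  res <- cpp_local_maps(image$pixels, gland$mask, as.integer(window_size),
                        min_support, as.integer(n_bins),
                        min(gl_vals), max(gl_vals), isTRUE(sample_var))
  structure(
    list(maps = res$maps, defined = res$defined == 1 | res$defined == TRUE,
         window_size = window_size, min_support = min_support,
         n_bins = n_bins, sample_var = sample_var,
         patient_id = image$patient_id, slice_id = image$slice_id),
    class = "parametric_maps"
  )
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %d maps (%s), window %d, %d defined px\n",
              length(x$maps), paste(names(x$maps), collapse = ", "),
              x$window_size, sum(x$defined)))
  invisible(x)
}
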