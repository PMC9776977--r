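# Lesion-level radiomic features: each lesion is summarised into 132 values,
# 120 from the 10 local parametric maps x 12 global descriptors, plus the 12
# descriptors computed directly on the raw ADC pixels of the lesion.

.map_base_names <- c(mean = "mu", median = "med", kurtosis = "k",
                     skewness = "s", entropy = "e", uniformity = "u",
                     iqr = "IQR", cv = "cv", std = "sigma", mad = "MAD")

.descriptor_suffixes <- c(mean = "mean", median = "m", kurtosis = "k",
                          skewness = "s", entropy = "e", uniformity = "u",
                          iqr = "IQR", cv = "cv", std = "std", mad = "MAD",
                          dmean = "d-mean", dmedian = "d-median")

#' Names of the 12 global descriptors
#'
#' The ten first-order statistics plus the mean and median of the last decile
#' (the subsample at or above the 90th percentile, inclusive).
#' @return Character vector of length 12.
#' @export
global_descriptors <- function() names(.descriptor_suffixes)

#' The 132 canonical feature names
#'
#' Features are named `"<base>-<descriptor>"` where base is the local-map
#' symbol (`mu`, `med`, `k`, `s`, `e`, `u`, `IQR`, `cv`, `sigma`, `MAD`) or
#' `ADC` for descriptors of the raw lesion pixels, and the descriptor suffix
#' follows the same symbols (`m` = median, `u` = uniformity, `s` = skewness,
#' `d-mean`/`d-median` = last-decile mean/median, ...). The four signature
#' features are `cv-m` (median of the local coefficient of variation),
#' `mu-u` (uniformity of the local mean), `s-s` (skewness of the local
#' skewness) and `sigma-IQR` (IQR of the local standard deviation).
#'
#' @return Character vector of length 132 in canonical order (10 maps x 12
#'   descriptors, then the 12 ADC descriptors).
#' @export
feature_names <- function() {
  bases <- c(.map_base_names, ADC = "ADC")
  as.vector(vapply(bases, function(b) {
    paste0(b, "-", .descriptor_suffixes)
  }, character(12)))
}

#' Compute one global descriptor of a lesion pixel sample
#'
#' @param values numeric vector of at least 4 pixel values.
#' @param descriptor_name one of [global_descriptors()].
#' @param n_bins histogram bins for the entropy/uniformity descriptors.
#' @param bin_range histogram support for entropy/uniformity; defaults to
#'   the sample's own range. [extract_feature_vector()] passes the gland-wide
#'   range of the underlying map so the descriptor measures how concentrated
#'   the lesion's values are relative to the whole gland, comparably across
#'   lesions.
#' @return Scalar descriptor value.
#' @export
global_descriptor <- function(values, descriptor_name, n_bins = 32,
                              bin_range = range(values)) {
  descriptor_name <- match.arg(descriptor_name, global_descriptors())
  values <- as.numeric(values)
  if (length(values) < 4 || !all(is.finite(values))) {
    stop("need at least 4 finite pixel values")
  }
  if (descriptor_name %in% c("dmean", "dmedian")) {
    p90 <- as.numeric(quantile(values, 0.9, type = 7))
    top <- values[values >= p90]
    if (descriptor_name == "dmean") mean(top) else median(top)
  } else {
    first_order_stat(values, descriptor_name, n_bins = n_bins,
                     bin_range = bin_range)
  }
}

.all_descriptors <- function(values, n_bins = 32, bin_range = range(values)) {
  vapply(global_descriptors(), function(d) {
    global_descriptor(values, d, n_bins = n_bins, bin_range = bin_range)
  }, numeric(1))
}

# Pixel samples feeding the descriptors: per-map values at lesion pixels with
# a defined local map, plus the raw ADC values of the in-gland lesion pixels.
.lesion_samples <- function(image, gland, lesion, window_size = 9,
                            min_support = 0.5, n_bins = 32,
                            maps = NULL) {
  lesion <- clip_lesion_to_gland(lesion, gland)
  if (is.null(maps)) {
    maps <- compute_all_local_maps(image, gland, window_size = window_size,
                                   min_support = min_support, n_bins = n_bins)
  }
  sel <- lesion$mask & maps$defined
  map_samples <- lapply(maps$maps, function(m) m[sel])
  # gland-wide value ranges, shared bin support for the entropy/uniformity
  # descriptors of every lesion of this image
  map_ranges <- lapply(maps$maps, function(m) range(m[maps$defined]))
  list(map_samples = map_samples, adc = image$pixels[lesion$mask],
       map_ranges = map_ranges,
       adc_range = range(image$pixels[gland$mask]),
       n_defined = sum(sel))
}

.fv_from_samples <- function(samples, n_bins = 32) {
  if (samples$n_defined < 4) {
    stop(structure(
      class = c("lesion_too_small", "error", "condition"),
      list(message = sprintf(
        "lesion has only %d defined map pixels (>= 4 required)",
        samples$n_defined), call = NULL)))
  }
  vals <- c(
    unlist(Map(function(v, r) .all_descriptors(v, n_bins = n_bins,
                                               bin_range = r),
               samples$map_samples, samples$map_ranges),
           use.names = FALSE),
    .all_descriptors(samples$adc, n_bins = n_bins,
                     bin_range = samples$adc_range)
  )
  setNames(vals, feature_names())
}

#' Extract the 132-feature radiomic vector of one lesion
#'
#' @param image an [adc_image].
#' @param gland,lesion [roi_mask] objects aligned to the image.
#' @param window_size,min_support,n_bins local-map parameters, see
#'   [compute_all_local_maps()].
#' @param maps optionally, precomputed [compute_all_local_maps()] output for
#'   this image (avoids recomputation across lesions of the same slice).
#' @return Named numeric vector of length 132 in [feature_names()] order.
#' @export
extract_feature_vector <- function(image, gland, lesion, window_size = 9,
                                   min_support = 0.5, n_bins = 32,
                                   maps = NULL) {
  samples <- .lesion_samples(image, gland, lesion, window_size = window_size,
                             min_support = min_support, n_bins = n_bins,
                             maps = maps)
  .fv_from_samples(samples, n_bins = n_bins)
}

#' Build the lesion x feature table of a cohort
#'
#' Consumes a cohort (as produced by [generate_cohort()] or assembled from
#' [read_adc()]/[read_mask()] calls): a list of slice entries, each holding an
#' `image`, a `gland` mask and a list of `lesions`, plus a label table with
#' columns `lesion_id, patient_id, gg, pirads`. Pixel samples of lesions whose
#' `lesion_id` appears on several slices are pooled before the global
#' descriptors are computed. Lesions with fewer than 4 defined pixels are
#' excluded and reported in the `exclusions` attribute, never silently
#' dropped.
#'
#' @param cohort list with elements `slices` (list of entries described
#'   above) and `labels` (data.frame).
#' @param window_size,min_support,n_bins local-map parameters.
#' @return data.frame of class `feature_table`: columns `lesion_id`,
#'   `patient_id`, `gg`, `pirads`, `cspca`, `area_mm2` and the 132 features;
#'   attribute `exclusions` lists excluded lesions and reasons, attribute
#'   `params` the extraction parameters.
#' @export
build_feature_table <- function(cohort, window_size = 9, min_support = 0.5,
                                n_bins = 32) {
  labels <- cohort$labels
  if (is.null(labels$cspca)) labels$cspca <- labels$gg >= 3
  # pool pixel samples per lesion_id across slices
  samples <- list()
  areas <- list()
  for (entry in cohort$slices) {
    maps <- compute_all_local_maps(entry$image, entry$gland,
                                   window_size = window_size,
                                   min_support = min_support, n_bins = n_bins)
    for (les in entry$lesions) {
      id <- les$lesion_id
      s <- .lesion_samples(entry$image, entry$gland, les,
                           window_size = window_size, maps = maps,
                           n_bins = n_bins)
      if (is.null(samples[[id]])) {
        samples[[id]] <- s
        areas[[id]] <- lesion_area_mm2(les, entry$image$pixel_spacing)
      } else {
        old <- samples[[id]]
        samples[[id]] <- list(
          map_samples = Map(c, old$map_samples, s$map_samples),
          adc = c(old$adc, s$adc),
          map_ranges = Map(function(a, b) range(c(a, b)), old$map_ranges,
                           s$map_ranges),
          adc_range = range(c(old$adc_range, s$adc_range)),
          n_defined = old$n_defined + s$n_defined)
        areas[[id]] <- areas[[id]] +
          lesion_area_mm2(les, entry$image$pixel_spacing)
      }
    }
  }
  ids <- names(samples)
  exclusions <- data.frame(lesion_id = character(0), reason = character(0))
  rows <- list()
  for (id in ids) {
    fv <- tryCatch(.fv_from_samples(samples[[id]], n_bins = n_bins),
                   lesion_too_small = function(e) e)
    if (inherits(fv, "condition")) {
      exclusions <- rbind(exclusions, data.frame(
        lesion_id = id, reason = conditionMessage(fv)))
      .adc_log("excluding lesion %s: %s", id, conditionMessage(fv))
    } else {
      rows[[id]] <- fv
    }
  }
  keep <- labels[match(names(rows), labels$lesion_id), , drop = FALSE]
  if (anyNA(keep$lesion_id)) stop("lesions without a label table entry")
  fmat <- do.call(rbind, rows)
  tab <- data.frame(lesion_id = keep$lesion_id, patient_id = keep$patient_id,
                    gg = keep$gg, pirads = keep$pirads, cspca = keep$cspca,
                    area_mm2 = unlist(areas[names(rows)]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(fmat, check.names = FALSE))
  rownames(tab) <- NULL
  if (length(unique(tab$cspca)) < 2 || min(table(tab$cspca)) < 2) {
    stop("need at least 2 lesions in each class (csPCa and non-csPCa)")
  }
  structure(tab, class = c("feature_table", "data.frame"),
            exclusions = exclusions,
            params = list(window_size = window_size,
                          min_support = min_support, n_bins = n_bins,
                          percentile_rule = "type7-linear-interpolation"))
}

#' Feature columns of a feature table as a matrix
#' @param table a `feature_table` (or any data.frame holding the columns).
#' @param features which features; defaults to all 132.
#' @return Numeric matrix, lesions x features.
#' @export
feature_matrix <- function(table, features = feature_names()) {
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  as.matrix(as.data.frame(table, check.names = FALSE)[, features,
                                                      drop = FALSE])
}

#' Persist a feature table as CSV plus a JSON parameter sidecar
#' @param table a `feature_table`.
#' @param path CSV destination; the sidecar lands at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table, check.names = FALSE), path,
            row.names = FALSE)
  jsonlite::write_json(attr(table, "params"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
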