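# Synthetic ADC cohort generator. Emulates the statistical structure the
# analysis assumes: ~102 patients / 117 lesions with Gleason-group counts
# 25/36/21/23/12, lesion areas within 8..1655 pixels, and class-dependent
# lesion texture built from a two-level Gaussian tile model (per-tile local
# mean drawn from a between-tile distribution, per-pixel noise with a
# within-tile SD): aggressive lesions (GG >= 3) have more uniform local
# means and a higher, spatially more uniform local variance; low-grade
# lesions (GG < 3) are a patchwork of subregions with differing local means
# and heterogeneous local variance. Both classes carry per-lesion random
# effects (mean jitter, per-lesion heterogeneity and noise-level draws) so
# the across-lesion dispersion of the lesion features is comparable between
# groups, as in the reference cohort. GG1 and GG2 share one texture
# distribution, as do GG3/4/5, so the similarity analysis has a built-in
# negative control.

#' Specification of a synthetic ADC cohort
#'
#' Defaults restate the reference cohort: lesion counts per Gleason group
#' 25/36/21/23/12 (61 GG<3, 56 GG>=3) over 102 patients; lesion areas
#' log-uniform in 8..1655 pixels; 0.78 mm pixels (so 1655 px is about
#' 1007 mm^2). ADC levels are in 1e-6 mm^2/s: benign gland tissue around
#' 1250, low-grade lesions around 1050 with strong between-tile mean
#' heterogeneity, aggressive lesions around 1000 with uniform local means and
#' high, homogeneous within-tile noise.
#'
#' @param n_per_gg lesion counts for GG 1..5.
#' @param n_patients number of patients (each gets one slice).
#' @param image_size (rows, cols) of each slice.
#' @param gland_radii (row, col) half-axes of the elliptical gland, pixels.
#' @param lesion_area_px (min, max) lesion area in pixels.
#' @param pixel_spacing (row, col) spacing in mm.
#' @param tile tile (texture unit) side in pixels, matching the local window.
#' @param benign,gg_low,gg_high texture parameter lists with `mean`,
#'   `lesion_sd` (SD of the per-lesion mean random effect), `between_sd`
#'   (SD of per-tile means around the lesion mean; a length-2 value is a
#'   per-lesion uniform draw), `within_sd_range` (per-lesion draw range of
#'   the lesion's typical within-tile pixel SD) and `within_jitter`
#'   (half-width of the per-tile SD variation around the lesion's typical
#'   SD: small = spatially uniform local variance, large = heterogeneous).
#' @param class_blend upper bound of the per-lesion blend toward the
#'   opposite class's texture (default 0.15): each lesion drifts a uniform
#'   random fraction toward the other class, emulating the biological
#'   continuum between Gleason growth patterns.
#' @param noise_mult range of the per-lesion multiplicative noise-scale
#'   nuisance (default 0.7..1.4): one multiplier per lesion scales all its
#'   texture SDs, emulating patient-to-patient variation in tissue noise
#'   that both classes share; it spreads the lesion features of both classes
#'   proportionally, so within-group score dispersions stay comparable.
#' @param separation class-separation scale in [0, 1]: 1 = stated textures,
#'   0 = both lesion classes collapse to their midpoint (indistinguishable).
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_gg = c(25, 36, 21, 23, 12), n_patients = 102,
                        image_size = c(96, 96), gland_radii = c(42, 32),
                        lesion_area_px = c(8, 1655),
                        pixel_spacing = c(0.78, 0.78), tile = 9,
                        benign = list(mean = 1250, lesion_sd = 0,
                                      between_sd = 60,
                                      within_sd_range = c(70, 90),
                                      within_jitter = 15),
                        gg_low = list(mean = 1070, lesion_sd = 80,
                                      between_sd = c(180, 340),
                                      within_sd_range = c(45, 145),
                                      within_jitter = 60),
                        gg_high = list(mean = 980, lesion_sd = 80,
                                       between_sd = c(25, 140),
                                       within_sd_range = c(140, 270),
                                       within_jitter = 10),
                        class_blend = 0.08, noise_mult = c(0.7, 1.4),
                        separation = 1, seed = 1) {
  stopifnot(length(n_per_gg) == 5, all(n_per_gg >= 0),
            lesion_area_px[1] >= 8, separation >= 0, separation <= 1,
            sum(n_per_gg) - n_patients <= n_patients)
  structure(list(n_per_gg = setNames(as.integer(n_per_gg), 1:5),
                 n_patients = n_patients, image_size = image_size,
                 gland_radii = gland_radii, lesion_area_px = lesion_area_px,
                 pixel_spacing = pixel_spacing, tile = tile, benign = benign,
                 gg_low = gg_low, gg_high = gg_high,
                 class_blend = class_blend, noise_mult = noise_mult,
                 separation = separation, seed = seed),
            class = "cohort_spec")
}

# class texture with the separation scale applied (0 = classes identical)
.class_texture <- function(spec, gg) {
  if (is.na(gg) || gg == 0) return(spec$benign)
  lo <- spec$gg_low; hi <- spec$gg_high
  mid <- function(f) (lo[[f]] + hi[[f]]) / 2
  pick <- if (gg >= 3) hi else lo
  s <- spec$separation
  list(mean = mid("mean") + s * (pick$mean - mid("mean")),
       lesion_sd = mid("lesion_sd") + s * (pick$lesion_sd -
                                           mid("lesion_sd")),
       between_sd = mid("between_sd") + s * (pick$between_sd -
                                             mid("between_sd")),
       within_sd_range = mid("within_sd_range") +
         s * (pick$within_sd_range - mid("within_sd_range")),
       within_jitter = mid("within_jitter") +
         s * (pick$within_jitter - mid("within_jitter")))
}

# per-lesion texture parameters: the class texture blended a random
# fraction toward the opposite class (the Gleason-continuum random effect)
.lesion_params <- function(spec, gg) {
  own <- .class_texture(spec, gg)
  other <- .class_texture(spec, if (gg >= 3) 1 else 3)
  blend <- if (is.null(spec$class_blend)) 0 else spec$class_blend
  lam <- runif(1, 0, blend)
  out <- Map(function(a, b) a + lam * (b - a), own, other)
  # shared noise-scale nuisance: scales all texture SDs of this lesion
  if (!is.null(spec$noise_mult)) {
    m <- runif(1, spec$noise_mult[1], spec$noise_mult[2])
    for (f in c("between_sd", "within_sd_range", "within_jitter")) {
      out[[f]] <- out[[f]] * m
    }
  }
  out
}

# two-level Gaussian tile texture over the TRUE pixels of `mask`;
# tiles are aligned to a random phase of the global pixel grid
.tile_texture <- function(mask, params, tile) {
  idx <- which(mask, arr.ind = TRUE)
  off <- sample.int(tile, 2) - 1L
  ti <- (idx[, 1] - 1L + off[1]) %/% tile
  tj <- (idx[, 2] - 1L + off[2]) %/% tile
  id <- factor(paste(ti, tj))
  k <- nlevels(id)
  lesion_sd <- if (is.null(params$lesion_sd)) 0 else params$lesion_sd
  mu0 <- rnorm(1, params$mean, lesion_sd)
  # a length-2 between_sd is a per-lesion draw: lesions of one class differ
  # in how heterogeneous their local means are
  bsd <- if (length(params$between_sd) == 2) {
    runif(1, params$between_sd[1], params$between_sd[2])
  } else params$between_sd
  mu_t <- rnorm(k, mu0, bsd)
  # per-lesion typical within-tile SD, with per-tile jitter around it
  centre <- runif(1, params$within_sd_range[1], params$within_sd_range[2])
  jit <- if (is.null(params$within_jitter)) 0 else params$within_jitter
  sd_t <- pmax(runif(k, centre - jit, centre + jit), 5)
  g <- as.integer(id)
  pmax(rnorm(nrow(idx), mu_t[g], sd_t[g]), 1)
}

.ellipse_mask <- function(nr, nc, center, a, b, theta = 0) {
  dr <- outer(seq_len(nr) - center[1], rep(1, nc))
  dc <- outer(rep(1, nr), seq_len(nc) - center[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# lesion ellipse mask of approximately `area` pixels, random aspect & angle
.lesion_shape <- function(nr, nc, center, area, theta = NULL, q = NULL) {
  if (is.null(q)) q <- runif(1, 0.45, 0.95)
  if (is.null(theta)) theta <- runif(1, 0, pi)
  a <- sqrt(area / (pi * q)); b <- q * a
  m <- .ellipse_mask(nr, nc, center, a, b, theta)
  while (sum(m) < max(area * 0.8, 8)) {   # raster under-coverage guard
    a <- a * 1.05; b <- b * 1.05
    m <- .ellipse_mask(nr, nc, center, a, b, theta)
  }
  m
}

#' Generate one synthetic lesion texture patch
#'
#' @param spec a [cohort_spec()].
#' @param gg Gleason group (1-5) selecting the class texture.
#' @param area lesion area in pixels (>= 8).
#' @param seed optional RNG seed (deterministic patch for a given seed).
#' @return A matrix covering the lesion bounding box with ADC values inside
#'   the lesion and `NA` outside; the lesion mask is `!is.na(patch)`.
#' @export
generate_lesion_texture <- function(spec, gg, area, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), gg %in% 1:5, area >= 8)
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(2 * sqrt(area / pi) / 0.45) + 4
  m <- .lesion_shape(side, side, c(side / 2, side / 2), area)
  if (!any(m)) stop("infeasible area for the lesion geometry")
  vals <- .tile_texture(m, .lesion_params(spec, gg), spec$tile)
  patch <- matrix(NA_real_, side, side)
  patch[m] <- vals
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  patch[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

#' Generate a synthetic ADC cohort
#'
#' Produces one slice per patient: an ADC image, a gland mask and the
#' patient's lesion masks, plus the lesion label table. Lesion Gleason
#' groups and areas are drawn per the spec; lesions that cannot be placed
#' without overlap after 100 attempts raise an error.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `adc_cohort` with `slices` (each: `image`, `gland`,
#'   `lesions`), `labels` (data.frame `lesion_id, patient_id, gg, pirads,
#'   cspca, area_px`) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_lesions <- sum(spec$n_per_gg)
  gg_all <- sample(rep(1:5, spec$n_per_gg))
  # PIRADS drawn with the class-conditional frequencies of the reference
  # cohort (GG<3: 34/22/5 for PIRADS 3/4/5; GG>=3: 9/35/12)
  pirads_all <- vapply(gg_all, function(g) {
    if (g < 3) sample(3:5, 1, prob = c(34, 22, 5))
    else sample(3:5, 1, prob = c(9, 35, 12))
  }, integer(1))
  la <- log(spec$lesion_area_px)
  areas <- round(exp(runif(n_lesions, la[1], la[2])))
  # lesion-to-patient assignment: the largest lesions go one per patient;
  # the smallest surplus lesions become second lesions of random patients,
  # keeping the per-slice packing feasible
  extra <- n_lesions - spec$n_patients
  lesion_patient <- integer(n_lesions)
  by_size <- order(areas, decreasing = TRUE)
  lesion_patient[by_size[seq_len(spec$n_patients)]] <-
    sample.int(spec$n_patients)
  if (extra > 0) {
    lesion_patient[by_size[spec$n_patients + seq_len(extra)]] <-
      sample.int(spec$n_patients, extra)
  }
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  slices <- vector("list", spec$n_patients)
  labels <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    les_idx <- which(lesion_patient == p)
    les_idx <- les_idx[order(areas[les_idx], decreasing = TRUE)]
    placement <- NULL
    for (attempt in seq_len(100)) {     # re-place the whole slice on failure
      radii <- spec$gland_radii * runif(2, 0.92, 1.05)
      gland_m <- .ellipse_mask(nr, nc, c(nr, nc) / 2 + 0.5, radii[1],
                               radii[2])
      centers <- which(gland_m, arr.ind = TRUE)
      occupied <- matrix(FALSE, nr, nc)
      masks <- list()
      ok <- TRUE
      for (i in les_idx) {
        placed <- FALSE
        for (try in seq_len(100)) {
          ctr <- if (try <= 50) centers[sample.int(nrow(centers), 1), ]
            else c(nr, nc) / 2 + 0.5
          theta <- if (try <= 50) NULL else 0
          m <- .lesion_shape(nr, nc, ctr, areas[i], theta = theta)
          if (all(gland_m[m]) && !any(occupied[m])) {
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
        occupied <- occupied | m
        masks[[as.character(i)]] <- m
      }
      if (ok) {
        placement <- list(gland = gland_m, masks = masks)
        break
      }
    }
    if (is.null(placement)) {
      stop(sprintf("could not place lesions (areas %s px) in one gland",
                   paste(areas[les_idx], collapse = ", ")))
    }
    gland_m <- placement$gland
    img <- matrix(0, nr, nc)
    img[gland_m] <- .tile_texture(gland_m, spec$benign, spec$tile)
    lesions <- list()
    for (k in seq_along(les_idx)) {
      i <- les_idx[k]
      lid <- sprintf("%s_L%d", pid, k)
      m <- placement$masks[[as.character(i)]]
      img[m] <- .tile_texture(m, .lesion_params(spec, gg_all[i]), spec$tile)
      lesions[[k]] <- roi_mask(m, role = "lesion", lesion_id = lid)
      labels[[length(labels) + 1]] <- data.frame(
        lesion_id = lid, patient_id = pid, gg = gg_all[i],
        pirads = pirads_all[i], cspca = gg_all[i] >= 3, area_px = sum(m),
        stringsAsFactors = FALSE)
    }
    slices[[p]] <- list(
      image = adc_image(img, spec$pixel_spacing, patient_id = pid,
                        slice_id = paste0(pid, "_S1")),
      gland = roi_mask(gland_m, role = "gland"),
      lesions = lesions)
  }
  structure(list(slices = slices, labels = do.call(rbind, labels),
                 spec = spec),
            class = "adc_cohort")
}

#' @export
print.adc_cohort <- function(x, ...) {
  cat(sprintf("<adc_cohort> %d patients, %d lesions (%d GG<3 / %d GG>=3)\n",
              length(x$slices), nrow(x$labels), sum(!x$labels$cspca),
              sum(x$labels$cspca)))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Images as 16-bit TIFF (values rounded to integers), gland and per-lesion
#' masks as PNG, labels as CSV, and the generating spec as YAML.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sl in cohort$slices) {
    pid <- sl$image$patient_id
    write_tiff16(sl$image$pixels, file.path(dir, paste0(pid, "_adc.tif")))
    write_mask(sl$gland, file.path(dir, paste0(pid, "_gland.png")))
    for (les in sl$lesions) {
      write_mask(les, file.path(dir, paste0(les$lesion_id, "_mask.png")))
    }
  }
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  spec <- cohort$spec
  yaml::write_yaml(unclass(spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir the cohort directory.
#' @return An `adc_cohort` (images re-read from TIFF, masks from PNG).
#' @export
read_cohort <- function(dir) {
  labels <- read_lesion_table(file.path(dir, "labels.csv"))
  spec_path <- file.path(dir, "cohort_spec.yaml")
  spec <- if (file.exists(spec_path)) {
    sp <- yaml::read_yaml(spec_path)
    structure(sp, class = "cohort_spec")
  } else NULL
  spacing <- if (!is.null(spec)) unlist(spec$pixel_spacing) else c(1, 1)
  slices <- lapply(unique(labels$patient_id), function(pid) {
    image <- read_adc(file.path(dir, paste0(pid, "_adc.tif")),
                      patient_id = pid, pixel_spacing = spacing)
    gland <- read_mask(file.path(dir, paste0(pid, "_gland.png")), "gland")
    ids <- labels$lesion_id[labels$patient_id == pid]
    lesions <- lapply(ids, function(lid) {
      read_mask(file.path(dir, paste0(lid, "_mask.png")), "lesion",
                lesion_id = lid)
    })
    list(image = image, gland = gland, lesions = lesions)
  })
  structure(list(slices = slices, labels = labels, spec = spec),
            class = "adc_cohort")
}
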