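test_that("default cohort matches the stated lesion composition", {
  coh <- generate_cohort(cohort_spec(seed = 2))
  expect_equal(nrow(coh$labels), 117)
  expect_equal(sum(!coh$labels$cspca), 61)
  expect_equal(sum(coh$labels$cspca), 56)
  expect_equal(as.vector(table(coh$labels$gg)), c(25, 36, 21, 23, 12))
  expect_length(coh$slices, 102)
  expect_true(all(coh$labels$pirads %in% 3:5))
  expect_true(all(coh$labels$area_px >= 8))
  expect_true(all(coh$labels$area_px <= 1655 * 1.25))  # raster tolerance
  # masks: lesions within the gland, no overlap within a slice
  for (sl in coh$slices[1:10]) {
    acc <- matrix(FALSE, nrow(sl$gland$mask), ncol(sl$gland$mask))
    for (les in sl$lesions) {
      expect_true(all(sl$gland$mask[les$mask]))
      expect_false(any(acc & les$mask))
      acc <- acc | les$mask
    }
  }
})

test_that("cohort generation is deterministic under the seed", {
  a <- generate_cohort(cohort_spec(seed = 5, n_per_gg = c(3, 3, 2, 2, 2),
                                   n_patients = 10))
  b <- generate_cohort(cohort_spec(seed = 5, n_per_gg = c(3, 3, 2, 2, 2),
                                   n_patients = 10))
  expect_identical(a$labels, b$labels)
  expect_identical(a$slices[[3]]$image$pixels, b$slices[[3]]$image$pixels)
  # lesion texture patches are reproducible too
  p1 <- generate_lesion_texture(cohort_spec(), gg = 4, area = 200, seed = 9)
  p2 <- generate_lesion_texture(cohort_spec(), gg = 4, area = 200, seed = 9)
  expect_identical(p1, p2)
  expect_gte(sum(!is.na(p1)), 160)
})

test_that("class textures express the planted contrasts", {
  # embed generated patches in a benign background and extract features:
  # aggressive lesions must show a more uniform local mean on average
  spec <- cohort_spec()
  extract_one <- function(gg, seed) {
    patch <- generate_lesion_texture(spec, gg = gg, area = 500, seed = seed)
    n <- 64
    img <- matrix(1250, n, n)
    set.seed(seed * 7)
    img <- img + matrix(rnorm(n * n, 0, 80), n, n)
    les <- matrix(FALSE, n, n)
    r0 <- 20; c0 <- 20
    sel <- !is.na(patch)
    img[r0 + row(patch)[sel] - 1 + (c0 + col(patch)[sel] - 2) * n] <-
      patch[sel]
    les[r0 + row(patch)[sel] - 1 + (c0 + col(patch)[sel] - 2) * n] <- TRUE
    extract_feature_vector(adc_image(pmax(img, 1)), full_gland(n, n),
                           roi_mask(les, "lesion"))
  }
  low <- t(vapply(1:15, function(s) extract_one(1, s), numeric(132)))
  high <- t(vapply(1:15, function(s) extract_one(3, 100 + s), numeric(132)))
  expect_gt(mean(high[, "mu-u"]), mean(low[, "mu-u"]))
  expect_gt(mean(high[, "cv-m"]), mean(low[, "cv-m"]))
  # zero separation: classes become indistinguishable by construction
  null_spec <- cohort_spec(separation = 0, class_blend = 0,
                           n_per_gg = c(8, 8, 8, 4, 4), n_patients = 32,
                           seed = 3)
  ft <- build_feature_table(generate_cohort(null_spec))
  expect_lt(abs(auc_rank(ft[["cv-m"]], ft$cspca) - 0.5), 0.25)
  expect_lt(abs(auc_rank(ft[["mu-u"]], ft$cspca) - 0.5), 0.25)
})

test_that("GG1/GG2 share a texture distribution (negative control)", {
  ft <- build_feature_table(generate_cohort(cohort_spec(seed = 4)))
  g1 <- ft$gg == 1; g2 <- ft$gg == 2
  # across all 132 features, GG1-vs-GG2 Wilcoxon p-values look uniform:
  # no feature separates the two groups beyond multiplicity
  p <- apply(feature_matrix(ft), 2, function(v) {
    wilcoxon_rank_sum(v[g1], v[g2], "two.sided")
  })
  expect_gt(min(p) * 132, 0.01)          # Bonferroni: nothing survives
  expect_gt(mean(p > 0.1), 0.75)
})

test_that("cohorts round-trip through the on-disk formats", {
  spec <- cohort_spec(n_per_gg = c(3, 3, 2, 2, 2), n_patients = 10,
                      seed = 13)
  coh <- generate_cohort(spec)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$labels), 12)
  expect_equal(back$labels$gg, coh$labels$gg)
  # images are stored as integer TIFF: values match after rounding
  expect_equal(back$slices[[1]]$image$pixels,
               round(coh$slices[[1]]$image$pixels))
  expect_identical(back$slices[[1]]$gland$mask, coh$slices[[1]]$gland$mask)
  m_back <- back$slices[[1]]$lesions[[1]]$mask
  m_orig <- coh$slices[[1]]$lesions[[1]]$mask
  expect_identical(m_back, m_orig)
  expect_equal(back$slices[[1]]$image$pixel_spacing, c(0.78, 0.78))
})
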