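test_that("feature naming: 132 unique names, 120 map-derived", {
  fn <- feature_names()
  expect_length(fn, 132)
  expect_length(unique(fn), 132)
  expect_length(grep("^ADC-", fn), 12)
  expect_length(grep("^ADC-", fn, invert = TRUE), 120)
  expect_true(all(c("cv-m", "mu-u", "s-s", "sigma-IQR") %in% fn))
  expect_length(global_descriptors(), 12)
})

test_that("global descriptors follow the last-decile rule", {
  expect_equal(global_descriptor(1:10, "dmean"), 10)
  expect_equal(global_descriptor(1:10, "dmedian"), 10)
  # with ties at the 90th percentile, ties are included
  expect_equal(global_descriptor(c(1:8, 9, 9, 9), "dmean"), 9)
  expect_equal(global_descriptor(rep(7, 6), "dmean"), 7)
  expect_equal(global_descriptor(rep(7, 6), "dmedian"), 7)
  # the other ten descriptors are the first-order statistics
  x <- c(2, 4, 4, 7, 9)
  expect_equal(global_descriptor(x, "median"), oracle_stat(x, "median"))
  expect_equal(global_descriptor(x, "uniformity"),
               oracle_stat(x, "uniformity"))
  expect_error(global_descriptor(c(1, 2, 3), "mean"), "at least 4")
})

test_that("a constant lesion yields the degenerate feature values", {
  img <- flat_image(1200, 30, 30)
  gl <- full_gland(30, 30)
  les_m <- matrix(FALSE, 30, 30); les_m[10:20, 10:20] <- TRUE
  fv <- extract_feature_vector(img, gl, roi_mask(les_m, "lesion"))
  expect_length(fv, 132)
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["cv-m"]), 0)
  expect_equal(unname(fv["mu-u"]), 1)
  expect_equal(unname(fv["sigma-IQR"]), 0)
  expect_equal(unname(fv["ADC-m"]), 1200)
  expect_equal(unname(fv["ADC-d-mean"]), 1200)
})

test_that("feature tables carry labels, exclusions and are deterministic", {
  spec <- cohort_spec(n_per_gg = c(4, 4, 3, 3, 2), n_patients = 14,
                      seed = 9)
  coh <- generate_cohort(spec)
  ft <- build_feature_table(coh)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 16)
  expect_equal(ncol(ft), 6 + 132)
  expect_equal(sum(!ft$cspca), 8)
  expect_equal(as.vector(table(ft$gg)), c(4, 4, 3, 3, 2))
  expect_true(all(is.finite(feature_matrix(ft))))
  # determinism: regenerating the same cohort gives a bit-identical table
  ft2 <- build_feature_table(generate_cohort(spec))
  expect_identical(feature_matrix(ft), feature_matrix(ft2))
  # persisting: CSV + JSON sidecar
  p <- tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  expect_true(file.exists(p) && file.exists(paste0(p, ".json")))
  back <- read.csv(p, check.names = FALSE)
  expect_equal(nrow(back), 16)
})

test_that("tiny lesions are excluded with a reported reason", {
  img <- flat_image(1000, 40, 40)
  gl_m <- matrix(FALSE, 40, 40); gl_m[5:35, 5:35] <- TRUE
  blk40 <- function(r, c) {
    m <- matrix(FALSE, 40, 40); m[r, c] <- TRUE
    m
  }
  tiny <- blk40(6, 6:8)                     # 3 px, near the gland edge
  cohort <- list(
    slices = list(list(
      image = img, gland = roi_mask(gl_m, "gland"),
      lesions = list(roi_mask(blk40(10:18, 10:18), "lesion", "A"),
                     roi_mask(blk40(24:32, 24:32), "lesion", "B"),
                     roi_mask(blk40(10:18, 24:32), "lesion", "D"),
                     roi_mask(blk40(24:32, 10:18), "lesion", "E"),
                     roi_mask(tiny, "lesion", "C")))),
    labels = data.frame(lesion_id = c("A", "B", "D", "E", "C"),
                        patient_id = "P1", gg = c(1, 4, 2, 5, 2),
                        pirads = c(3, 4, 3, 5, 3)))
  ft <- build_feature_table(cohort)
  expect_equal(nrow(ft), 4)
  excl <- attr(ft, "exclusions")
  expect_equal(excl$lesion_id, "C")
  expect_match(excl$reason, "defined")
})

test_that("multi-slice lesions pool their pixel samples", {
  img1 <- flat_image(1000, 30, 30)
  img2 <- flat_image(2000, 30, 30)
  gl <- full_gland(30, 30)
  blk <- function(r, c) {
    m <- matrix(FALSE, 30, 30); m[r, c] <- TRUE
    m
  }
  les <- blk(10:20, 10:20)
  cohort <- list(
    slices = list(
      list(image = img1, gland = gl,
           lesions = list(roi_mask(les, "lesion", "L1"),
                          roi_mask(blk(4:8, 4:8), "lesion", "L2"),
                          roi_mask(blk(22:27, 22:27), "lesion", "L3"),
                          roi_mask(blk(4:8, 22:27), "lesion", "L4"))),
      list(image = img2, gland = gl,
           lesions = list(roi_mask(les, "lesion", "L1")))),
    labels = data.frame(lesion_id = c("L1", "L2", "L3", "L4"),
                        patient_id = "P1", gg = c(4, 1, 1, 4),
                        pirads = c(4, 3, 3, 4)))
  ft <- build_feature_table(cohort)
  # equal pixel counts at 1000 and 2000: the pooled raw-ADC mean is 1500
  expect_equal(ft[["ADC-mean"]][ft$lesion_id == "L1"], 1500)
  expect_equal(ft[["ADC-mean"]][ft$lesion_id == "L2"], 1000)
})
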