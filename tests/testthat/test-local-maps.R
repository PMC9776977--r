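test_that("first-order statistics follow their definitions", {
  # constant sample conventions
  x <- c(5, 5, 5, 5)
  expect_equal(first_order_stat(x, "mean"), 5)
  expect_equal(first_order_stat(x, "std"), 0)
  expect_equal(first_order_stat(x, "cv"), 0)
  expect_equal(first_order_stat(x, "entropy"), 0)
  expect_equal(first_order_stat(x, "uniformity"), 1)
  expect_equal(first_order_stat(x, "iqr"), 0)
  expect_equal(first_order_stat(x, "mad"), 0)
  expect_equal(first_order_stat(x, "skewness"), 0)   # undefined -> 0
  expect_equal(first_order_stat(x, "kurtosis"), 3)   # undefined -> 3
  # direct-formula oracle on a simple sample
  y <- c(1, 2, 3, 4)
  for (s in first_order_stats()) {
    expect_equal(first_order_stat(y, s), oracle_stat(y, s), info = s)
  }
  expect_equal(first_order_stat(y, "mean"), 2.5)
  expect_equal(first_order_stat(y, "median"), 2.5)
  expect_equal(first_order_stat(y, "iqr"), 1.5)
  # two equal-mass bins give exactly one bit of entropy
  z <- rep(c(0, 10), each = 8)
  expect_equal(first_order_stat(z, "entropy", n_bins = 2), 1)
  expect_equal(first_order_stat(z, "uniformity", n_bins = 2), 0.5)
  # zero mean: cv undefined -> 0
  expect_equal(first_order_stat(c(-1, 1), "cv"), 0)
  # sample-variance convention is switchable
  expect_equal(first_order_stat(y, "std", sample_var = TRUE), sd(y))
  expect_error(first_order_stat(5, "mean"), "at least 2")
})

test_that("first-order statistics match the oracle on random samples", {
  set.seed(11)
  for (r in 1:20) {
    x <- rnorm(sample(4:60, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 9))
    for (s in first_order_stats()) {
      expect_equal(first_order_stat(x, s), oracle_stat(x, s),
                   tolerance = 1e-12, info = s)
    }
  }
})

test_that("local map engine equals the naive double-loop oracle", {
  set.seed(3)
  for (r in 1:3) {
    img <- adc_image(matrix(runif(400, 500, 2000), 20, 20))
    gl_m <- matrix(runif(400) > 0.15, 20, 20)
    if (!any(gl_m)) gl_m[10, 10] <- TRUE
    gl <- roi_mask(gl_m, "gland")
    maps <- compute_all_local_maps(img, gl, window_size = 5)
    exact <- c("mean", "median", "iqr", "mad", "std", "entropy",
               "uniformity", "cv")
    for (s in exact) {
      expect_equal(maps$maps[[s]],
                   oracle_local_map(img$pixels, gl_m, s, window = 5),
                   tolerance = 1e-12, info = s)
    }
    for (s in c("skewness", "kurtosis")) {
      expect_equal(maps$maps[[s]],
                   oracle_local_map(img$pixels, gl_m, s, window = 5),
                   tolerance = 1e-9, info = s)
    }
  }
})

test_that("maps are shift-invariant / scale-covariant as appropriate", {
  set.seed(5)
  img0 <- matrix(runif(400, 800, 1600), 20, 20)
  gl <- full_gland()
  m0 <- compute_all_local_maps(adc_image(img0), gl)
  m_shift <- compute_all_local_maps(adc_image(img0 + 250), gl)
  for (s in c("std", "iqr", "mad", "entropy", "uniformity", "skewness",
              "kurtosis")) {
    expect_equal(m_shift$maps[[s]], m0$maps[[s]], tolerance = 1e-8, info = s)
  }
  expect_equal(m_shift$maps$mean, m0$maps$mean + 250, tolerance = 1e-8)
  m_scale <- compute_all_local_maps(adc_image(img0 * 3), gl)
  for (s in c("mean", "median", "std", "iqr", "mad")) {
    expect_equal(m_scale$maps[[s]], 3 * m0$maps[[s]], tolerance = 1e-8,
                 info = s)
  }
  expect_equal(m_scale$maps$cv, m0$maps$cv, tolerance = 1e-8)
})

test_that("window support rule and argument contracts hold", {
  img <- flat_image(1000, 30, 30)
  # a tiny gland island: centre pixel has only 9 of 81 window pixels inside
  gl_m <- matrix(FALSE, 30, 30); gl_m[14:16, 14:16] <- TRUE
  maps <- compute_all_local_maps(img, roi_mask(gl_m, "gland"),
                                 window_size = 9, min_support = 0.5)
  expect_false(any(maps$defined))
  maps2 <- compute_all_local_maps(img, roi_mask(gl_m, "gland"),
                                  window_size = 9, min_support = 0.1)
  expect_true(maps2$defined[15, 15])
  expect_error(compute_all_local_maps(img, full_gland(30, 30),
                                      window_size = 8), "odd")
  expect_error(compute_all_local_maps(flat_image(1, 10, 10),
                                      full_gland(10, 10),
                                      window_size = 11), "fit")
})

test_that("constant image gives the expected parametric maps", {
  maps <- compute_all_local_maps(flat_image(1000), full_gland())
  def <- maps$defined
  expect_true(any(def))
  expect_true(all(maps$maps$mean[def] == 1000))
  expect_true(all(maps$maps$std[def] == 0))
  expect_true(all(maps$maps$entropy[def] == 0))
  expect_true(all(maps$maps$uniformity[def] == 1))
  expect_true(all(is.na(maps$maps$mean[!def])))
  # exactly 10 named maps, and per-statistic extraction agrees
  expect_named(maps$maps, first_order_stats())
  one <- compute_local_map(flat_image(1000), full_gland(), "uniformity")
  expect_equal(one, maps$maps$uniformity)
})
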