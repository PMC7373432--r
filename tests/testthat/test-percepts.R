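test_that("area uses the palm calibration and is additive", {
  tpl <- arm_template()
  palm <- percept_mask(tpl, tpl$labels == 4L)
  expect_equal(mask_area_cm2(palm), 75)
  # 4 px at 0.25 cm2/px = 1 cm2 on a hand-built template
  ft <- flat_template(cm2_per_px = 0.25)
  m4 <- mask_from_pixels(ft, c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(mask_area_cm2(m4), 1.0)
  # additivity over disjoint unions
  a <- mask_from_pixels(ft, 1:3, rep(1, 3))
  b <- mask_from_pixels(ft, 1:5, rep(10, 5))
  u <- percept_mask(ft, a$pixels | b$pixels)
  expect_equal(mask_area_cm2(u), mask_area_cm2(a) + mask_area_cm2(b))
})

test_that("centroid arithmetic matches pixel-center geometry", {
  ft <- flat_template(mm_per_px = 1)
  # symmetric 3x3 square centred at (col 5, row 7) -> centroid (4.5, 6.5) mm
  sq <- mask_from_pixels(ft, rep(6:8, each = 3), rep(4:6, times = 3))
  expect_equal(mask_centroid_mm(sq), c(x = 4.5, y = 6.5))
  # single pixel: that pixel's center
  one <- mask_from_pixels(ft, 3, 9)
  expect_equal(mask_centroid_mm(one), c(x = 8.5, y = 2.5))
  # translation by (3, 4) px at 1 mm/px shifts the centroid by 5 mm
  moved <- mask_from_pixels(ft, rep(6:8, each = 3) + 4, rep(4:6, times = 3) + 3)
  d <- mask_centroid_mm(moved) - mask_centroid_mm(sq)
  expect_equal(sqrt(sum(d^2)), 5)
})

test_that("overlap fraction uses the smaller-mask denominator", {
  ft <- flat_template()
  a <- mask_from_pixels(ft, 1:4, rep(1, 4))
  expect_equal(overlap_fraction(a, a), 1.0)
  b <- mask_from_pixels(ft, 1:4, rep(10, 4))
  expect_equal(overlap_fraction(a, b), 0.0)
  # containment scores 1 regardless of the larger mask's size
  big <- mask_from_pixels(ft, rep(1:10, each = 5), rep(1:5, times = 10))
  inner <- mask_from_pixels(ft, 2:3, rep(2, 2))
  expect_equal(overlap_fraction(inner, big), 1.0)
  expect_equal(overlap_fraction(big, inner), 1.0)  # symmetric
  # different templates are rejected
  expect_error(overlap_fraction(a, mask_from_pixels(flat_template(30, 30), 1, 1)),
               "template")
})

test_that("reference amplitude maximizes week coverage then minimizes amplitude", {
  tr <- tibble::tibble(amplitude_mA = c(2, 2, 2, 2, 1.5, 1.5),
                       week = c(1, 2, 3, 4, 1, 2))
  expect_equal(select_reference_amplitude(tr), 2.0)
  tr2 <- tibble::tibble(amplitude_mA = rep(c(2, 3), each = 4),
                        week = rep(1:4, 2))
  expect_equal(select_reference_amplitude(tr2), 2.0)
  tr3 <- tibble::tibble(amplitude_mA = c(1, 2, 3), week = c(1, 2, 3))
  expect_error(select_reference_amplitude(tr3), "excluded")
})

test_that("weekly stability recovers constructed drift exactly", {
  tpl <- arm_template()
  pd <- percept_drift_params(c(31, 135), c(9, 12),
                             centroid_drift_mm_per_week = 5, jitter_mm = 0)
  ms <- generate_percept_series(tpl, pd, weeks = 4, reps_per_week = 2)
  ss <- weekly_stability(ms)
  # one pixel of calibration error tolerance
  expect_true(all(abs(ss$migration_mm[-1] - 5) <= tpl$mm_per_px))
  # zero drift, zero jitter: identical masks, zero migration and area change
  pd0 <- percept_drift_params(c(31, 135), c(9, 12))
  ss0 <- weekly_stability(generate_percept_series(tpl, pd0, weeks = 3))
  expect_equal(ss0$migration_mm[-1], c(0, 0))
  expect_equal(ss0$area_change_cm2[-1], c(0, 0))
})

test_that("area-change generation tracks the multiplicative ground truth", {
  tpl <- arm_template()
  pd <- percept_drift_params(c(62, 240), c(12, 14),
                             area_change_frac_per_week = -0.1)
  ms <- generate_percept_series(tpl, pd, weeks = 4, reps_per_week = 1)
  areas <- vapply(ms, mask_area_cm2, numeric(1))
  ratios <- areas[-1] / areas[-4]
  expect_true(all(abs(ratios - 0.9) < 0.02))  # raster tolerance
})

test_that("stability metrics match a brute-force pixel oracle", {
  tpl <- arm_template()
  set.seed(51)
  for (i in 1:10) {
    pd <- percept_drift_params(c(runif(1, 45, 75), runif(1, 110, 160)),
                               c(runif(1, 6, 12), runif(1, 6, 12)),
                               centroid_drift_mm_per_week = runif(1, 0, 6),
                               jitter_mm = runif(1, 0, 2))
    ms <- generate_percept_series(tpl, pd, weeks = 3, reps_per_week = 2)
    ss <- weekly_stability(ms)
    # oracle: raw pixel lists, no package helpers
    oracle <- lapply(1:3, function(w) {
      wk <- Filter(function(m) m$meta$week == w, ms)
      cents <- sapply(wk, function(m) {
        ij <- which(m$pixels, arr.ind = TRUE)
        c(mean(ij[, 2]) - 0.5, mean(ij[, 1]) - 0.5) * tpl$mm_per_px
      })
      list(cen = rowMeans(cents),
           area = mean(sapply(wk, function(m) sum(m$pixels))) * tpl$cm2_per_px)
    })
    for (w in 2:3) {
      mig <- sqrt(sum((oracle[[w]]$cen - oracle[[w - 1]]$cen)^2))
      expect_equal(ss$migration_mm[w], mig, tolerance = 1e-12)
      expect_equal(ss$area_change_cm2[w],
                   oracle[[w]]$area - oracle[[w - 1]]$area, tolerance = 1e-12)
    }
  }
})

test_that("missing weeks leave gaps rather than spurious week pairs", {
  tpl <- arm_template()
  m <- function(w) ellipse_mask(tpl, c(31, 135 + 5 * w), c(8, 8), week = w)
  ss <- weekly_stability(list(m(1), m(2), m(4)))
  expect_true(is.na(ss$migration_mm[ss$week == 4]))
  expect_false(is.na(ss$migration_mm[ss$week == 2]))
  expect_equal(attr(ss, "gaps"), 4L)
})

test_that("area-amplitude regression and modulation classes behave", {
  tr0 <- tibble::tibble(amplitude_mA = 1:5, area_cm2 = 2)
  s0 <- area_amplitude_slope(tr0)
  expect_equal(s0$beta_area, 0)
  expect_gt(s0$p_area, 0.99)
  tr1 <- tibble::tibble(amplitude_mA = 1:5,
                        area_cm2 = 0.25 * (1:5) + 1)
  expect_equal(area_amplitude_slope(tr1)$beta_area, 0.25, tolerance = 1e-12)
  # intensity-modulated but area-stable electrode
  set.seed(52)
  x <- seq(1, 5, length.out = 12)
  int_fit <- fit_intensity_models(x, 1.33 * x + rnorm(12, 0, 0.1))
  area_sl <- area_amplitude_slope(
    tibble::tibble(amplitude_mA = x, area_cm2 = 3 + rnorm(12, 0, 0.4)))
  expect_equal(classify_modulation(int_fit, area_sl), "intensity-only")
})
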