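# chamber renderer ---------------------------------------------------------

test_that("rendered object counts follow the dilution arithmetic", {
  p <- std_panel()
  # full-geometry expectation: 4.5e6 / 179 * 0.1 ~ 2514 red cells
  lam <- pocbc:::expected_class_counts(p, 2L, chamber_geometry(2))
  expect_equal(unname(lam[["rbc"]]), 4.5e6 / 179 * 0.1, tolerance = 1e-12)
  lam1 <- pocbc:::expected_class_counts(p, 1L, chamber_geometry(1))
  expect_equal(sum(lam1), 7000 / 9 * 0.1, tolerance = 1e-12)

  # observed counts on a small field stay within 4 Poisson SD
  g <- small_geom2(0.04)
  lam_small <- 4.5e6 / 179 * 0.1 * 0.04
  for (s in 1:5) {
    img <- render_chamber(p, 2, g, seed = s)
    n <- sum(img$truth_objects$class == "rbc")
    expect_lt(abs(n - lam_small), 4 * sqrt(lam_small))
  }
})

test_that("rendered counts are Poisson (variance/mean ratio near 1)", {
  p <- std_panel()
  g <- small_geom2(0.02)  # ~50 red cells expected
  counts <- vapply(1:250, function(s)
    sum(render_chamber(p, 2, g, seed = s)$truth_objects$class == "rbc"),
    numeric(1))
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("an almost empty field is still a valid image", {
  p <- gt_panel(rbc = 0.1, hb = 4, plt = 1, wbc = 0.5)
  g <- chamber_geometry(2, counting_area = 0.001)
  img <- render_chamber(p, 2, g, seed = 1)
  expect_s3_class(img, "chamber_image")
  expect_true(nrow(img$truth_objects) >= 0)
  tr <- img$truth_objects
  if (nrow(tr)) {
    expect_true(all(tr$x >= 0 & tr$x <= dim(img$pixels)[2]))
    expect_true(all(tr$y >= 0 & tr$y <= dim(img$pixels)[1]))
  }
})

test_that("impossible densities are refused with the analyte named", {
  p <- gt_panel(rbc = 60, hb = 14, plt = 250, wbc = 7)
  expect_error(render_chamber(p, 2, small_geom2(0.01), seed = 1),
               "rbc")
})

test_that("rendering is deterministic per seed", {
  p <- std_panel()
  g <- small_geom2(0.01)
  a <- render_chamber(p, 2, g, seed = 5)
  b <- render_chamber(p, 2, g, seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth_objects, b$truth_objects)
  expect_false(identical(a$pixels,
                         render_chamber(p, 2, g, seed = 6)$pixels))
})

test_that("raster dimensions follow the geometry", {
  g <- chamber_geometry(2, counting_area = 0.04, pixel_scale = 0.5)
  img <- render_chamber(std_panel(), 2, g, seed = 1)
  expect_equal(dim(img$pixels)[1:2], rep(round(sqrt(0.04) * 1000 / 0.5), 2))
})

# strip renderer ------------------------------------------------------------

test_that("the noiseless color response is strictly monotone over 4-19 g/dL", {
  hb <- seq(4, 19, by = 0.25)
  vals <- hb_forward_color(hb)
  expect_true(all(diff(vals) < 0))
  cfg0 <- strip_config(strip_noise_sd = 0, pixel_noise_sd = 0)
  read1 <- read_colorimetric_value(render_strip(8, cfg0, seed = 1))
  read2 <- read_colorimetric_value(render_strip(12, cfg0, seed = 1))
  expect_gt(read1, read2)
})

test_that("noiseless render/read round-trips through the calibration", {
  cfg0 <- strip_config(strip_noise_sd = 0, pixel_noise_sd = 0)
  cal <- default_hb_calibration()
  s <- render_strip(15, cfg0, seed = 2)
  expect_equal(as.numeric(hb_from_color(read_colorimetric_value(s), cal)),
               15, tolerance = 0.05)
})

test_that("default strip noise gives replicate HB CVs near the device anchor", {
  cal <- default_hb_calibration()
  vals <- vapply(1:10, function(i)
    as.numeric(hb_from_color(read_colorimetric_value(
      render_strip(14, seed = i)), cal)), numeric(1))
  cv <- 100 * sd(vals) / mean(vals)
  expect_gt(cv, 0.5)
  expect_lt(cv, 3.6)
})

# comparator ---------------------------------------------------------------

test_that("a zero-error comparator reproduces the truth exactly", {
  p <- std_panel()
  em <- comparator_error_model(proportional_cv = 0, constant_sd = 0)
  out <- simulate_reference_analyzer(p, em, seed = 1)
  expect_equal(out$rbc, p$rbc)
  expect_equal(out$hb, p$hb)
  expect_equal(out$wbc, p$wbc, tolerance = 1e-12)
  expect_equal(out$mch, 10 * p$hb / p$rbc, tolerance = 1e-9)
})

test_that("proportional error is reproduced in distribution", {
  p <- std_panel()
  em <- comparator_error_model(proportional_cv = 0.02, constant_sd = 0)
  vals <- vapply(1:1000, function(i)
    simulate_reference_analyzer(p, em, seed = i)$rbc / p$rbc, numeric(1))
  expect_lt(abs(sd(vals) - 0.02), 0.003)
  expect_lt(abs(mean(vals) - 1), 0.003)
})

test_that("nonpositive comparator results are clipped to the floor", {
  p <- gt_panel(rbc = 4.5, hb = 14, plt = 250, wbc = 7,
                diff_fractions = c(neu = 0.97, lym = 0.01, mon = 0.01,
                                   eosbas = 0.01))
  em <- comparator_error_model(proportional_cv = 0,
                               constant_sd = c(rbc = 0, hb = 0, plt = 0,
                                               neu = 0, lym = 0, mon = 0,
                                               eosbas = 10))
  expect_warning(out <- simulate_reference_analyzer(p, em, seed = 1),
                 "clipped")
  expect_gt(out$eosbas, 0)
})
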