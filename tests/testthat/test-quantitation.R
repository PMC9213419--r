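test_that("count-to-concentration follows the hemocytometer formula", {
  g <- chamber_geometry(2)  # 1 mm^2 x 0.1 mm
  expect_equal(count_to_concentration(2514, 179, g), 4500060)
  expect_equal(count_to_concentration(0, 179, g), 0)
  expect_equal(count_to_concentration(78, 9, g), 7020)
  expect_error(count_to_concentration(-1, 179, g), "nonnegative")
  expect_error(count_to_concentration(2.5, 179, g), "integer")
})

test_that("differential counting follows the argmax labels", {
  det <- data.frame(label = c(rep("neu", 60), rep("lym", 30),
                              rep("mon", 8), rep("eosbas", 2)))
  d <- differential_counts(det)
  expect_equal(unname(d$fractions),
               c(0.60, 0.30, 0.08, 0.02))
  empty <- differential_counts(NULL)
  expect_equal(sum(empty$counts), 0)
  expect_true(all(is.na(empty$fractions)))
})

test_that("immature cells are excluded from the differential denominator", {
  det <- data.frame(label = c(rep("neu", 57), rep("lym", 28),
                              rep("mon", 7), rep("eosbas", 3),
                              rep("imm", 5)))
  d <- differential_counts(det)
  expect_equal(d$n_mature, 95)
  expect_equal(unname(d$n_immature), 5)
  expect_equal(unname(d$fractions[["neu"]]), 57 / 95)
})

test_that("the colorimetric reader averages the window", {
  px <- array(0.2, dim = c(40, 60, 3))
  img <- list(pixels = px, roi = c(x0 = 10, y0 = 10, x1 = 30, y1 = 30))
  expect_equal(read_colorimetric_value(img), 0.2)
  px2 <- px
  px2[, 1:30, 2] <- 0.1
  px2[, 31:60, 2] <- 0.3
  img2 <- list(pixels = px2, roi = c(x0 = 20, y0 = 5, x1 = 40, y1 = 35))
  expect_equal(read_colorimetric_value(img2), 0.2)
  img3 <- list(pixels = px, roi = c(x0 = 50, y0 = 10, x1 = 70, y1 = 30))
  expect_error(read_colorimetric_value(img3), "roi")
})

test_that("a rendered strip reads back the forward map exactly", {
  cfg0 <- strip_config(strip_noise_sd = 0, pixel_noise_sd = 0)
  s <- render_strip(12, cfg0, seed = 1)
  expect_equal(read_colorimetric_value(s), hb_forward_color(12, cfg0),
               tolerance = 1e-6)
})

test_that("calibration fitting honors its preconditions", {
  st <- data.frame(hb = 4:19, value = hb_forward_color(4:19))
  m <- fit_hb_calibration(st)
  back <- hb_from_color(st$value, m)
  expect_true(all(abs(as.numeric(back) - st$hb) < 0.05))
  expect_equal(m$form, "satexp")
  expect_error(fit_hb_calibration(st[1:3, ]), "at least 4")
  dup <- st; dup$hb[2] <- dup$hb[1]
  expect_error(fit_hb_calibration(dup), "duplicated")
  nm <- st; nm$value[5] <- nm$value[1] + 1
  expect_error(fit_hb_calibration(nm), "monotone")
})

test_that("inversion round-trips and clamps out-of-range values", {
  m <- default_hb_calibration()
  for (hb in c(6, 10, 14, 18)) {
    est <- hb_from_color(hb_forward_color(hb), m)
    expect_lt(abs(as.numeric(est) - hb), 0.05)
    expect_false(attr(est, "clamped"))
  }
  too_dark <- hb_from_color(hb_forward_color(25), m)
  expect_true(attr(too_dark, "clamped"))
  expect_equal(as.numeric(too_dark), m$hb_range[2])
  # monotone: higher color value (less converted dye) means lower HB
  expect_gt(as.numeric(hb_from_color(0.2, m)),
            as.numeric(hb_from_color(0.3, m)))
})

test_that("hematimetric indices follow the rule-of-three estimator", {
  expect_equal(unname(estimate_indices(15, 5)), c(45, 90, 30))
  expect_equal(unname(estimate_indices(10, 4)), c(30, 75, 25))
  idx <- estimate_indices(13.7, 4.83)
  expect_equal(unname(idx[["mcv"]] / idx[["mch"]]), 3)
  expect_error(estimate_indices(0, 4), "> 0")
  # pluggable strategy
  alt <- estimate_indices(15, 5, strategy = function(hb, rbc)
    c(ht = 2.9 * hb, mcv = 88, mch = 29))
  expect_equal(unname(alt[["ht"]]), 43.5)
})

test_that("assembled panels satisfy the panel invariants", {
  cal <- default_hb_calibration()
  g <- chamber_geometry(2)
  set.seed(42)
  for (i in 1:100) {
    counts <- rpois(5, c(400, 40, 20, 6, 3))
    det1 <- data.frame(label = rep(c("neu", "lym", "mon", "eosbas", "imm"),
                                   counts))
    det2 <- data.frame(label = rep(c("rbc", "plt"), rpois(2, c(2500, 150))))
    p <- assemble_cbc(det1, det2, hb_forward_color(14), cal,
                      geometry = g, sex = "F")
    expect_equal(p$neu + p$lym + p$mon + p$eosbas, p$wbc,
                 tolerance = 1e-6)
    expect_equal(p$mch, 10 * p$hb / p$rbc, tolerance = 1e-6)
  }
})

test_that("missing components yield explicit NA, not errors", {
  cal <- default_hb_calibration()
  p <- assemble_cbc(NULL, NULL, hb_forward_color(14), cal)
  expect_true(is.na(p$rbc))
  expect_false(is.na(p$hb))
  p2 <- assemble_cbc(data.frame(label = character(0)),
                     data.frame(label = c("rbc", "plt")), NA, NULL,
                     geometry = chamber_geometry(2))
  expect_equal(p2$wbc, 0)
  expect_true(is.na(p2$hb))
})

test_that("concentration units round-trip through the CSV interface", {
  p <- analyte_panel(rbc = 4.5, hb = 14, ht = 42, mcv = 93, mch = 31,
                     plt = 250, neu = 4.2, lym = 2.1, mon = 0.5,
                     eosbas = 0.2, sex = "M")
  path <- tempfile(fileext = ".csv")
  write_panel_csv(p, path, sample_id = 7)
  back <- read_panel_csv(path, sex = "M")
  for (a in c("rbc", "hb", "plt", "wbc", "neu"))
    expect_equal(back[[a]], p[[a]])
  # a corrupted unit tag is an error, not a silent rescale
  df <- read.csv(path)
  df$unit[df$analyte == "plt"] <- "1e6/mm3"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_panel_csv(path), "unit mismatch")
})
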