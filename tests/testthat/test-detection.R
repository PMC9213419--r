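# tiling -------------------------------------------------------------------

test_that("tiles cover every pixel and respect the overlap contract", {
  img <- array(0, dim = c(1000, 1000, 3))
  spec <- tile_spec(250, 25)
  tiles <- tile_image(img, spec)
  expect_gte(length(tiles), 16)
  covered <- matrix(FALSE, 1000, 1000)
  for (t in tiles) {
    rows <- (t$origin[2] + 1):(t$origin[2] + dim(t$pixels)[1])
    cols <- (t$origin[1] + 1):(t$origin[1] + dim(t$pixels)[2])
    covered[rows, cols] <- TRUE
  }
  expect_true(all(covered))
})

test_that("degenerate tilings collapse to a single tile at the origin", {
  img <- array(0, dim = c(100, 100, 3))
  expect_warning(tiles <- tile_image(img, tile_spec(256, 16)), "single tile")
  expect_length(tiles, 1)
  expect_equal(tiles[[1]]$origin, c(0L, 0L))
})

test_that("tiles reproduce the image bit-exactly", {
  set.seed(1)
  img <- array(runif(300 * 300 * 3), dim = c(300, 300, 3))
  tiles <- tile_image(img, tile_spec(120, 30))
  recon <- array(NA_real_, dim = dim(img))
  for (t in tiles) {
    rows <- (t$origin[2] + 1):(t$origin[2] + dim(t$pixels)[1])
    cols <- (t$origin[1] + 1):(t$origin[1] + dim(t$pixels)[2])
    recon[rows, cols, ] <- t$pixels
  }
  expect_identical(recon, img)
  expect_error(tile_spec(64, 40), "twice")
})

# single-tile detection -----------------------------------------------------

test_that("a blank tile yields no detections", {
  cfg <- detector_config(2)
  g <- chamber_geometry(2)
  blank <- array(0.03, dim = c(128, 128, 3))
  expect_equal(nrow(detect_in_tile(blank, cfg, g)), 0)
})

test_that("isolated and well-separated discs are each found once", {
  cfg <- detector_config(2)
  g <- chamber_geometry(2)
  one <- disc_field(128, 60, 60)
  d1 <- detect_in_tile(one, cfg, g)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$label, "rbc")
  expect_lt(abs(d1$cx - 60), 1.5)
  expect_lt(abs(d1$diameter_um - 7.4), 1)

  two <- disc_field(160, c(50, 110), c(50, 110))  # > 3 diameters apart
  d2 <- detect_in_tile(two, cfg, g)
  expect_equal(nrow(d2), 2)
})

test_that("class probabilities are a proper distribution", {
  p <- std_panel()
  img <- render_chamber(p, 2, small_geom2(0.02), seed = 3)
  det <- detect_cells(img)
  psum <- det$p_rbc + det$p_plt
  expect_true(all(abs(psum - 1) < 1e-9))
  img1 <- render_chamber(p, 1, small_geom1(0.1), seed = 3)
  det1 <- detect_cells(img1)
  psum1 <- det1$p_neu + det1$p_lym + det1$p_mon + det1$p_eosbas + det1$p_imm
  expect_true(all(abs(psum1 - 1) < 1e-9))
})

# merging ------------------------------------------------------------------

test_that("identical boxes merge and disjoint boxes survive", {
  b <- random_boxes(1, 1)
  two_same <- rbind(b, b)
  expect_equal(nrow(merge_detections(two_same, 0.5)), 1)
  apart <- random_boxes(2, 2)
  apart$x0 <- c(0, 50); apart$x1 <- c(10, 60)
  apart$y0 <- c(0, 50); apart$y1 <- c(10, 60)
  expect_equal(nrow(merge_detections(apart, 0.5)), 2)
})

test_that("overlap chains collapse transitively to one survivor", {
  # A-B and B-C overlap above threshold, A-C below: one connected group
  det <- data.frame(x0 = c(0, 4, 8), y0 = 0, x1 = c(10, 14, 18), y1 = 10,
                    cx = c(5, 9, 13), cy = 5, label = "rbc",
                    confidence = c(0.9, 0.8, 0.7), diameter_um = 7,
                    source_tile = 1L)
  thr <- 0.4  # A-B IoU = 6/14 ~ 0.43; A-C IoU = 2/18 ~ 0.11
  merged <- merge_detections(det, thr)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$confidence, 0.9)
})

test_that("merging is idempotent and matches the connected-components oracle", {
  for (case in 1:12) {
    n <- sample(3:20, 1)
    det <- random_boxes(n, 100 + case)
    thr <- runif(1, 0.2, 0.7)
    m1 <- merge_detections(det, thr)
    m2 <- merge_detections(m1, thr)
    expect_identical(m1, m2)
    oracle <- merge_oracle(det, thr)
    expect_equal(m1$x0, oracle$x0)
    expect_equal(m1$confidence, oracle$confidence)
    # surviving pairs are below threshold
    if (nrow(m1) > 1) {
      for (i in 1:(nrow(m1) - 1)) {
        ious <- pocbc:::iou_one_many(
          unlist(m1[i, c("x0", "y0", "x1", "y1")]),
          as.matrix(m1[(i + 1):nrow(m1), c("x0", "y0", "x1", "y1")]))
        expect_true(all(ious < thr))
      }
    }
  }
})

# full detection pipeline ---------------------------------------------------

test_that("well-separated cells are all found with nothing spurious", {
  # deterministic grid of 100 cells, far from tile seams
  xs <- rep(seq(30, 470, length.out = 10), 10)
  ys <- rep(seq(30, 470, length.out = 10), each = 10)
  px <- disc_field(500, xs, ys)
  g <- chamber_geometry(2)
  det <- detect_cells(px, tile_spec(300, 48), geometry = g)
  expect_equal(nrow(det), 100)
  expect_true(all(det$label == "rbc"))
})

test_that("a cell on a tile seam is detected exactly once", {
  # stride of tile 128/overlap 48 puts a seam at x = 128; center a cell there
  px <- disc_field(208, c(128, 40), c(104, 40))
  det <- detect_cells(px, tile_spec(128, 48),
                      geometry = chamber_geometry(2))
  expect_equal(nrow(det), 2)
})

test_that("an empty image yields an empty detection table", {
  px <- array(0.03, dim = c(256, 256, 3))
  det <- detect_cells(px, geometry = chamber_geometry(2))
  expect_equal(nrow(det), 0)
})

test_that("detections are independent of tile size away from seams", {
  xs <- rep(seq(40, 360, length.out = 6), 6)
  ys <- rep(seq(40, 360, length.out = 6), each = 6)
  px <- disc_field(400, xs, ys)
  g <- chamber_geometry(2)
  d_a <- detect_cells(px, tile_spec(200, 48), geometry = g)
  d_b <- detect_cells(px, tile_spec(400, 48), geometry = g)
  expect_equal(nrow(d_a), 36)
  expect_equal(nrow(d_b), 36)
  oa <- order(d_a$cx, d_a$cy); ob <- order(d_b$cx, d_b$cy)
  expect_equal(d_a$cx[oa], d_b$cx[ob], tolerance = 0.5)
  expect_equal(d_a$cy[oa], d_b$cy[ob], tolerance = 0.5)
  expect_equal(d_a$label[oa], d_b$label[ob])
})

test_that("touching and superposed red-cell pairs are resolved into two", {
  g <- chamber_geometry(2)
  cfg <- detector_config(2)
  # calibrator singletons plus one pair at separations across the
  # touching / merged / superposed regimes
  for (sep_um in c(1.5, 3, 4.5, 6, 7.5)) {
    base <- data.frame(x = c(40, 160, 40, 160), y = c(40, 40, 160, 160),
                       diameter_um = 7.4, class = "rbc", amp = 1)
    pair <- data.frame(x = c(100, 100 + sep_um / 0.5), y = 100,
                       diameter_um = 7.4, class = "rbc", amp = 1)
    px <- render_field(200, rbind(base, pair), 0.5, noise_sd = 0)
    det <- detect_in_tile(px, cfg, g)
    expect_equal(nrow(det), 6)
  }
})
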