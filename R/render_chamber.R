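#' Draw a table of cells into an RGB raster
#'
#' Deterministic rasterizer used by [render_chamber()] and by tests that
#' need fields with hand-placed cells. Coordinates are 0-based continuous
#' pixel coordinates (the center of the top-left pixel is (0.5, 0.5));
#' intensities are linear and additive, so superposed cells sum.
#'
#' @param side_px Side of the square raster in pixels.
#' @param cells data.frame with columns x, y (px), diameter_um, class, and
#'   optionally amp (per-cell amplitude factor, default 1).
#' @param pixel_scale um per pixel.
#' @param appearance Appearance table, see [cell_appearance()].
#' @param bg Background level.
#' @param noise_sd Per-pixel Gaussian noise SD (shared across channels);
#'   0 for a noiseless field.
#' @param seed Seed for the noise draw (ignored when `noise_sd = 0`).
#' @return Array `side_px x side_px x 3` of linear intensities.
#' @export
render_field <- function(side_px, cells, pixel_scale,
                         appearance = cell_appearance(),
                         bg = RENDER_BG, noise_sd = RENDER_NOISE_SD,
                         seed = 1L) {
  px <- array(bg, dim = c(side_px, side_px, 3))
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(side_px * side_px, 0, noise_sd),
                                    side_px, side_px))
    for (ch in 1:3) px[, , ch] <- px[, , ch] + noise
  }
  if (is.null(cells) || nrow(cells) == 0) return(px)
  app <- appearance[match(cells$class, appearance$class), ]
  if (anyNA(app$class)) stop("unknown cell class in cells table")
  amp <- if ("amp" %in% names(cells)) cells$amp else rep(1, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d_px <- cells$diameter_um[i] / pixel_scale
    s <- (d_px / 2) / HALFMAX_K
    ext <- ceiling(3 * s)
    # pixel centers are at integer+0.5 in 0-based continuous coords
    c0 <- floor(cells$x[i]) + 1L   # 1-based column of the center pixel
    r0 <- floor(cells$y[i]) + 1L
    cc <- max(1L, c0 - ext):min(side_px, c0 + ext)
    rr <- max(1L, r0 - ext):min(side_px, r0 + ext)
    if (!length(cc) || !length(rr)) next
    dx <- (cc - 0.5) - cells$x[i]
    dy <- (rr - 0.5) - cells$y[i]
    prof <- exp(-outer(dy^2, dx^2, "+") / (2 * s^2))
    col3 <- amp[i] * c(app$r[i], app$g[i], app$b[i])
    for (ch in 1:3)
      px[rr, cc, ch] <- px[rr, cc, ch] + col3[ch] * prof
  }
  px
}

# Expected object count per class for a panel in a chamber.
expected_class_counts <- function(panel, chamber_id, geometry,
                                  scheme = dilution_scheme()) {
  vol <- chamber_volume(geometry)
  dil <- dilution_for_chamber(scheme, chamber_id)
  if (chamber_id == 2L) {
    c(rbc = panel$rbc * 1e6 / dil * vol,
      plt = panel$plt * 1e3 / dil * vol)
  } else {
    wbc_n <- panel$wbc * 1e3 / dil * vol
    counts <- setNames(wbc_n * panel$diff_fractions,
                       c("neu", "lym", "mon", "eosbas"))
    if (panel$flags_truth[["immature_cells"]])
      counts <- c(counts, imm = 0.08 * wbc_n)
    counts
  }
}

#' Render a counting-chamber field from a ground-truth panel
#'
#' Object counts per class are Poisson with mean `concentration / dilution *
#' counted volume`; positions are uniform over the field (complete spatial
#' randomness), emulating the projected composite of a settled chamber.
#' Red-cell diameters follow the panel's mean/CV; other classes use the
#' appearance table. When the panel carries the `plt_clumps` flag, a
#' quarter of the platelets are placed in tight clusters of 3-8 cells whose
#' members sit within 1.2 diameters of the cluster seed. When
#' `immature_cells` is flagged, an extra immature class is rendered in
#' chamber 1 at 8% of the leukocyte density.
#'
#' @param panel A [gt_panel()].
#' @param chamber_id 1 (WBC) or 2 (RBC/PLT).
#' @param geometry A [chamber_geometry()]; defaults to the standard chamber.
#' @param seed Integer seed; the image is a deterministic function of it.
#' @param scheme A [dilution_scheme()].
#' @param appearance Appearance table.
#' @return Object of class `chamber_image`: list(pixels, geometry,
#'   truth_objects) where truth_objects has x, y (0-based px), diameter_um,
#'   class.
#' @export
#' @examples
#' p <- gt_panel(rbc = 4.5, hb = 14, plt = 250, wbc = 7)
#' img <- render_chamber(p, 2, chamber_geometry(2, counting_area = 0.02),
#'                       seed = 7)
#' nrow(img$truth_objects)
render_chamber <- function(panel, chamber_id, geometry = chamber_geometry(chamber_id),
                           seed = 1L, scheme = dilution_scheme(),
                           appearance = cell_appearance()) {
  stopifnot(inherits(panel, "gt_panel"))
  if (geometry$chamber_id != chamber_id)
    stop("geometry was built for chamber ", geometry$chamber_id)
  side <- field_side_px(geometry)
  lambda <- expected_class_counts(panel, chamber_id, geometry, scheme)

  # packing guard: refuse fields where expected projected cell area exceeds
  # 40% of the field (counting would be meaningless)
  app <- appearance
  d_of <- function(cl) if (cl == "rbc") panel$rbc_diameter_mean else
    app$diameter_um[app$class == cl]
  areas <- vapply(names(lambda),
                  function(cl) pi * (d_of(cl) / 2)^2, numeric(1))
  occupancy <- sum(lambda * areas) / (geometry$counting_area * 1e6)
  if (occupancy > 0.4) {
    worst <- names(lambda)[which.max(lambda * areas)]
    stop("expected cell density too high to render (", worst,
         " exceeds the packing limit)")
  }

  side_um <- side * geometry$pixel_scale
  truth <- with_seed(seed, {
    rows <- list()
    for (cl in names(lambda)) {
      n <- rpois(1, lambda[[cl]])
      if (n == 0) next
      if (cl == "rbc") {
        dm <- panel$rbc_diameter_mean
        dcv <- panel$rbc_diameter_cv
      } else {
        dm <- app$diameter_um[app$class == cl]
        dcv <- app$diameter_cv[app$class == cl]
      }
      diam <- rtruncnorm1(n, dm, dm * dcv, dm * (1 - 3.5 * dcv),
                          dm * (1 + 3.5 * dcv))
      x <- runif(n, 0, side_um) / geometry$pixel_scale
      y <- runif(n, 0, side_um) / geometry$pixel_scale
      if (cl == "plt" && panel$flags_truth[["plt_clumps"]] && n >= 3) {
        n_cl <- round(0.25 * n)
        i <- 1
        while (i <= n_cl) {
          k <- min(sample(3:8, 1), n_cl - i + 1)
          if (k < 2) break
          sx <- runif(1, 0, side_um)
          sy <- runif(1, 0, side_um)
          rad <- 1.2 * dm
          th <- runif(k, 0, 2 * pi)
          rr <- rad * sqrt(runif(k))
          x[i:(i + k - 1)] <- pmin(pmax(sx + rr * cos(th), 0), side_um) /
            geometry$pixel_scale
          y[i:(i + k - 1)] <- pmin(pmax(sy + rr * sin(th), 0), side_um) /
            geometry$pixel_scale
          i <- i + k
        }
      }
      rows[[cl]] <- data.frame(x = x, y = y, diameter_um = diam, class = cl,
                               amp = pmin(pmax(rnorm(n, 1, AMP_JITTER_SD),
                                               0.75), 1.25))
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(x = numeric(0), y = numeric(0), diameter_um = numeric(0),
                 class = character(0), amp = numeric(0))
  })
  rownames(truth) <- NULL
  px <- render_field(side, truth, geometry$pixel_scale, appearance,
                     seed = split_seed(seed, 999983L))
  structure(list(pixels = px, geometry = geometry,
                 truth_objects = truth[, c("x", "y", "diameter_um", "class")]),
            class = "chamber_image")
}

#' @export
print.chamber_image <- function(x, ...) {
  cat(sprintf("<chamber_image> chamber %d, %d x %d px (%.2f um/px), %d truth objects\n",
              x$geometry$chamber_id, dim(x$pixels)[1], dim(x$pixels)[2],
              x$geometry$pixel_scale,
              if (is.null(x$truth_objects)) 0L else nrow(x$truth_objects)))
  invisible(x)
}
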