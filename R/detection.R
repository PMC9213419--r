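#' Tiling specification for large chamber images
#'
#' The full field is processed as a grid of overlapping square tiles so
#' that detection operates on small sub-images. The overlap margin must
#' exceed the largest cell diameter (in pixels): every cell then lies fully
#' inside the interior of at least one tile, and duplicates arising from
#' cells seen by two tiles are removed by [merge_detections()].
#'
#' @param tile_size Tile side in pixels.
#' @param overlap_margin Overlap between adjacent tiles in pixels; must be
#'   less than half the tile size.
#' @return Object of class `tile_spec`.
#' @export
tile_spec <- function(tile_size = 1024, overlap_margin = 48) {
  if (tile_size <= 2 * overlap_margin)
    stop("tile_size must exceed twice the overlap_margin")
  structure(list(tile_size = as.integer(tile_size),
                 overlap_margin = as.integer(overlap_margin)),
            class = "tile_spec")
}

tile_starts <- function(extent, tile, overlap) {
  if (tile >= extent) return(0L)
  stride <- tile - overlap
  s <- seq(0L, extent - tile, by = stride)
  if (max(s) + tile < extent) s <- c(s, extent - tile)
  as.integer(unique(s))
}

#' Split an image into overlapping tiles
#'
#' @param image A `chamber_image` or a raster array (h x w x 3 or h x w).
#' @param spec A [tile_spec()].
#' @return List of tiles; each is `list(pixels, origin = c(x0, y0),
#'   image_dim = c(w, h))` with a 0-based origin. The union of tiles covers
#'   every pixel.
#' @export
tile_image <- function(image, spec = tile_spec()) {
  px <- if (inherits(image, "chamber_image")) image$pixels else image
  h <- dim(px)[1]; w <- dim(px)[2]
  if (spec$tile_size >= h && spec$tile_size >= w) {
    if (spec$tile_size > h && spec$tile_size > w)
      warning("tile_size larger than image; using a single tile")
    return(list(list(pixels = px, origin = c(0L, 0L), image_dim = c(w, h))))
  }
  xs <- tile_starts(w, spec$tile_size, spec$overlap_margin)
  ys <- tile_starts(h, spec$tile_size, spec$overlap_margin)
  tiles <- list()
  for (y0 in ys) for (x0 in xs) {
    rows <- (y0 + 1):min(h, y0 + spec$tile_size)
    cols <- (x0 + 1):min(w, x0 + spec$tile_size)
    sub <- if (length(dim(px)) == 3) px[rows, cols, , drop = FALSE]
           else px[rows, cols, drop = FALSE]
    tiles[[length(tiles) + 1]] <- list(pixels = sub,
                                       origin = c(x0, y0),
                                       image_dim = c(w, h))
  }
  tiles
}

#' Reference detector configuration
#'
#' A deterministic classical detector standing in for a trained network,
#' honoring the same contract (boxes, class probabilities, confidence).
#' Segmentation runs per chromatic projection: each projection is a linear
#' combination of the RGB channels chosen so that one cell family dominates
#' (in chamber 2 the platelet projection cancels red cells and vice versa,
#' emulating the differential stain). Within a projection: Gaussian smooth,
#' fixed threshold above the tile background, and an intensity-basin
#' watershed to split touching cells; regions that remain multi-cell are
#' resolved by elongation cuts and a peak-amplitude coincidence
#' (multiplicity) correction - the imaging analogue of coincidence
#' correction in impedance counters (see [detect_in_tile()]).
#' Classification is by nearest class prototype in (chromaticity,
#' log-diameter) feature space with softmax-normalized scores.
#'
#' @param chamber_id 1 or 2.
#' @param threshold Detection threshold on the smoothed projection response,
#'   above tile background.
#' @param blur_sigma Smoothing sigma in px.
#' @param appearance Appearance table the prototypes are taken from
#'   (the stand-in for detector training).
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(chamber_id, threshold = 0.12, blur_sigma = 1,
                            appearance = cell_appearance()) {
  app <- appearance[appearance$chamber == chamber_id, ]
  protos <- data.frame(class = app$class,
                       diameter_um = app$diameter_um,
                       amp_r = app$r, amp_g = app$g, amp_b = app$b)
  tot <- protos$amp_r + protos$amp_g + protos$amp_b
  protos$chroma_r <- protos$amp_r / tot
  protos$chroma_g <- protos$amp_g / tot
  protos$chroma_b <- protos$amp_b / tot
  if (chamber_id == 2L) {
    # chromatic unmixing: each projection is the class color orthogonalized
    # against the other class, so the other family contributes ~zero (not a
    # negative shadow that could swallow a superposed cell)
    rbc_col <- unlist(protos[protos$class == "rbc", c("amp_r", "amp_g", "amp_b")])
    plt_col <- unlist(protos[protos$class == "plt", c("amp_r", "amp_g", "amp_b")])
    orth <- function(a, b) a - sum(a * b) / sum(b * b) * b
    projections <- list(
      rbc = list(weights = unname(orth(rbc_col, plt_col)), classes = "rbc",
                 scale_um = c(3.5, 13)),
      plt = list(weights = unname(orth(plt_col, rbc_col)), classes = "plt",
                 scale_um = c(1.2, 4.5))
    )
  } else {
    projections <- list(
      wbc = list(weights = c(1, 1, 1) / 3,
                 classes = c("neu", "lym", "mon", "eosbas", "imm"),
                 scale_um = c(5.5, 24))
    )
  }
  structure(list(chamber_id = as.integer(chamber_id),
                 threshold = threshold, blur_sigma = blur_sigma,
                 ws_tolerance = 0.04, elongation_ratio = 1.35,
                 projections = projections, prototypes = protos,
                 chroma_scale = 0.05, size_scale = 0.25,
                 max_multiplicity = 4L),
            class = "detector_config")
}

# project an RGB raster onto a weight vector
project_raster <- function(px, w3) {
  if (length(dim(px)) == 2) return(px * sum(w3))
  w3[1] * px[, , 1] + w3[2] * px[, , 2] + w3[3] * px[, , 3]
}

# prototype amplitude of a class under a projection (pre-smoothing)
proto_amplitude <- function(config, class, proj_w) {
  p <- config$prototypes[config$prototypes$class == class, ]
  sum(proj_w * c(p$amp_r, p$amp_g, p$amp_b))
}

# prototype peak amplitude of a class under a projection, after smoothing
proto_peak_amplitude <- function(config, class, proj_w, pixel_scale) {
  p <- config$prototypes[config$prototypes$class == class, ]
  s <- (p$diameter_um / 2 / pixel_scale) / HALFMAX_K
  proto_amplitude(config, class, proj_w) * s^2 / (s^2 + config$blur_sigma^2)
}

#' Detect cells in a single tile
#'
#' Returns detections in tile-local 0-based pixel coordinates with
#' half-open boxes. Regions touching a tile edge that is an interior seam
#' (not an image boundary) are discarded; the overlap margin guarantees the
#' same cell is seen whole by a neighboring tile. Deterministic: no
#' randomness is involved.
#'
#' Touching and superposed same-class cells are resolved in three layers:
#' an intensity-basin watershed splits pairs whose profiles still show two
#' maxima; a principal-axis elongation test (second-moment axis ratio)
#' catches pairs merged into one elongated region; and a peak-amplitude
#' multiplicity test catches full superpositions, whose summed peak is an
#' integer multiple of the single-cell prototype peak (a single cell's
#' stain jitter is bounded well below 1.5x). Multi-cell regions are split
#' into slabs perpendicular to the principal axis and one detection is
#' emitted per slab.
#'
#' @param tile A tile from [tile_image()] (or a raw raster array, in which
#'   case all edges count as image boundaries).
#' @param config A [detector_config()].
#' @param geometry The [chamber_geometry()] the image was rendered with
#'   (provides the pixel scale).
#' @return data.frame: x0, y0, x1, y1, cx, cy, label, confidence,
#'   diameter_um, source_tile, p_<class> columns. Empty on a blank tile.
#' @export
detect_in_tile <- function(tile, config, geometry) {
  if (!is.list(tile) || is.null(tile$pixels))
    tile <- list(pixels = tile, origin = c(0L, 0L),
                 image_dim = c(dim(tile)[2], dim(tile)[1]))
  px <- tile$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  ps <- geometry$pixel_scale
  # which tile edges are interior seams
  seam <- c(left = tile$origin[1] > 0,
            top = tile$origin[2] > 0,
            right = tile$origin[1] + w < tile$image_dim[1],
            bottom = tile$origin[2] + h < tile$image_dim[2])
  # medians estimated on a pixel subsample (background statistics only)
  sub_med <- function(m) median(m[seq(1L, length(m), by = 7L)])
  ch_med <- if (length(dim(px)) == 3)
    vapply(1:3, function(k) sub_med(px[, , k]), numeric(1)) else rep(0, 3)

  # flat accumulators: one numeric row + label per detection
  acc_n <- 0L
  acc_rows <- vector("list", 512L)
  acc_lab <- character(512L)
  push_det <- function(vec, label) {
    acc_n <<- acc_n + 1L
    if (acc_n > length(acc_rows)) {
      length(acc_rows) <<- 2L * length(acc_rows)
      length(acc_lab) <<- 2L * length(acc_lab)
    }
    acc_rows[[acc_n]] <<- vec
    acc_lab[acc_n] <<- label
  }

  for (gname in names(config$projections)) {
    g <- config$projections[[gname]]
    P <- project_raster(px, g$weights)
    # blur with replicated borders: plain FFT convolution would wrap
    # bright cells at one tile border into ghost responses at the
    # opposite one, so pad, blur, and crop the pad away
    pad <- 8L
    nr <- nrow(P); nc <- ncol(P)
    Ppad <- P[c(rep(1L, pad), seq_len(nr), rep(nr, pad)),
              c(rep(1L, pad), seq_len(nc), rep(nc, pad))]
    Spad <- EBImage::gblur(Ppad, sigma = config$blur_sigma)
    S <- Spad[pad + seq_len(nr), pad + seq_len(nc)]
    med <- sub_med(S)
    mask <- S > med + config$threshold
    if (!any(mask)) next
    heights <- (S - med) * mask
    L <- EBImage::watershed(heights, tolerance = config$ws_tolerance,
                            ext = 1)
    L <- matrix(as.integer(L), nrow = h)
    nlab <- max(L)
    if (nlab == 0) next

    idx <- which(L > 0)
    lab <- L[idx]
    rows <- ((idx - 1) %% h) + 1
    cols <- ((idx - 1) %/% h) + 1
    v <- S[idx] - med
    ord <- order(lab)
    lab <- lab[ord]; rows <- rows[ord]; cols <- cols[ord]; v <- v[ord]
    bounds <- c(0, cumsum(tabulate(lab, nbins = nlab)))

    # prototype quantities for this projection, precomputed as vectors
    pr_tab <- config$prototypes
    pr_class <- pr_tab$class
    pr_d <- pr_tab$diameter_um
    pr_chroma <- cbind(pr_tab$chroma_r, pr_tab$chroma_g, pr_tab$chroma_b)
    pr_amp3 <- cbind(pr_tab$amp_r, pr_tab$amp_g, pr_tab$amp_b)
    amp0_all <- setNames(as.numeric(pr_amp3 %*% g$weights), pr_class)
    s_proto <- (pr_d / 2 / ps) / HALFMAX_K
    pp_all <- setNames(amp0_all * s_proto^2 /
                         (s_proto^2 + config$blur_sigma^2), pr_class)

    # first pass per region: peak, near-peak centroid and width statistic
    pk_all <- rep(NA_real_, nlab)
    tx_all <- rep(NA_real_, nlab)
    ty_all <- rep(NA_real_, nlab)
    s2_all <- rep(NA_real_, nlab)
    vis_all <- rep(NA_real_, nlab)
    for (l in seq_len(nlab)) {
      if (bounds[l + 1] - bounds[l] < 4) next
      sl <- (bounds[l] + 1):bounds[l + 1]
      vs <- pmax(v[sl], 0)
      pk <- max(vs)
      if (pk <= config$threshold) next
      top <- vs >= 0.7 * pk
      pk_all[l] <- pk
      tx_all[l] <- sum((cols[sl][top] - 0.5) * vs[top]) / sum(vs[top])
      ty_all[l] <- sum((rows[sl][top] - 0.5) * vs[top]) / sum(vs[top])
      s2_all[l] <- (sum(vs) / max(1 - config$threshold / pk, 0.2)) /
        (2 * pi * pk)
      vis_all[l] <- sum(vs)
    }
    # per-tile self-calibration of the single-cell scale: median of the
    # width statistic over regions (most regions hold one cell)
    s2_med <- if (any(is.finite(s2_all))) unname(quantile(s2_all, 0.35, na.rm = TRUE))
              else NULL
    # lower-quantile visible (above-threshold) flux of a region: tracks the
    # single-cell flux unit (the median is biased up by multi-cell regions)
    vis_med <- if (any(is.finite(vis_all))) unname(quantile(vis_all, 0.35, na.rm = TRUE))
               else NULL

    # neighbor-tail subtraction: before judging a region's shape, remove
    # the modeled Gaussian contribution of nearby regions so that crowding
    # does not masquerade as elongation
    clean_values <- function(l, rsel, csel, vsel) {
      if (!is.finite(pk_all[l])) return(vsel)
      nb <- which(is.finite(pk_all) &
                    abs(tx_all - tx_all[l]) < 30 &
                    abs(ty_all - ty_all[l]) < 30)
      nb <- nb[nb != l]
      if (!length(nb)) return(vsel)
      out <- vsel
      for (j in nb) {
        r2 <- ((csel - 0.5) - tx_all[j])^2 + ((rsel - 0.5) - ty_all[j])^2
        out <- out - pk_all[j] * exp(-r2 / (2 * s2_all[j]))
      }
      pmax(out, 0)
    }

    # recursive region analysis: emit one detection per resolved cell.
    # A region judged multi-cell (by elongation or by peak amplitude) is
    # cut in two perpendicular to its principal axis and each half is
    # re-analyzed, unravelling chains of touching cells; fully superposed
    # stacks (no spatial structure left) emit `m_peak` co-located
    # detections over a slab partition.
    # `axis`: once a region has been cut, pieces inherit the chain axis and
    # elongation is judged along it only -- the cut itself makes any piece
    # look elongated along the cut line, which must not trigger re-splits.
    analyze_region <- function(rsel, csel, vsel, depth, axis = NULL,
                               allow_split = TRUE) {
      wsum <- sum(vsel)
      peak <- max(vsel)
      if (length(vsel) < 4 || peak <= config$threshold || wsum <= 0)
        return(invisible(NULL))
      flux <- sum(vsel) / max(1 - config$threshold / peak, 0.2)
      cx <- sum((csel - 0.5) * vsel) / wsum
      cy <- sum((rsel - 0.5) * vsel) / wsum
      dxs <- (csel - 0.5) - cx
      dys <- (rsel - 0.5) - cy
      vxx <- sum(dxs^2 * vsel) / wsum
      vyy <- sum(dys^2 * vsel) / wsum
      vxy <- sum(dxs * dys * vsel) / wsum
      trm <- vxx + vyy
      disc <- sqrt(max((vxx - vyy)^2 / 4 + vxy^2, 0))
      if (is.null(axis)) {
        axis_ratio <- (trm / 2 + disc) / max(trm / 2 - disc, 1e-6)
        theta <- 0.5 * atan2(2 * vxy, vxx - vyy)
        u <- c(cos(theta), sin(theta))
      } else {
        u <- axis
        var_u <- vxx * u[1]^2 + 2 * vxy * u[1] * u[2] + vyy * u[2]^2
        var_p <- vxx * u[2]^2 - 2 * vxy * u[1] * u[2] + vyy * u[1]^2
        axis_ratio <- var_u / max(var_p, 1e-6)
      }

      chroma <- if (length(dim(px)) == 3) {
        # color from the near-peak core: in a merged pair the core is
        # dominated by one cell, so its hue is not a class mixture
        core <- which(vsel >= 0.6 * peak)
        rc <- rsel[core]; cc <- csel[core]; vc <- vsel[core]
        wc <- sum(vc)
        mr <- sum((px[cbind(rc, cc, rep(1L, length(rc)))] - ch_med[1]) * vc) / wc
        mg <- sum((px[cbind(rc, cc, rep(2L, length(rc)))] - ch_med[2]) * vc) / wc
        mb <- sum((px[cbind(rc, cc, rep(3L, length(rc)))] - ch_med[3]) * vc) / wc
        tot <- max(mr + mg + mb, 1e-9)
        c(mr, mg, mb) / tot
      } else rep(1 / 3, 3)

      s_obs2 <- flux / (2 * pi * peak)
      if (is.null(axis)) {
        d_est <- 2 * HALFMAX_K *
          sqrt(max(s_obs2 - config$blur_sigma^2, 0.25)) * ps
      } else {
        # pieces of a cut region lose along-axis flux, but the variance
        # perpendicular to the cut axis is unaffected by a half-plane cut;
        # correct it for the threshold truncation of the Gaussian profile
        tt <- max(log(peak / config$threshold), 0.1)
        truncfrac <- 1 - tt * exp(-tt) / (1 - exp(-tt))
        var_perp <- vxx * u[2]^2 - 2 * vxy * u[1] * u[2] + vyy * u[1]^2
        d_est <- 2 * HALFMAX_K *
          sqrt(max(var_perp / truncfrac - config$blur_sigma^2, 0.25)) * ps
      }
      dchr <- sqrt((chroma[1] - pr_chroma[, 1])^2 +
                     (chroma[2] - pr_chroma[, 2])^2 +
                     (chroma[3] - pr_chroma[, 3])^2)
      dist <- dchr / config$chroma_scale +
        abs(log(max(d_est, 0.3) / pr_d)) / config$size_scale
      sc <- exp(-(dist - min(dist)))
      probs <- setNames(sc / sum(sc), pr_class)
      label <- pr_class[which.max(probs)]

      m_peak <- 1L
      if (label %in% g$classes) {
        if (depth == 0L) {
          # peak multiplicity: a fully superposed stack of k cells sums to
          # about k times the single-cell peak
          m_peak <- as.integer(round(peak / pp_all[[label]]))
        } else if (!is.null(s2_med)) {
          # pieces produced by a cut carry their partner's tail in the
          # peak; flux is additive and tail-robust, so judge multiplicity
          # by flux units instead
          m_peak <- as.integer(round(flux / (2 * pi * s2_med *
                                               amp0_all[[label]])))
        }
      }
      # flux evidence: approximate number of single-cell flux units in the
      # region, judged against the per-tile self-calibrated cell scale
      q <- if (!is.null(s2_med)) (flux / (2 * pi * peak)) / s2_med
           else NA_real_
      # split on elongation: merged same-class pairs show axis ratios of
      # 1.4 and above, while single-cell basins (including halves cut at a
      # watershed saddle, whose truncation shape is the worst case) stay
      # at or below ~1.35
      split2 <- allow_split && depth < 4L && label %in% g$classes &&
        axis_ratio > config$elongation_ratio
      if (!split2 && allow_split && depth >= 1L && depth < 4L &&
          label %in% g$classes && is.finite(q) && q > 1.55) {
        # the piece still holds two cells' flux but its partner lies off
        # the inherited chain axis (bent cluster): cut along the piece's
        # own principal axis instead
        split2 <- TRUE
        theta <- 0.5 * atan2(2 * vxy, vxx - vyy)
        u <- c(cos(theta), sin(theta))
      }
      if (split2) {
        t_coord <- dxs * u[1] + dys * u[2]
        left <- t_coord <= stats::weighted.mean(t_coord, vsel)
        ok <- any(left) && any(!left)
        if (ok && !is.null(vis_med) && label %in% g$classes) {
          # fragment guard: a genuine cut leaves close to one cell's flux
          # on each side; cutting a lone cell leaves half-cell fragments
          ok <- sum(vsel[left]) / vis_med >= 0.6 &&
            sum(vsel[!left]) / vis_med >= 0.6
        }
        if (ok) {
          analyze_region(rsel[left], csel[left], vsel[left],
                         depth + 1L, axis = u)
          analyze_region(rsel[!left], csel[!left], vsel[!left],
                         depth + 1L, axis = u)
          return(invisible(NULL))
        }
      }

      mult <- if (allow_split)
        max(1L, min(m_peak, config$max_multiplicity)) else 1L
      if (mult >= 2L) {
        s1 <- max(flux / mult / (2 * pi * pp_all[[label]]) -
                    config$blur_sigma^2, 0.25)
        d_est <- 2 * HALFMAX_K * sqrt(s1) * ps
      }
      if (d_est < g$scale_um[1] || d_est > g$scale_um[2])
        return(invisible(NULL))
      r_px <- (d_est / 2) / ps
      conf <- unname(max(probs))

      emit <- function(ccx, ccy, bbox = NULL) {
        if (is.null(bbox))
          bbox <- c(ccx - r_px, ccx + r_px, ccy - r_px, ccy + r_px)
        push_det(c(bbox[1], bbox[3], bbox[2], bbox[4], ccx, ccy, conf,
                   d_est, probs), label)
      }

      # superposed cross-class pairs sum to a mixed hue that can mimic the
      # immature class; prefer a two-class explanation when it accounts
      # for both the color and the summed peak clearly better
      if (mult == 1L && label == "imm" && depth == 0L &&
          length(g$classes) > 2) {
        mature <- setdiff(g$classes, "imm")
        pp_imm <- proto_peak_amplitude(config, "imm", g$weights, ps)
        best <- list(score = Inf, a = NULL, b = NULL)
        pr <- config$prototypes
        for (ai in seq_along(mature)) for (bi in seq_len(ai)) {
          a <- mature[ai]; b <- mature[bi]
          ra <- pr[pr$class == a, ]; rb <- pr[pr$class == b, ]
          mix <- c(ra$amp_r + rb$amp_r, ra$amp_g + rb$amp_g,
                   ra$amp_b + rb$amp_b)
          mix_chroma <- mix / sum(mix)
          pp_ab <- proto_peak_amplitude(config, a, g$weights, ps) +
            proto_peak_amplitude(config, b, g$weights, ps)
          sc <- sqrt(sum((chroma - mix_chroma)^2)) / config$chroma_scale +
            abs(log(peak / pp_ab)) / 0.15
          if (sc < best$score) best <- list(score = sc, a = a, b = b)
        }
        sc_imm <- sqrt(sum((chroma - c(pr$chroma_r[pr$class == "imm"],
                                       pr$chroma_g[pr$class == "imm"],
                                       pr$chroma_b[pr$class == "imm"]))^2)) /
          config$chroma_scale + abs(log(peak / pp_imm)) / 0.15
        if (best$score + 0.15 < sc_imm) {
          # emit the two mature cells over a slab partition of the region
          t_coord <- dxs * u[1] + dys * u[2]
          halves <- t_coord <= median(t_coord)
          for (half in list(halves, !halves)) {
            if (!any(half)) next
            wts <- vsel[half]
            lab_h <- if (identical(half, halves)) best$a else best$b
            d_h <- pr$diameter_um[pr$class == lab_h]
            r_h <- (d_h / 2) / ps
            mx <- cx + sum(dxs[half] * wts) / sum(wts)
            my <- cy + sum(dys[half] * wts) / sum(wts)
            bb <- c(min(csel[half]) - 1, max(csel[half]),
                    min(rsel[half]) - 1, max(rsel[half]))
            pr_vec <- setNames(rep(0.01, nrow(pr)), pr$class)
            pr_vec[lab_h] <- 1 - 0.01 * (nrow(pr) - 1)
            push_det(c(bb[1], bb[3], bb[2], bb[4], mx, my,
                       unname(pr_vec[lab_h]), d_h, pr_vec), lab_h)
          }
          return(invisible(NULL))
        }
      }

      if (mult == 1L) {
        multi_flux <- !is.null(vis_med) && sum(vsel) / vis_med > 1.3
        if (multi_flux) {
          # unresolvable multi-cell region: represent it by its flux
          # centroid, which lies between the members
          emit(cx, cy)
        } else {
          # localize at the near-peak centroid: robust to neighbor tails
          # and to the flux asymmetry that region cuts introduce
          top <- vsel >= 0.7 * peak
          tx <- sum((csel[top] - 0.5) * vsel[top]) / sum(vsel[top])
          ty <- sum((rsel[top] - 0.5) * vsel[top]) / sum(vsel[top])
          emit(tx, ty)
        }
        return(invisible(NULL))
      }
      # superposed stack: slab partition along the (residual) spread
      t_coord <- dxs * u[1] + dys * u[2]
      qs <- unique(quantile(t_coord, probs = seq(0, 1,
                                                 length.out = mult + 1)))
      grp <- if (length(qs) > 2)
        cut(t_coord, breaks = qs, include.lowest = TRUE, labels = FALSE)
      else rep(seq_len(mult), length.out = length(vsel))
      for (m in sort(unique(grp))) {
        msel <- grp == m
        wts <- vsel[msel]
        mx <- cx + sum(dxs[msel] * wts) / sum(wts)
        my <- cy + sum(dys[msel] * wts) / sum(wts)
        bb <- c(min(csel[msel]) - 1, max(csel[msel]),
                min(rsel[msel]) - 1, max(rsel[msel]))
        emit(mx, my, bb)
      }
      invisible(NULL)
    }

    for (l in seq_len(nlab)) {
      sel <- if (bounds[l + 1] > bounds[l]) (bounds[l] + 1):bounds[l + 1]
             else integer(0)
      if (length(sel) < 4) next
      rsel <- rows[sel]; csel <- cols[sel]; vsel <- pmax(v[sel], 0)
      # seam guard
      if ((seam["left"] && min(csel) == 1) || (seam["right"] && max(csel) == w) ||
          (seam["top"] && min(rsel) == 1) || (seam["bottom"] && max(rsel) == h))
        next
      analyze_region(rsel, csel, clean_values(l, rsel, csel, vsel), 0L)
    }
  }
  if (acc_n == 0L) return(empty_detections(config))
  M <- do.call(rbind, acc_rows[seq_len(acc_n)])
  res <- data.frame(x0 = M[, 1], y0 = M[, 2], x1 = M[, 3], y1 = M[, 4],
                    cx = M[, 5], cy = M[, 6],
                    label = acc_lab[seq_len(acc_n)],
                    confidence = M[, 7], diameter_um = M[, 8],
                    source_tile = NA_integer_)
  for (k in seq_along(config$prototypes$class))
    res[[paste0("p_", config$prototypes$class[k])]] <- M[, 8 + k]
  res
}

empty_detections <- function(config) {
  df <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                   y1 = numeric(0), cx = numeric(0), cy = numeric(0),
                   label = character(0), confidence = numeric(0),
                   diameter_um = numeric(0), source_tile = integer(0))
  for (cl in config$prototypes$class) df[[paste0("p_", cl)]] <- numeric(0)
  df
}

# IoU of one box against a matrix of boxes (half-open, real-valued areas)
iou_one_many <- function(b, M) {
  ix <- pmax(0, pmin(b[3], M[, 3]) - pmax(b[1], M[, 1]))
  iy <- pmax(0, pmin(b[4], M[, 4]) - pmax(b[2], M[, 2]))
  inter <- ix * iy
  a1 <- (b[3] - b[1]) * (b[4] - b[2])
  a2 <- (M[, 3] - M[, 1]) * (M[, 4] - M[, 2])
  inter / (a1 + a2 - inter)
}

#' Deduplicate overlapping detections
#'
#' Two detections whose boxes overlap with IoU at or above the threshold
#' are considered the same cell. Groups are the connected components of the
#' IoU graph; within each group the highest-confidence member survives
#' (ties: larger box area, then smaller x0, then smaller y0). The
#' operation is idempotent and any surviving pair has IoU below the
#' threshold.
#'
#' @param detections Detection data.frame in global coordinates.
#' @param overlap_threshold IoU threshold in (0, 1).
#' @return Filtered detection data.frame.
#' @export
merge_detections <- function(detections, overlap_threshold = 0.5) {
  if (!(overlap_threshold > 0 && overlap_threshold < 1))
    stop("overlap_threshold must be in (0,1)")
  n <- nrow(detections)
  if (n <= 1) return(detections)
  B <- as.matrix(detections[, c("x0", "y0", "x1", "y1")])
  ord <- order(B[, 1])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  xs0 <- B[ord, 1]; xs1 <- B[ord, 3]
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    # candidates: boxes starting before this box ends
    b <- a + 1
    cand <- integer(0)
    while (b <= n && xs0[b] < xs1[a]) { cand <- c(cand, ord[b]); b <- b + 1 }
    if (!length(cand)) next
    ious <- iou_one_many(B[i, ], B[cand, , drop = FALSE])
    for (j in cand[ious >= overlap_threshold]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), comp), function(members) {
    d <- detections[members, ]
    area <- (d$x1 - d$x0) * (d$y1 - d$y0)
    o <- order(-d$confidence, -area, d$x0, d$y0)
    members[o[1]]
  }, integer(1))
  out <- detections[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Detect and classify all cells in a chamber image
#'
#' Full pipeline: [tile_image()], [detect_in_tile()] on each tile, shift to
#' global coordinates, then [merge_detections()].
#'
#' @param image A `chamber_image` (or raster array).
#' @param spec A [tile_spec()].
#' @param config A [detector_config()]; defaults to the chamber's standard
#'   configuration.
#' @param overlap_threshold IoU threshold for deduplication.
#' @param geometry Geometry override when `image` is a raw array.
#' @return Detection data.frame in global 0-based pixel coordinates.
#' @export
#' @examples
#' p <- gt_panel(rbc = 4.5, hb = 14, plt = 250, wbc = 7)
#' g <- chamber_geometry(2, counting_area = 0.02)
#' img <- render_chamber(p, 2, g, seed = 11)
#' det <- detect_cells(img)
#' table(det$label)
detect_cells <- function(image, spec = tile_spec(), config = NULL,
                         overlap_threshold = 0.5, geometry = NULL) {
  if (inherits(image, "chamber_image")) {
    geometry <- image$geometry
  } else if (is.null(geometry)) {
    stop("geometry must be supplied for raw rasters")
  }
  if (is.null(config)) config <- detector_config(geometry$chamber_id)
  px_dim <- if (inherits(image, "chamber_image")) dim(image$pixels)
            else dim(image)
  if (px_dim[1] <= spec$tile_size && px_dim[2] <= spec$tile_size)
    spec <- structure(list(tile_size = as.integer(max(px_dim[1:2])),
                           overlap_margin = spec$overlap_margin),
                      class = "tile_spec")
  tiles <- tile_image(image, spec)
  parts <- vector("list", length(tiles))
  for (k in seq_along(tiles)) {
    d <- detect_in_tile(tiles[[k]], config, geometry)
    if (nrow(d)) {
      d$x0 <- d$x0 + tiles[[k]]$origin[1]; d$x1 <- d$x1 + tiles[[k]]$origin[1]
      d$cx <- d$cx + tiles[[k]]$origin[1]
      d$y0 <- d$y0 + tiles[[k]]$origin[2]; d$y1 <- d$y1 + tiles[[k]]$origin[2]
      d$cy <- d$cy + tiles[[k]]$origin[2]
      d$source_tile <- k
    }
    parts[[k]] <- d
  }
  merged <- merge_detections(do.call(rbind, parts), overlap_threshold)
  rownames(merged) <- NULL
  merged
}

#' Score detections against generator ground truth
#'
#' A truth object is recalled when some detection center lies within half
#' the object's true diameter of its center; a detection is a true positive
#' when its center lies within half the true diameter of some truth object.
#'
#' @param detections Detection data.frame (global coords).
#' @param truth `truth_objects` data.frame from [render_chamber()].
#' @param pixel_scale um per pixel of the image.
#' @param by_class Restrict both sides to one class label (optional).
#' @return List: recall, precision, n_truth, n_detections.
#' @export
match_detections <- function(detections, truth, pixel_scale,
                             by_class = NULL) {
  if (!is.null(by_class)) {
    detections <- detections[detections$label == by_class, ]
    truth <- truth[truth$class == by_class, ]
  }
  nt <- nrow(truth); nd <- nrow(detections)
  if (nt == 0 || nd == 0)
    return(list(recall = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0,
                n_truth = nt, n_detections = nd))
  r_px <- (truth$diameter_um / 2) / pixel_scale
  d2 <- outer(truth$x, detections$cx, "-")^2 +
    outer(truth$y, detections$cy, "-")^2
  hit <- d2 <= r_px^2  # nt x nd
  list(recall = mean(apply(hit, 1, any)),
       precision = mean(apply(hit, 2, any)),
       n_truth = nt, n_detections = nd)
}
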