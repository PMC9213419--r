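#' A complete blood count result
#'
#' Units: rbc 10^6/mm^3; hb g/dL; ht %; mcv fL; mch pg; plt, wbc and the
#' four leukocyte subpopulations 10^3/mm^3. WBC is the sum of the four
#' mature subpopulations (immature cells are surfaced via flagging only),
#' which the constructor enforces.
#'
#' @param rbc,hb,ht,mcv,mch,plt Analyte values (NA allowed for a partial
#'   panel).
#' @param neu,lym,mon,eosbas Mature leukocyte subpopulation concentrations.
#' @param sex "F" or "M".
#' @return Object of class `analyte_panel`.
#' @export
analyte_panel <- function(rbc = NA_real_, hb = NA_real_, ht = NA_real_,
                          mcv = NA_real_, mch = NA_real_, plt = NA_real_,
                          neu = NA_real_, lym = NA_real_, mon = NA_real_,
                          eosbas = NA_real_, sex = "F") {
  sub <- c(neu = neu, lym = lym, mon = mon, eosbas = eosbas)
  wbc <- if (all(is.finite(sub))) sum(sub) else NA_real_
  vals <- c(rbc = rbc, hb = hb, ht = ht, mcv = mcv, mch = mch, plt = plt,
            wbc = wbc, sub)
  if (any(vals < 0, na.rm = TRUE)) stop("analyte values must be >= 0")
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  structure(c(as.list(vals), list(sex = sex)), class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("<analyte_panel> (%s)\n", x$sex))
  cat(sprintf("  RBC %.2f  HB %.1f  HT %.1f  MCV %.1f  MCH %.1f  PLT %.0f\n",
              x$rbc, x$hb, x$ht, x$mcv, x$mch, x$plt))
  cat(sprintf("  WBC %.2f (NEU %.2f LYM %.2f MON %.2f EOS/BAS %.2f)\n",
              x$wbc, x$neu, x$lym, x$mon, x$eosbas))
  invisible(x)
}

#' @export
as.data.frame.analyte_panel <- function(x, ...) {
  data.frame(analyte = c("rbc", "hb", "ht", "mcv", "mch", "plt", "wbc",
                         "neu", "lym", "mon", "eosbas"),
             value = c(x$rbc, x$hb, x$ht, x$mcv, x$mch, x$plt, x$wbc,
                       x$neu, x$lym, x$mon, x$eosbas),
             unit = analyte_units(), sex = x$sex)
}

analyte_units <- function() {
  c(rbc = "1e6/mm3", hb = "g/dL", ht = "%", mcv = "fL", mch = "pg",
    plt = "1e3/mm3", wbc = "1e3/mm3", neu = "1e3/mm3", lym = "1e3/mm3",
    mon = "1e3/mm3", eosbas = "1e3/mm3")
}

#' Convert a cell count to a whole-blood concentration
#'
#' `concentration = n_cells * dilution_fold / (counting_area * depth)`,
#' in cells per mm^3 of whole blood.
#'
#' @param n_cells Nonnegative integer count.
#' @param dilution_fold Blood dilution of the counted chamber.
#' @param geometry A [chamber_geometry()].
#' @return Concentration per mm^3 (caller rescales to reporting units).
#' @export
#' @examples
#' count_to_concentration(2514, 179, chamber_geometry(2))  # ~4.5e6/mm3
count_to_concentration <- function(n_cells, dilution_fold, geometry) {
  if (n_cells < 0 || n_cells != round(n_cells))
    stop("n_cells must be a nonnegative integer")
  vol <- chamber_volume(geometry)
  if (vol <= 0) stop("counted volume must be > 0")
  n_cells * dilution_fold / vol
}

#' Four-part leukocyte differential from chamber-1 detections
#'
#' Counts detections by their argmax class label. Fractions are computed
#' over the four mature classes only; immature detections are counted
#' separately and excluded from the denominator (they surface through
#' flagging, not the differential).
#'
#' @param detections Detection data.frame with a `label` column.
#' @return List: counts (named, incl. imm), fractions (neu, lym, mon,
#'   eosbas; NA when no mature cells), n_mature, n_immature.
#' @export
differential_counts <- function(detections) {
  mature <- c("neu", "lym", "mon", "eosbas")
  lab <- if (is.null(detections) || nrow(detections) == 0) character(0)
         else detections$label
  counts <- setNames(vapply(c(mature, "imm"),
                            function(cl) sum(lab == cl), numeric(1)),
                     c(mature, "imm"))
  n_mat <- sum(counts[mature])
  fractions <- if (n_mat > 0) counts[mature] / n_mat else
    setNames(rep(NA_real_, 4), mature)
  list(counts = counts, fractions = fractions,
       n_mature = n_mat, n_immature = counts[["imm"]])
}

#' Mean colorimetric value of a strip reading window
#'
#' Mean of the green channel (the reacted-dye channel) over the ROI.
#'
#' @param strip_image A [render_strip()] result, or a list with `pixels`
#'   and `roi`.
#' @return Scalar mean value.
#' @export
read_colorimetric_value <- function(strip_image) {
  px <- strip_image$pixels
  roi <- strip_image$roi
  h <- dim(px)[1]; w <- dim(px)[2]
  if (roi[["x0"]] < 0 || roi[["y0"]] < 0 || roi[["x1"]] > w ||
      roi[["y1"]] > h || roi[["x1"]] <= roi[["x0"]] ||
      roi[["y1"]] <= roi[["y0"]])
    stop("roi outside raster bounds")
  mean(px[(roi[["y0"]] + 1):roi[["y1"]], (roi[["x0"]] + 1):roi[["x1"]], 2])
}

#' Fit the hemoglobin calibration curve
#'
#' Least-squares fit of the saturating-exponential form `value = a + b *
#' exp(-hb / h0)` (Beer-Lambert-like strip response) to calibration
#' standards; falls back to a straight line only if the exponential fit
#' fails to converge. The fitted map must be strictly monotone over the
#' standard span; non-monotone standards are refused.
#'
#' @param standards data.frame with columns `hb` (g/dL) and `value`; at
#'   least 4 standards with distinct hb values.
#' @return Object of class `calibration_model`: form, coefficients, valid
#'   hb range, residual SD.
#' @export
#' @examples
#' st <- data.frame(hb = 4:19, value = hb_forward_color(4:19))
#' m <- fit_hb_calibration(st)
#' hb_from_color(hb_forward_color(10), m)
fit_hb_calibration <- function(standards) {
  stopifnot(is.data.frame(standards), all(c("hb", "value") %in% names(standards)))
  if (nrow(standards) < 4) stop("need at least 4 calibration standards")
  if (anyDuplicated(standards$hb)) stop("duplicated hb values in standards")
  st <- standards[order(standards$hb), ]
  dv <- diff(st$value)
  if (!(all(dv < 0) || all(dv > 0)))
    stop("standards are not monotone in hb; refusing to fit")
  # profiled least squares: for a fixed decay scale h the model
  # a + b * exp(-hb/h) is linear in (a, b), so minimize the profiled RSS
  # over h directly -- robust on noiseless standards where iterative
  # exponential fitters can stall
  rss_at <- function(h) {
    z <- exp(-st$hb / h)
    f <- stats::lm.fit(cbind(1, z), st$value)
    sum(f$residuals^2)
  }
  span <- diff(range(st$hb))
  opt <- optimize(rss_at, interval = c(span / 50, span * 10))
  h0 <- opt$minimum
  z <- exp(-st$hb / h0)
  lf <- stats::lm.fit(cbind(1, z), st$value)
  lin <- stats::lm.fit(cbind(1, st$hb), st$value)
  if (sum(lf$residuals^2) <= sum(lin$residuals^2)) {
    coefs <- c(a = unname(lf$coefficients[1]),
               b = unname(lf$coefficients[2]), h0 = h0)
    form <- "satexp"
    resid_sd <- sqrt(mean(lf$residuals^2))
  } else {
    coefs <- c(a = unname(lin$coefficients[1]),
               b = unname(lin$coefficients[2]), h0 = NA_real_)
    form <- "linear"
    resid_sd <- sqrt(mean(lin$residuals^2))
  }
  model <- structure(list(form = form, coefficients = coefs,
                          hb_range = range(st$hb), residual_sd = resid_sd),
                     class = "calibration_model")
  # monotonicity of the fitted map on the span
  grid <- seq(model$hb_range[1], model$hb_range[2], length.out = 200)
  pred <- predict_color(model, grid)
  dg <- diff(pred)
  if (!(all(dg < 0) || all(dg > 0)))
    stop("fitted calibration is not strictly monotone on the standard span")
  model
}

predict_color <- function(model, hb) {
  cf <- model$coefficients
  if (model$form == "satexp") cf[["a"]] + cf[["b"]] * exp(-hb / cf[["h0"]])
  else cf[["a"]] + cf[["b"]] * hb
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> form = %s, hb range %.1f-%.1f g/dL, residual SD %.2g\n",
              x$form, x$hb_range[1], x$hb_range[2], x$residual_sd))
  invisible(x)
}

#' Invert a colorimetric value to HB concentration
#'
#' Values mapping outside the calibrated HB span are clamped to the span
#' boundary and marked in the `clamped` attribute.
#'
#' @param value Colorimetric value(s).
#' @param model A [fit_hb_calibration()] model.
#' @return HB in g/dL with logical attribute `clamped`.
#' @export
hb_from_color <- function(value, model) {
  stopifnot(inherits(model, "calibration_model"))
  cf <- model$coefficients
  if (model$form == "satexp") {
    ratio <- (value - cf[["a"]]) / cf[["b"]]
    hb <- ifelse(ratio > 0, -cf[["h0"]] * log(ratio), Inf)
  } else {
    hb <- (value - cf[["a"]]) / cf[["b"]]
  }
  clamped <- hb < model$hb_range[1] | hb > model$hb_range[2] | !is.finite(hb)
  hb <- pmin(pmax(hb, model$hb_range[1]), model$hb_range[2])
  attr(hb, "clamped") <- clamped
  hb
}

#' Default hemoglobin calibration fitted on noiseless standards
#'
#' @param config A [strip_config()].
#' @param hb_grid Standards span (g/dL).
#' @return A `calibration_model`.
#' @export
default_hb_calibration <- function(config = strip_config(),
                                   hb_grid = seq(4, 19, by = 1)) {
  fit_hb_calibration(data.frame(hb = hb_grid,
                                value = hb_forward_color(hb_grid, config)))
}

#' Estimate hematocrit, MCV and MCH from HB and RBC
#'
#' The device does not measure packed cell volume; HT, MCV and MCH are
#' estimated. The default strategy is the classical rule of three plus the
#' standard index definitions: `ht = 3 * hb`, `mcv = 10 * ht / rbc`,
#' `mch = 10 * hb / rbc` (rbc in 10^6/mm^3). The estimator is pluggable via
#' `strategy`.
#'
#' @param hb HB g/dL, > 0.
#' @param rbc RBC 10^6/mm^3, > 0.
#' @param strategy Either "rule_of_three" or a function(hb, rbc) returning
#'   a named vector c(ht, mcv, mch).
#' @return Named vector: ht (%), mcv (fL), mch (pg).
#' @export
#' @examples
#' estimate_indices(15, 5)  # ht 45, mcv 90, mch 30
estimate_indices <- function(hb, rbc, strategy = "rule_of_three") {
  if (!is.numeric(hb) || !is.numeric(rbc) || hb <= 0 || rbc <= 0)
    stop("hb and rbc must be > 0")
  if (is.function(strategy)) return(strategy(hb, rbc))
  ht <- 3 * hb
  c(ht = ht, mcv = 10 * ht / rbc, mch = 10 * hb / rbc)
}

#' Assemble a full CBC from pipeline components
#'
#' Combines chamber-1 and chamber-2 detections, the strip colorimetric
#' value and the calibration into an [analyte_panel()]: class counts are
#' converted through dilution and counted volume; leukocyte subpopulation
#' concentrations are the mature WBC total split by the differential
#' fractions; HB comes from the calibration inverse and HT/MCV/MCH from
#' [estimate_indices()]. A missing chamber or strip yields a partial panel
#' with NA entries rather than an error.
#'
#' @param chamber1_detections,chamber2_detections Detection data.frames
#'   (or NULL).
#' @param strip_value Mean colorimetric value (or NA).
#' @param model Calibration model (required when strip_value given).
#' @param scheme A [dilution_scheme()].
#' @param geometry A [chamber_geometry()] giving the counted area and
#'   depth of the RBC/PLT chamber.
#' @param geometry1 Geometry of the WBC chamber when it differs from
#'   `geometry` (the counted volume is what matters).
#' @param sex "F" or "M".
#' @return An [analyte_panel()] with attribute `immature_count`.
#' @export
assemble_cbc <- function(chamber1_detections, chamber2_detections,
                         strip_value = NA_real_, model = NULL,
                         scheme = dilution_scheme(),
                         geometry = chamber_geometry(2),
                         geometry1 = geometry, sex = "F") {
  rbc <- plt <- NA_real_
  if (!is.null(chamber2_detections)) {
    lab2 <- chamber2_detections$label
    rbc <- count_to_concentration(sum(lab2 == "rbc"),
                                  scheme$rbc_plt_dilution, geometry) / 1e6
    plt <- count_to_concentration(sum(lab2 == "plt"),
                                  scheme$rbc_plt_dilution, geometry) / 1e3
  }

  neu <- lym <- mon <- eosbas <- NA_real_
  imm_count <- NA_integer_
  if (!is.null(chamber1_detections)) {
    diff <- differential_counts(chamber1_detections)
    wbc_conc <- count_to_concentration(diff$n_mature, scheme$wbc_dilution,
                                       geometry1) / 1e3
    if (diff$n_mature > 0) {
      sub <- wbc_conc * diff$fractions
      neu <- sub[["neu"]]; lym <- sub[["lym"]]
      mon <- sub[["mon"]]; eosbas <- sub[["eosbas"]]
    } else {
      neu <- lym <- mon <- eosbas <- 0
    }
    imm_count <- as.integer(diff$n_immature)
  }

  hb <- ht <- mcv <- mch <- NA_real_
  if (is.finite(strip_value)) {
    if (is.null(model)) stop("a calibration model is required to read HB")
    hb <- as.numeric(hb_from_color(strip_value, model))
    if (is.finite(rbc) && rbc > 0) {
      idx <- estimate_indices(hb, rbc)
      ht <- idx[["ht"]]; mcv <- idx[["mcv"]]; mch <- idx[["mch"]]
    } else {
      ht <- 3 * hb
    }
  }

  out <- analyte_panel(rbc = rbc, hb = hb, ht = ht, mcv = mcv, mch = mch,
                       plt = plt, neu = neu, lym = lym, mon = mon,
                       eosbas = eosbas, sex = sex)
  attr(out, "immature_count") <- imm_count
  out
}
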