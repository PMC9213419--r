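#' Analyze one simulated sample end to end
#'
#' Runs the detector on both chamber images, reads the strip, assembles
#' the CBC panel and raises the flags.
#'
#' @param chamber1_image,chamber2_image `chamber_image` objects (either
#'   may be NULL for a partial sample).
#' @param strip_image A `strip_image` (or NULL).
#' @param calibration A [fit_hb_calibration()] model; defaults to the
#'   standard curve fitted on noiseless standards.
#' @param scheme A [dilution_scheme()].
#' @param sex "F" or "M".
#' @param thresholds Flagging thresholds.
#' @return List: panel ([analyte_panel()]), flags (named logicals),
#'   detections (list with chamber1, chamber2).
#' @export
analyze_sample <- function(chamber1_image = NULL, chamber2_image = NULL,
                           strip_image = NULL,
                           calibration = default_hb_calibration(),
                           scheme = dilution_scheme(), sex = "F",
                           thresholds = flag_thresholds()) {
  det1 <- if (!is.null(chamber1_image)) detect_cells(chamber1_image)
  det2 <- if (!is.null(chamber2_image)) detect_cells(chamber2_image)
  strip_value <- if (!is.null(strip_image))
    read_colorimetric_value(strip_image) else NA_real_
  geometry <- if (!is.null(chamber2_image)) chamber2_image$geometry
              else if (!is.null(chamber1_image)) chamber1_image$geometry
              else chamber_geometry(2)
  geometry1 <- if (!is.null(chamber1_image)) chamber1_image$geometry
               else geometry
  panel <- assemble_cbc(det1, det2, strip_value, calibration,
                        scheme, geometry, geometry1, sex)
  flags <- sample_flags(det1, det2,
                        geometry = if (!is.null(chamber2_image))
                          chamber2_image$geometry else geometry,
                        thresholds = thresholds)
  list(panel = panel, flags = flags,
       detections = list(chamber1 = det1, chamber2 = det2))
}

#' Simulate a paired clinical validation dataset
#'
#' For each virtual patient: sample a ground-truth panel from the cohort
#' mixture, render both chamber images and the strip, run the full
#' image-analysis pipeline (the point-of-care result), and run the
#' simulated comparator analyzer (the reference result). Deterministic
#' given the seed.
#'
#' @param n Number of samples, >= 2.
#' @param mixture_config Condition mixture, see [cohort_mixture()].
#' @param error_model Comparator error model.
#' @param seed Root seed.
#' @param geometry1,geometry2 Chamber geometries (the defaults are the
#'   full 1 mm^2 chambers; smaller areas trade precision for speed).
#' @param strip_cfg Strip configuration.
#' @param calibration HB calibration model.
#' @return List of class `validation_dataset`: `measurements` (long
#'   data.frame: sample_id, analyte, truth, poct, reference, condition,
#'   sex, flags), `flags` (per-sample truth and predicted flags).
#' @export
make_validation_dataset <- function(n, mixture_config = cohort_mixture(),
                                    error_model = comparator_error_model(),
                                    seed = 1L,
                                    geometry1 = chamber_geometry(1),
                                    geometry2 = chamber_geometry(2),
                                    strip_cfg = strip_config(),
                                    calibration = default_hb_calibration(strip_cfg)) {
  if (n < 2) stop("n must be >= 2")
  meas <- vector("list", n)
  flag_rows <- vector("list", n)
  analytes <- c("rbc", "hb", "ht", "mcv", "mch", "plt", "wbc",
                "neu", "lym", "mon", "eosbas")
  for (i in seq_len(n)) {
    s <- split_seed(seed, i)
    gt <- sample_patient(mixture_config, seed = s)
    img1 <- render_chamber(gt, 1, geometry1, seed = split_seed(s, 1))
    img2 <- render_chamber(gt, 2, geometry2, seed = split_seed(s, 2))
    strip <- render_strip(gt$hb, strip_cfg, seed = split_seed(s, 3))
    res <- analyze_sample(img1, img2, strip, calibration, sex = gt$sex)
    ref <- simulate_reference_analyzer(gt, error_model,
                                       seed = split_seed(s, 4))
    truth <- panel_to_analytes(gt)
    flag_str <- paste(names(gt$flags_truth)[gt$flags_truth],
                      collapse = ";")
    meas[[i]] <- data.frame(
      sample_id = i, analyte = analytes,
      truth = vapply(analytes, function(a) truth[[a]], numeric(1)),
      poct = vapply(analytes, function(a) res$panel[[a]], numeric(1)),
      reference = vapply(analytes, function(a) ref[[a]], numeric(1)),
      condition = gt$condition_label, sex = gt$sex, flags = flag_str)
    flag_rows[[i]] <- data.frame(
      sample_id = i, flag = names(gt$flags_truth),
      truth = unname(gt$flags_truth),
      predicted = unname(res$flags[names(gt$flags_truth)]))
  }
  structure(list(measurements = do.call(rbind, meas),
                 flags = do.call(rbind, flag_rows)),
            class = "validation_dataset")
}
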