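#' Default target concentrations for the simulated precision study
#'
#' Four concentrations per analyte, spanning the clinical decision region
#' of each. At the kit's counted volume (0.1 uL) counting statistics set a
#' hard floor of 1/sqrt(N) on achievable CV, so the defaults sit where
#' expected per-field counts support the EFLM goals (about 100 objects or
#' more per field for PLT and WBC); concentrations far below the reference
#' interval cannot meet the goals with a 0.1 uL field, whatever the
#' detector does.
#'
#' @return Named list of numeric target vectors (units: rbc 10^6/mm^3;
#'   wbc, plt 10^3/mm^3; hb g/dL).
#' @export
default_precision_ranges <- function() {
  list(rbc = c(3.5, 4.25, 5.0, 5.75),
       wbc = c(5, 7, 9, 11),
       plt = c(200, 275, 350, 425),
       hb = c(8, 11, 14, 17))
}

# render + measure one analyte once, at a given target concentration
measure_once <- function(analyte, target, seed, geometry1, geometry2,
                         strip_cfg, calibration, scheme) {
  if (analyte == "hb") {
    strip <- render_strip(target, strip_cfg, seed = seed)
    return(as.numeric(hb_from_color(read_colorimetric_value(strip),
                                    calibration)))
  }
  base <- list(rbc = 4.5, hb = 14, plt = 250, wbc = 7)
  base[[analyte]] <- target
  panel <- gt_panel(rbc = base$rbc, hb = base$hb, plt = base$plt,
                    wbc = base$wbc)
  if (analyte == "wbc") {
    img <- render_chamber(panel, 1, geometry1, seed = seed,
                          scheme = scheme)
    det <- detect_cells(img)
    n <- sum(det$label %in% c("neu", "lym", "mon", "eosbas"))
    count_to_concentration(n, scheme$wbc_dilution, geometry1) / 1e3
  } else {
    img <- render_chamber(panel, 2, geometry2, seed = seed,
                          scheme = scheme)
    det <- detect_cells(img)
    n <- sum(det$label == analyte)
    conc <- count_to_concentration(n, scheme$rbc_plt_dilution, geometry2)
    if (analyte == "rbc") conc / 1e6 else conc / 1e3
  }
}

# measure all four analytes of one composite sample (one render per
# chamber plus a strip), as a real precision-study sample would be run
measure_level <- function(level, seed, geometry1, geometry2, strip_cfg,
                          calibration, scheme) {
  panel <- gt_panel(rbc = level$rbc, hb = level$hb, plt = level$plt,
                    wbc = level$wbc)
  det2 <- detect_cells(render_chamber(panel, 2, geometry2,
                                      seed = split_seed(seed, 1),
                                      scheme = scheme))
  det1 <- detect_cells(render_chamber(panel, 1, geometry1,
                                      seed = split_seed(seed, 2),
                                      scheme = scheme))
  strip <- render_strip(level$hb, strip_cfg, seed = split_seed(seed, 3))
  c(rbc = count_to_concentration(sum(det2$label == "rbc"),
                                 scheme$rbc_plt_dilution, geometry2) / 1e6,
    plt = count_to_concentration(sum(det2$label == "plt"),
                                 scheme$rbc_plt_dilution, geometry2) / 1e3,
    wbc = count_to_concentration(
      sum(det1$label %in% c("neu", "lym", "mon", "eosbas")),
      scheme$wbc_dilution, geometry1) / 1e3,
    hb = as.numeric(hb_from_color(read_colorimetric_value(strip),
                                  calibration)))
}

#' Simulated repeatability / reproducibility study
#'
#' Measures each analyte at each target concentration `replicates` times
#' through the full generator + detection pipeline (strip pipeline for
#' HB), optionally across several simulated devices. Each device carries a
#' small fixed multiplicative bias per analyte (SD `device_bias_sd`),
#' emulating unit-to-unit calibration spread; replicates within a device
#' share that bias.
#'
#' @param ranges Named list of target vectors, see
#'   [default_precision_ranges()].
#' @param replicates Consecutive measurements per range and device.
#' @param devices Number of simulated devices.
#' @param seed Root seed.
#' @param device_bias_sd SD of the per-device multiplicative bias.
#' @param geometry1,geometry2 Chamber geometries.
#' @param strip_cfg,calibration,scheme Pipeline components.
#' @param goals EFLM goals for the summary.
#' @return List of class `precision_study`: `replicates` (long table:
#'   analyte, range, device, replicate, value) and `report`
#'   ([precision_summary()] output).
#' @export
simulate_precision_study <- function(ranges = default_precision_ranges(),
                                     replicates = 10, devices = 1,
                                     seed = 1L, device_bias_sd = 0.005,
                                     geometry1 = chamber_geometry(1),
                                     geometry2 = chamber_geometry(2),
                                     strip_cfg = strip_config(),
                                     calibration = default_hb_calibration(strip_cfg),
                                     scheme = dilution_scheme(),
                                     goals = eflm_goals()) {
  if (replicates < 2) stop("need at least 2 replicates per range")
  rows <- list()
  k <- 0L
  dev_bias <- with_seed(split_seed(seed, 777L),
                        matrix(rnorm(devices * length(ranges), 1,
                                     device_bias_sd),
                               nrow = devices,
                               dimnames = list(NULL, names(ranges))))
  joint <- all(c("rbc", "wbc", "plt", "hb") %in% names(ranges)) &&
    length(unique(lengths(ranges))) == 1
  if (joint) {
    # composite samples: each level sets all four targets at once, so one
    # chamber render serves every analyte it carries - as a physical
    # precision-study sample would
    n_lev <- length(ranges$rbc)
    for (lev in seq_len(n_lev)) {
      level <- lapply(ranges, `[`, lev)
      for (dev in seq_len(devices)) {
        for (rep in seq_len(replicates)) {
          k <- k + 1L
          vals <- measure_level(level, split_seed(seed, k), geometry1,
                                geometry2, strip_cfg, calibration,
                                scheme)
          for (analyte in names(ranges)) {
            rows[[length(rows) + 1]] <- data.frame(
              analyte = analyte, range = format(level[[analyte]]),
              device = dev, replicate = rep,
              value = vals[[analyte]] * dev_bias[dev, analyte])
          }
        }
      }
    }
  } else {
    for (analyte in names(ranges)) {
      for (target in ranges[[analyte]]) {
        for (dev in seq_len(devices)) {
          for (rep in seq_len(replicates)) {
            k <- k + 1L
            val <- measure_once(analyte, target, split_seed(seed, k),
                                geometry1, geometry2, strip_cfg,
                                calibration, scheme)
            rows[[length(rows) + 1]] <- data.frame(
              analyte = analyte, range = format(target),
              device = dev, replicate = rep,
              value = val * dev_bias[dev, analyte])
          }
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(replicates = tab,
                 report = precision_summary(tab[, c("analyte", "range",
                                                    "value")], goals)),
            class = "precision_study")
}
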