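#' Counting-chamber geometry
#'
#' Describes the hemocytometer field that is imaged and counted. The default
#' evaluation area is 1 mm^2 with the conventional improved-Neubauer chamber
#' depth of 0.1 mm, so the counted volume is 0.1 mm^3 (0.1 uL) of diluted
#' sample. Chamber 1 holds the leukocyte dilution (red cells lysed); chamber
#' 2 holds the erythrocyte/platelet dilution. The default pixel scale is
#' finer for chamber 2 because platelets (~2.5 um) need sub-cellular
#' sampling, while leukocytes (9-16 um) are comfortably resolved at 1 um/px.
#'
#' @param chamber_id 1 (WBC chamber) or 2 (RBC/PLT chamber).
#' @param counting_area Evaluated area in mm^2.
#' @param depth Chamber depth in mm.
#' @param pixel_scale Image sampling in um per pixel.
#' @return An object of class `chamber_geometry`.
#' @export
#' @examples
#' g <- chamber_geometry(2)
#' chamber_volume(g)  # 0.1 mm^3
chamber_geometry <- function(chamber_id,
                             counting_area = 1,
                             depth = 0.1,
                             pixel_scale = if (chamber_id == 1) 1.0 else 0.5) {
  stopifnot(chamber_id %in% c(1L, 2L))
  if (!is.numeric(counting_area) || counting_area <= 0)
    stop("counting_area must be > 0")
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop("pixel_scale must be > 0")
  structure(list(chamber_id = as.integer(chamber_id),
                 counting_area = counting_area,
                 depth = depth,
                 pixel_scale = pixel_scale),
            class = "chamber_geometry")
}

#' @rdname chamber_geometry
#' @param geometry A `chamber_geometry`.
#' @export
chamber_volume <- function(geometry) {
  geometry$counting_area * geometry$depth
}

# Side length of the (square) rendered field, in pixels.
field_side_px <- function(geometry) {
  side_um <- sqrt(geometry$counting_area) * 1000
  max(8L, as.integer(round(side_um / geometry$pixel_scale)))
}

#' Blood dilution scheme of the counting kit
#'
#' The single-use kit dilutes whole blood 179-fold for the erythrocyte /
#' platelet chamber and 9-fold for the leukocyte chamber.
#'
#' @param rbc_plt_dilution Fold dilution for chamber 2.
#' @param wbc_dilution Fold dilution for chamber 1.
#' @return An object of class `dilution_scheme`.
#' @export
dilution_scheme <- function(rbc_plt_dilution = 179, wbc_dilution = 9) {
  if (rbc_plt_dilution <= 1 || wbc_dilution <= 1)
    stop("dilution folds must be > 1")
  structure(list(rbc_plt_dilution = rbc_plt_dilution,
                 wbc_dilution = wbc_dilution),
            class = "dilution_scheme")
}

dilution_for_chamber <- function(scheme, chamber_id) {
  if (chamber_id == 1L) scheme$wbc_dilution else scheme$rbc_plt_dilution
}

#' Sex-specific reference intervals for CBC analytes
#'
#' Normal clinical ranges used for in/out-of-range concordance and for
#' centering the virtual-patient generator. Units: RBC 10^6/mm^3; HB g/dL;
#' HT %; MCV fL; MCH pg; PLT, WBC and the differential in 10^3/mm^3.
#'
#' @return A data.frame with columns analyte, sex, low, high.
#' @export
#' @examples
#' subset(reference_ranges(), analyte == "hb")
reference_ranges <- function() {
  rr <- rbind(
    data.frame(analyte = "rbc",    sex = c("F", "M"), low = c(3.9, 4.4),     high = c(5.1, 5.8)),
    data.frame(analyte = "hb",     sex = c("F", "M"), low = c(11.3, 12.3),   high = c(15.1, 16.9)),
    data.frame(analyte = "ht",     sex = c("F", "M"), low = c(35.1, 38.0),   high = c(46.7, 52.1)),
    data.frame(analyte = "mcv",    sex = c("F", "M"), low = c(81.0, 81.5),   high = c(100.7, 101.8)),
    data.frame(analyte = "mch",    sex = c("F", "M"), low = c(26.3, 26.9),   high = c(32.6, 33.1)),
    data.frame(analyte = "plt",    sex = c("F", "M"), low = c(126.6, 128.4), high = c(344.7, 302.1)),
    data.frame(analyte = "wbc",    sex = c("F", "M"), low = c(2.9, 2.8),     high = c(10.05, 9.7)),
    data.frame(analyte = "neu",    sex = c("F", "M"), low = c(0.590, 0.550), high = c(6.5, 6.35)),
    data.frame(analyte = "mon",    sex = c("F", "M"), low = c(0.019, 0.002), high = c(0.7, 0.845)),
    data.frame(analyte = "lym",    sex = c("F", "M"), low = c(0.716, 0.582), high = c(3.4, 3.4)),
    data.frame(analyte = "eosbas", sex = c("F", "M"), low = c(0, 0),         high = c(0.574, 0.718))
  )
  rownames(rr) <- NULL
  rr
}

#' @rdname reference_ranges
#' @param analyte Analyte name (lowercase, e.g. "hb").
#' @param sex "F" or "M".
#' @param ranges Range table, defaults to [reference_ranges()].
#' @export
reference_range <- function(analyte, sex, ranges = reference_ranges()) {
  row <- ranges[ranges$analyte == analyte & ranges$sex == sex, ]
  if (nrow(row) != 1) stop("unknown analyte/sex: ", analyte, "/", sex)
  c(low = row$low, high = row$high)
}

#' EFLM analytical performance goals (maximum allowable CV, %)
#'
#' Desirable imprecision specifications used to judge the precision study:
#' PLT < 10%, RBC < 4%, HB < 3.6%, WBC < 15.9%.
#'
#' @return Named numeric vector of CV goals in percent.
#' @export
eflm_goals <- function() {
  c(rbc = 4, hb = 3.6, plt = 10, wbc = 15.9)
}
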