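#' Cell appearance model for the chamber renderer
#'
#' Each class is drawn as a radially symmetric Gaussian-profile disc on a
#' flat background: intensity `A * exp(-rho^2 / (2 s^2))` per channel, with
#' `s` set so the half-maximum radius equals half the cell diameter. Colors
#' stand in for the differential stain of the counting kit (red cells keep
#' their hemoglobin hue in chamber 2; the four mature leukocyte classes and
#' the immature class receive distinct dye mixtures in chamber 1). Diameters
#' are in um; the red-cell diameter distribution comes from the panel, not
#' from this table.
#'
#' @return data.frame: class, chamber, diameter_um, diameter_cv, r, g, b.
#' @export
cell_appearance <- function() {
  data.frame(
    class = c("rbc", "plt", "neu", "lym", "mon", "eosbas", "imm"),
    chamber = c(2L, 2L, 1L, 1L, 1L, 1L, 1L),
    diameter_um = c(7.4, 2.5, 12, 9, 16, 13, 15),
    diameter_cv = c(0.10, 0.15, 0.08, 0.08, 0.08, 0.08, 0.10),
    # the immature stain is low-red teal: outside the convex hull of the
    # mature-class chromaticities, so no superposition of mature cells
    # can mimic it
    r = c(0.85, 0.35, 0.45, 0.25, 0.75, 0.85, 0.10),
    g = c(0.30, 0.25, 0.35, 0.70, 0.55, 0.25, 0.55),
    b = c(0.12, 0.85, 0.80, 0.35, 0.25, 0.55, 0.85)
  )
}

# Background level and per-pixel camera noise of the rendered composite.
RENDER_BG <- 0.03
RENDER_NOISE_SD <- 0.01
AMP_JITTER_SD <- 0.05  # per-cell multiplicative stain-uptake jitter

# Gaussian profile scale: half-maximum radius = s * sqrt(2 ln 2)
HALFMAX_K <- sqrt(2 * log(2))
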