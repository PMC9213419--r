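#' Error model of the simulated comparator analyzer
#'
#' Stand-in for the central-laboratory reference instrument in method
#' comparison: each reported analyte is `truth * (1 + N(0, proportional_cv))
#' + N(0, constant_sd)`. Defaults: 2% proportional CV on every analyte and
#' no constant error.
#'
#' @param proportional_cv Single value or named per-analyte vector (over
#'   rbc, hb, plt, neu, lym, mon, eosbas).
#' @param constant_sd Single value or named per-analyte vector, analyte
#'   units.
#' @return List of class `comparator_error_model`.
#' @export
comparator_error_model <- function(proportional_cv = 0.02, constant_sd = 0) {
  analytes <- c("rbc", "hb", "plt", "neu", "lym", "mon", "eosbas")
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, length(analytes)), analytes)
    if (!all(analytes %in% names(x)))
      stop(what, " must cover all analytes or be a single value")
    if (any(x[analytes] < 0)) stop(what, " must be >= 0")
    x[analytes]
  }
  structure(list(proportional_cv = expand(proportional_cv, "proportional_cv"),
                 constant_sd = expand(constant_sd, "constant_sd")),
            class = "comparator_error_model")
}

#' Simulate the comparator analyzer on a ground-truth panel
#'
#' Perturbs RBC, HB, PLT and the four leukocyte subpopulations with the
#' error model; WBC is the sum of the perturbed subpopulations, and the
#' derived indices (HT, MCV, MCH) are recomputed from the perturbed HB and
#' RBC, as the reference instrument would report them. Values that fall
#' nonpositive after noise are clipped to a floor of 0.001 analyte units
#' (with a warning), never reported negative.
#'
#' @param panel A [gt_panel()].
#' @param error_model A [comparator_error_model()].
#' @param seed Integer seed.
#' @return An [analyte_panel()].
#' @export
simulate_reference_analyzer <- function(panel,
                                        error_model = comparator_error_model(),
                                        seed = 1L) {
  stopifnot(inherits(panel, "gt_panel"),
            inherits(error_model, "comparator_error_model"))
  truth <- c(rbc = panel$rbc, hb = panel$hb, plt = panel$plt,
             setNames(panel$wbc * panel$diff_fractions,
                      c("neu", "lym", "mon", "eosbas")))
  with_seed(seed, {
    cv <- error_model$proportional_cv[names(truth)]
    csd <- error_model$constant_sd[names(truth)]
    out <- truth * (1 + rnorm(length(truth), 0, cv)) +
      rnorm(length(truth), 0, csd)
    if (any(out <= 0)) {
      warning("comparator result(s) clipped to positivity floor: ",
              paste(names(out)[out <= 0], collapse = ", "))
      out[out <= 0] <- 0.001
    }
    idx <- estimate_indices(out[["hb"]], out[["rbc"]])
    analyte_panel(rbc = out[["rbc"]], hb = out[["hb"]],
                  ht = idx[["ht"]], mcv = idx[["mcv"]], mch = idx[["mch"]],
                  plt = out[["plt"]],
                  neu = out[["neu"]], lym = out[["lym"]],
                  mon = out[["mon"]], eosbas = out[["eosbas"]],
                  sex = panel$sex)
  })
}

#' True analyte panel implied by a ground-truth panel
#'
#' Derived indices use the same estimator the pipeline reports
#' ([estimate_indices()]), so truth and measurement live on the same scale.
#'
#' @param panel A [gt_panel()].
#' @return An [analyte_panel()].
#' @export
panel_to_analytes <- function(panel) {
  stopifnot(inherits(panel, "gt_panel"))
  sub <- panel$wbc * panel$diff_fractions
  idx <- estimate_indices(panel$hb, panel$rbc)
  analyte_panel(rbc = panel$rbc, hb = panel$hb,
                ht = idx[["ht"]], mcv = idx[["mcv"]], mch = idx[["mch"]],
                plt = panel$plt,
                neu = sub[["neu"]], lym = sub[["lym"]],
                mon = sub[["mon"]], eosbas = sub[["eosbas"]],
                sex = panel$sex)
}
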