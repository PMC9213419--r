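ALL_FLAGS <- c("microcytosis", "macrocytosis", "anisocytosis",
               "plt_clumps", "immature_cells")
CONDITIONS <- c("normal", "anemia", "thalassemia", "infection")

#' Ground-truth panel of a virtual patient
#'
#' Holds the true analyte values a simulated sample is generated from:
#' concentrations, the 4-part leukocyte differential, the red-cell size
#' distribution, the clinical condition label and the abnormality flags that
#' the renderer must realize. Units: rbc 10^6/mm^3; hb g/dL; plt and wbc
#' 10^3/mm^3; rbc_diameter_mean um; rbc_diameter_cv a fraction.
#'
#' Morphology flags are derived from the size distribution itself
#' (microcytosis iff mean diameter < 6.4 um, macrocytosis iff > 8.4 um,
#' anisocytosis iff diameter CV > 0.16) so truth flags and rendered
#' appearance can never disagree.
#'
#' @param rbc,hb,plt,wbc Positive analyte concentrations.
#' @param diff_fractions Numeric length-4 (neu, lym, mon, eosbas), sums to 1.
#' @param rbc_diameter_mean Mean red-cell diameter, um.
#' @param rbc_diameter_cv Red-cell diameter coefficient of variation, in
#'   (0, 0.5).
#' @param condition_label One of normal, anemia, thalassemia, infection.
#' @param plt_clumps,immature_cells Logical abnormality states.
#' @param sex "F" or "M".
#' @return An object of class `gt_panel`.
#' @export
gt_panel <- function(rbc, hb, plt, wbc,
                     diff_fractions = c(neu = 0.6, lym = 0.3, mon = 0.07,
                                        eosbas = 0.03),
                     rbc_diameter_mean = 7.4,
                     rbc_diameter_cv = 0.10,
                     condition_label = "normal",
                     plt_clumps = FALSE,
                     immature_cells = FALSE,
                     sex = "F") {
  vals <- c(rbc = rbc, hb = hb, plt = plt, wbc = wbc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all concentrations must be finite and > 0")
  diff_fractions <- setNames(as.numeric(diff_fractions),
                             c("neu", "lym", "mon", "eosbas"))
  if (any(diff_fractions < 0) || abs(sum(diff_fractions) - 1) > 1e-9)
    stop("diff_fractions must be nonnegative and sum to 1")
  if (!(rbc_diameter_cv > 0 && rbc_diameter_cv < 0.5))
    stop("rbc_diameter_cv must be in (0, 0.5)")
  if (!condition_label %in% CONDITIONS)
    stop("unknown condition_label: ", condition_label)
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  p <- structure(list(rbc = rbc, hb = hb, plt = plt, wbc = wbc,
                      diff_fractions = diff_fractions,
                      rbc_diameter_mean = rbc_diameter_mean,
                      rbc_diameter_cv = rbc_diameter_cv,
                      condition_label = condition_label,
                      sex = sex),
                 class = "gt_panel")
  p$flags_truth <- derive_truth_flags(rbc_diameter_mean, rbc_diameter_cv,
                                      plt_clumps, immature_cells)
  p
}

#' Truth flags implied by a panel's red-cell size distribution
#'
#' @param rbc_diameter_mean,rbc_diameter_cv Red-cell size distribution.
#' @param plt_clumps,immature_cells Logical states carried through.
#' @param thresholds Morphology thresholds, see [flag_thresholds()].
#' @return Named logical vector over the five flag families.
#' @export
derive_truth_flags <- function(rbc_diameter_mean, rbc_diameter_cv,
                               plt_clumps = FALSE, immature_cells = FALSE,
                               thresholds = flag_thresholds()) {
  c(microcytosis = rbc_diameter_mean < thresholds$microcytosis_um,
    macrocytosis = rbc_diameter_mean > thresholds$macrocytosis_um,
    anisocytosis = rbc_diameter_cv > thresholds$anisocytosis_cv,
    plt_clumps = isTRUE(plt_clumps),
    immature_cells = isTRUE(immature_cells))
}

#' @export
print.gt_panel <- function(x, ...) {
  cat(sprintf("<gt_panel> %s (%s)\n", x$condition_label, x$sex))
  cat(sprintf("  RBC %.2f e6/mm3  HB %.1f g/dL  PLT %.0f e3/mm3  WBC %.2f e3/mm3\n",
              x$rbc, x$hb, x$plt, x$wbc))
  cat(sprintf("  diff: NEU %.2f LYM %.2f MON %.2f EOS/BAS %.2f\n",
              x$diff_fractions[1], x$diff_fractions[2],
              x$diff_fractions[3], x$diff_fractions[4]))
  cat(sprintf("  RBC diameter %.2f um (CV %.2f); flags: %s\n",
              x$rbc_diameter_mean, x$rbc_diameter_cv,
              paste(names(x$flags_truth)[x$flags_truth], collapse = ", ")))
  invisible(x)
}

#' Cohort condition mixture of the simulated clinical study
#'
#' Defaults to 82% normal, 2.2% thalassemia, 6.6% anemia, 9.2% infection.
#'
#' @return Named numeric probabilities summing to 1.
#' @export
cohort_mixture <- function() {
  c(normal = 0.82, thalassemia = 0.022, anemia = 0.066, infection = 0.092)
}

# Draw a value from a truncated normal centered in a reference interval.
draw_in_range <- function(rng, frac_sd = 0.25) {
  mid <- mean(rng)
  w <- rng[["high"]] - rng[["low"]]
  rtruncnorm1(1, mid, frac_sd * w, rng[["low"]], rng[["high"]])
}

#' Sample a virtual patient
#'
#' Draws a condition from the cohort mixture, then analyte values from
#' documented per-condition distributions:
#' \itemize{
#'   \item normal: truncated Gaussians centered inside the sex-specific
#'     reference interval for each analyte; red-cell diameter N(7.4, 0.3) um
#'     truncated to (6.7, 8.2), diameter CV N(0.10, 0.015) truncated to
#'     (0.06, 0.14) -- no morphology flags arise.
#'   \item anemia: HB uniform on (8.0, sex lower bound - 0.2), RBC uniform on
#'     (2.8, sex lower bound), mildly microcytic and more dispersed red
#'     cells (diameter N(6.8, 0.5) on (5.6, 7.9); CV N(0.18, 0.04) on
#'     (0.10, 0.30)).
#'   \item thalassemia: small red cells with elevated count (diameter
#'     N(5.9, 0.25) on (5.3, 6.3); RBC uniform on (5.3, 6.5); HB uniform on
#'     (9.5, sex lower bound - 0.2); CV N(0.19, 0.03) on (0.12, 0.28)).
#'   \item infection: WBC uniform on (upper bound + 0.5, 24) with a
#'     neutrophil-shifted differential; immature cells present with
#'     probability 0.35.
#' }
#' Platelet clumps occur with probability 0.038 in any condition (the
#' prevalence seen in point-of-care flagging studies). Immature cells occur
#' with probability 0.005 outside infection.
#'
#' @param mixture_config Named probabilities over conditions; must sum to 1.
#' @param sex_ratio Named probabilities for sexes (default 58% F / 42% M).
#' @param seed Integer seed; the draw is a deterministic function of it.
#' @return A [gt_panel()].
#' @export
#' @examples
#' sample_patient(c(normal = 1), seed = 1)
sample_patient <- function(mixture_config = cohort_mixture(),
                           sex_ratio = c(F = 0.58, M = 0.42),
                           seed = 1L) {
  if (any(mixture_config < 0) || abs(sum(mixture_config) - 1) > 1e-6)
    stop("mixture probabilities must be nonnegative and sum to 1")
  if (!all(names(mixture_config) %in% CONDITIONS))
    stop("unknown condition in mixture: ",
         paste(setdiff(names(mixture_config), CONDITIONS), collapse = ", "))
  with_seed(seed, {
    condition <- sample(names(mixture_config), 1, prob = mixture_config)
    sex <- sample(names(sex_ratio), 1, prob = sex_ratio)
    rr <- reference_ranges()
    rng <- function(a) reference_range(a, sex, rr)

    rbc <- draw_in_range(rng("rbc"))
    hb <- draw_in_range(rng("hb"))
    plt <- draw_in_range(rng("plt"))
    wbc <- draw_in_range(rng("wbc"))
    dmean <- rtruncnorm1(1, 7.4, 0.3, 6.7, 8.2)
    dcv <- rtruncnorm1(1, 0.10, 0.015, 0.06, 0.14)
    subc <- vapply(c("neu", "lym", "mon", "eosbas"),
                   function(a) draw_in_range(rng(a)), numeric(1))
    immature_p <- 0.005

    if (condition == "anemia") {
      lo <- rng("hb")[["low"]]
      hb <- runif(1, 8.0, lo - 0.2)
      rbc <- runif(1, 2.8, rng("rbc")[["low"]])
      dmean <- rtruncnorm1(1, 6.8, 0.5, 5.6, 7.9)
      dcv <- rtruncnorm1(1, 0.18, 0.04, 0.10, 0.30)
    } else if (condition == "thalassemia") {
      dmean <- rtruncnorm1(1, 5.9, 0.25, 5.3, 6.3)
      rbc <- runif(1, 5.3, 6.5)
      hb <- runif(1, 9.5, rng("hb")[["low"]] - 0.2)
      dcv <- rtruncnorm1(1, 0.19, 0.03, 0.12, 0.28)
    } else if (condition == "infection") {
      wbc <- runif(1, rng("wbc")[["high"]] + 0.5, 24)
      subc["neu"] <- subc["neu"] * runif(1, 2.5, 4)
      immature_p <- 0.35
    }

    fractions <- subc / sum(subc)
    gt_panel(rbc = rbc, hb = hb, plt = plt, wbc = wbc,
             diff_fractions = fractions,
             rbc_diameter_mean = dmean, rbc_diameter_cv = dcv,
             condition_label = condition,
             plt_clumps = runif(1) < 0.038,
             immature_cells = runif(1) < immature_p,
             sex = sex)
  })
}
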