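#' Default thresholds for morphological flagging
#'
#' Standard red-cell morphology heuristics scaled to the renderer geometry:
#' microcytosis below a mean equivalent diameter of 6.4 um, macrocytosis
#' above 8.4 um, anisocytosis above a diameter CV of 0.16 (normal cohorts
#' sit near 0.10). Platelet clumping uses single-linkage clustering with a
#' cutoff of 1.5 mean platelet diameters and a minimum cluster of 3.
#'
#' @param microcytosis_um,macrocytosis_um Mean-diameter thresholds (um).
#' @param anisocytosis_cv Diameter-CV threshold.
#' @param min_rbc Minimum red-cell detections for stable morphology flags.
#' @param clump_link_factor Linkage cutoff in units of mean PLT diameter.
#' @param clump_min_size Minimum cluster size to call clumping.
#' @param immature_min Minimum immature-labelled detections to flag.
#' @return Named list of thresholds.
#' @export
flag_thresholds <- function(microcytosis_um = 6.4, macrocytosis_um = 8.4,
                            anisocytosis_cv = 0.16, min_rbc = 200,
                            clump_link_factor = 1.5, clump_min_size = 3,
                            immature_min = 1) {
  list(microcytosis_um = microcytosis_um, macrocytosis_um = macrocytosis_um,
       anisocytosis_cv = anisocytosis_cv, min_rbc = min_rbc,
       clump_link_factor = clump_link_factor,
       clump_min_size = clump_min_size, immature_min = immature_min)
}

#' Red-cell morphology flags from chamber-2 detections
#'
#' Uses the per-detection equivalent diameters: microcytosis iff the mean
#' diameter is below the low threshold, macrocytosis iff above the high
#' threshold, anisocytosis iff the diameter CV exceeds the dispersion
#' threshold. With fewer red cells than `min_rbc` the flags are returned as
#' NA with a reason, never silently negative.
#'
#' @param rbc_detections Detection data.frame (rows with label "rbc" are
#'   used).
#' @param thresholds See [flag_thresholds()].
#' @return List with logical microcytosis/macrocytosis/anisocytosis,
#'   `evidence` (mean_diameter_um, diameter_cv, n) and optional `reason`.
#' @export
rbc_morphology_flags <- function(rbc_detections,
                                 thresholds = flag_thresholds()) {
  d <- rbc_detections
  if (!is.null(d) && nrow(d) && "label" %in% names(d))
    d <- d[d$label == "rbc", ]
  n <- if (is.null(d)) 0L else nrow(d)
  if (n < thresholds$min_rbc) {
    return(list(microcytosis = NA, macrocytosis = NA, anisocytosis = NA,
                evidence = list(mean_diameter_um = NA_real_,
                                diameter_cv = NA_real_, n = n),
                reason = sprintf("only %d red cells (need >= %d)",
                                 n, thresholds$min_rbc)))
  }
  m <- mean(d$diameter_um)
  cv <- sd(d$diameter_um) / m
  list(microcytosis = m < thresholds$microcytosis_um,
       macrocytosis = m > thresholds$macrocytosis_um,
       anisocytosis = cv > thresholds$anisocytosis_cv,
       evidence = list(mean_diameter_um = m, diameter_cv = cv, n = n))
}

#' Platelet clump flag from chamber-2 detections
#'
#' Single-linkage clustering of platelet centers at a distance cutoff of
#' `clump_link_factor` times the mean platelet diameter; the flag is raised
#' iff any cluster reaches `clump_min_size` members.
#'
#' @param plt_detections Detection data.frame (rows with label "plt" are
#'   used); needs cx, cy, diameter_um.
#' @param geometry [chamber_geometry()] supplying the pixel scale.
#' @param thresholds See [flag_thresholds()].
#' @return List: plt_clumps flag, evidence (n_clusters of qualifying size,
#'   largest cluster, n platelets).
#' @export
platelet_clump_flag <- function(plt_detections, geometry,
                                thresholds = flag_thresholds()) {
  d <- plt_detections
  if (!is.null(d) && nrow(d) && "label" %in% names(d))
    d <- d[d$label == "plt", ]
  n <- if (is.null(d)) 0L else nrow(d)
  if (n < thresholds$clump_min_size)
    return(list(plt_clumps = FALSE,
                evidence = list(n_clusters = 0L, largest = n, n_plt = n)))
  xy_um <- cbind(d$cx, d$cy) * geometry$pixel_scale
  cutoff <- thresholds$clump_link_factor * mean(d$diameter_um)
  cl <- cutree(hclust(dist(xy_um), method = "single"), h = cutoff)
  sizes <- tabulate(cl)
  qual <- sum(sizes >= thresholds$clump_min_size)
  list(plt_clumps = qual > 0,
       evidence = list(n_clusters = qual, largest = max(sizes), n_plt = n))
}

#' Immature-cell flag from chamber-1 detections
#'
#' Counts immature-labelled detections whose equivalent diameter lies in
#' the class's plausible range; fragments of split mature cells are much
#' smaller than genuine immature precursors and are not counted.
#'
#' @param chamber1_detections Detection data.frame.
#' @param min_count Minimum credible immature detections (default 1).
#' @param min_diameter_um Lower size bound for a credible immature cell.
#' @return List: immature_cells flag, evidence (immature count).
#' @export
immature_cell_flag <- function(chamber1_detections, min_count = 1,
                               min_diameter_um = 11) {
  n <- if (is.null(chamber1_detections) || !nrow(chamber1_detections)) 0L
       else sum(chamber1_detections$label == "imm" &
                  chamber1_detections$diameter_um >= min_diameter_um)
  list(immature_cells = n >= min_count, evidence = list(n_immature = n))
}

#' Confusion-matrix metrics for binary concordance
#'
#' @param tp,fp,tn,fn Cell counts of the 2x2 table (positive = abnormal /
#'   outside range).
#' @return Object of class `confusion_metrics`: counts, sensitivity,
#'   specificity, accuracy, balanced_accuracy (all %), and Cohen's kappa.
#'   Degenerate margins give NA (a study with no positives cannot report a
#'   sensitivity), never a silent 100%.
#' @export
#' @examples
#' confusion_metrics(tp = 17, fp = 0, tn = 433, fn = 0)
confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / n
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  po <- (tp + tn) / n
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 balanced_accuracy = ba, kappa = kappa),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> tp %d fp %d tn %d fn %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  acc %.1f%%  sens %s  spec %s  bal.acc %s  kappa %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.1f%%", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.1f%%", x$specificity)),
              ifelse(is.na(x$balanced_accuracy), "NA", sprintf("%.1f%%", x$balanced_accuracy)),
              ifelse(is.na(x$kappa), "NA", sprintf("%.2f", x$kappa))))
  invisible(x)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity In percent.
#' @return Balanced accuracy in percent.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Flagging concordance against truth
#'
#' Builds one confusion matrix per flag family from paired predicted and
#' true flag tables.
#'
#' @param predicted_flags,truth_flags data.frames (or matrices) of logicals
#'   with the same flag columns and equal row counts.
#' @return Named list of [confusion_metrics()] per flag column.
#' @export
flag_concordance <- function(predicted_flags, truth_flags) {
  predicted_flags <- as.data.frame(predicted_flags)
  truth_flags <- as.data.frame(truth_flags)
  if (nrow(predicted_flags) != nrow(truth_flags))
    stop("predicted and truth flag tables must have equal length")
  common <- intersect(names(predicted_flags), names(truth_flags))
  if (!length(common)) stop("no shared flag columns")
  out <- lapply(common, function(fl) {
    p <- as.logical(predicted_flags[[fl]])
    t <- as.logical(truth_flags[[fl]])
    ok <- !is.na(p) & !is.na(t)
    confusion_metrics(tp = sum(p[ok] & t[ok]), fp = sum(p[ok] & !t[ok]),
                      tn = sum(!p[ok] & !t[ok]), fn = sum(!p[ok] & t[ok]))
  })
  setNames(out, common)
}

#' All flags for one analyzed sample
#'
#' @param chamber1_detections,chamber2_detections Detection data.frames
#'   (either may be NULL).
#' @param geometry Chamber-2 [chamber_geometry()] (pixel scale for clump
#'   distances).
#' @param thresholds See [flag_thresholds()].
#' @return Named logical vector over the five flag families (NA where not
#'   assessable) with attribute `evidence`.
#' @export
sample_flags <- function(chamber1_detections, chamber2_detections,
                         geometry = chamber_geometry(2),
                         thresholds = flag_thresholds()) {
  morph <- if (is.null(chamber2_detections))
    list(microcytosis = NA, macrocytosis = NA, anisocytosis = NA,
         evidence = NULL)
  else rbc_morphology_flags(chamber2_detections, thresholds)
  clump <- if (is.null(chamber2_detections))
    list(plt_clumps = NA, evidence = NULL)
  else platelet_clump_flag(chamber2_detections, geometry, thresholds)
  imm <- if (is.null(chamber1_detections))
    list(immature_cells = NA, evidence = NULL)
  else immature_cell_flag(chamber1_detections, thresholds$immature_min)
  out <- c(microcytosis = morph$microcytosis,
           macrocytosis = morph$macrocytosis,
           anisocytosis = morph$anisocytosis,
           plt_clumps = clump$plt_clumps,
           immature_cells = imm$immature_cells)
  attr(out, "evidence") <- list(morphology = morph$evidence,
                                clumps = clump$evidence,
                                immature = imm$evidence)
  out
}
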