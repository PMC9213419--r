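# intensity scale used when quantizing linear rasters to 16-bit files:
# rendered intensities are linear and can exceed 1 where cells superpose
RASTER_SCALE <- 4

#' Write a chamber image as 16-bit TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) carries the chamber geometry, the fixed
#' intensity scale of the quantization, and the ground-truth objects
#' (0-based pixel coordinates, boxes half-open), so a dataset on disk is
#' self-describing.
#'
#' @param image A `chamber_image`.
#' @param path Path without extension; writes `<path>.tiff` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_chamber_image <- function(image, path) {
  stopifnot(inherits(image, "chamber_image"))
  px <- pmin(pmax(image$pixels / RASTER_SCALE, 0), 1)
  tiff::writeTIFF(px, paste0(path, ".tiff"), bits.per.sample = 16L)
  g <- image$geometry
  sidecar <- list(
    geometry = list(chamber_id = g$chamber_id,
                    counting_area = g$counting_area, depth = g$depth,
                    pixel_scale = g$pixel_scale),
    intensity_scale = RASTER_SCALE,
    truth_objects = image$truth_objects)
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a chamber image written by [write_chamber_image()]
#'
#' @param path Path without extension.
#' @return A `chamber_image`.
#' @export
read_chamber_image <- function(path) {
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path))
    stop("missing sidecar: ", json_path, call. = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  px <- tiff::readTIFF(paste0(path, ".tiff")) * side$intensity_scale
  g <- side$geometry
  truth <- side$truth_objects
  if (is.null(truth) || length(truth) == 0) truth <- NULL
  else truth <- as.data.frame(truth)
  structure(list(pixels = px,
                 geometry = chamber_geometry(g$chamber_id,
                                             g$counting_area, g$depth,
                                             g$pixel_scale),
                 truth_objects = truth),
            class = "chamber_image")
}

#' Write / read a strip image (16-bit TIFF + JSON sidecar)
#'
#' @param strip A `strip_image`.
#' @param path Path without extension.
#' @return `path`, invisibly.
#' @export
write_strip_image <- function(strip, path) {
  stopifnot(inherits(strip, "strip_image"))
  px <- pmin(pmax(strip$pixels, 0), 1)
  tiff::writeTIFF(px, paste0(path, ".tiff"), bits.per.sample = 16L)
  jsonlite::write_json(list(roi = as.list(strip$roi),
                            hb_truth = strip$hb_truth),
                       paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_strip_image
#' @export
read_strip_image <- function(path) {
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path))
    stop("missing sidecar: ", json_path, call. = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(pixels = tiff::readTIFF(paste0(path, ".tiff")),
                 roi = unlist(side$roi), hb_truth = side$hb_truth),
            class = "strip_image")
}

#' Write an analyte panel as CSV
#'
#' Columns: sample_id, analyte, value, unit, flag. The flag column
#' carries per-sample qualitative flags (semicolon-joined) on every row.
#'
#' @param panel An [analyte_panel()].
#' @param path Output file.
#' @param sample_id Identifier written in the first column.
#' @param flags Optional named logical vector of flags.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, sample_id = 1, flags = NULL) {
  df <- as.data.frame(panel)
  flag_str <- if (is.null(flags)) ""
              else paste(names(flags)[!is.na(flags) & flags], collapse = ";")
  out <- data.frame(sample_id = sample_id, analyte = df$analyte,
                    value = df$value, unit = df$unit, flag = flag_str)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an analyte panel CSV back into an [analyte_panel()]
#'
#' @param path CSV written by [write_panel_csv()].
#' @param sex Sex label for the reconstructed panel.
#' @return An [analyte_panel()] (units are validated against the
#'   package's unit tags; a mismatch is an error, not a silent rescale).
#' @export
read_panel_csv <- function(path, sex = "F") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  units <- analyte_units()
  for (a in df$analyte) {
    if (a %in% names(units) && df$unit[df$analyte == a][1] != units[[a]])
      stop("unit mismatch for ", a, ": ", df$unit[df$analyte == a][1],
           " (expected ", units[[a]], ")", call. = FALSE)
  }
  val <- function(a) {
    v <- df$value[df$analyte == a]
    if (length(v)) v[1] else NA_real_
  }
  analyte_panel(rbc = val("rbc"), hb = val("hb"), ht = val("ht"),
                mcv = val("mcv"), mch = val("mch"), plt = val("plt"),
                neu = val("neu"), lym = val("lym"), mon = val("mon"),
                eosbas = val("eosbas"), sex = sex)
}

#' Write detections as CSV
#'
#' Columns: sample_id, chamber_id, x0, y0, x1, y1, label, confidence and
#' the per-class probability columns.
#'
#' @param detections Detection data.frame from [detect_cells()].
#' @param path Output file.
#' @param sample_id,chamber_id Identifiers for the first columns.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path, sample_id = 1,
                                 chamber_id = NA) {
  pcols <- grep("^p_", names(detections), value = TRUE)
  out <- cbind(data.frame(sample_id = sample_id, chamber_id = chamber_id),
               detections[, c("x0", "y0", "x1", "y1", "label",
                              "confidence", pcols)])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read the paired validation measurements table
#'
#' CSV header: sample_id, analyte, truth, poct, reference, condition,
#' sex, flags.
#'
#' @param dataset A `validation_dataset` (or its `measurements`
#'   data.frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(dataset, path) {
  df <- if (inherits(dataset, "validation_dataset")) dataset$measurements
        else dataset
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed CSV: ",
                                          conditionMessage(e),
                                          call. = FALSE))
  need <- c("sample_id", "analyte", "truth", "poct", "reference",
            "condition", "sex", "flags")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("truth", "poct", "reference")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & v != "NA" &
                   !is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("malformed numeric value in column ", col, ", row ",
           bad[1] + 1L, call. = FALSE)
    df[[col]] <- suppressWarnings(as.numeric(v))
  }
  df
}
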