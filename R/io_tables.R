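.FIBRE_TABLE_COLUMNS <- c(
  "label", "centroid_y", "centroid_x",
  "fibre_area", "sarcoplasm_area", "sarcolemma_area",
  "fibre_width", "sarcoplasm_width",
  "mean_ring_thickness", "max_ring_thickness", "circumference",
  "mask_sarcolemma_mean", "mask_sarcoplasm_mean",
  "primary_sarcolemma_mean", "primary_sarcoplasm_mean",
  "primary_threshold", "primary_circumference_positivity",
  "primary_coverage_class", "primary_is_positive",
  "tertiary_sarcolemma_mean", "tertiary_sarcoplasm_mean",
  "tertiary_threshold", "tertiary_circumference_positivity",
  "tertiary_coverage_class", "tertiary_is_positive",
  "tertiary_mean_in_primary_pos", "tertiary_mean_in_primary_neg",
  "myosin_positive", "quantifiable")

#' Write the per-fibre record table as CSV
#'
#' One row per fibre in a fixed, documented column order (label and
#' centroid; morphometrics in um / um^2; per-channel raw means, threshold,
#' Circumference Positivity, coverage class and positive call; the
#' colocalisation pair; the myosin call; the quantifiable flag). Floats are
#' written at 6 significant digits; output is byte-stable across runs on
#' identical input. Columns missing from `records` are emitted as empty.
#'
#' @param records Per-fibre data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fibre_table <- function(records, path) {
  if (nrow(records) == 0L) stop("records must be non-empty")
  out <- records
  for (col in setdiff(.FIBRE_TABLE_COLUMNS, names(out))) out[[col]] <- NA
  out <- out[, .FIBRE_TABLE_COLUMNS]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "label"
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  con <- file(path, open = "wb")  # binary mode: identical bytes on all platforms
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, eol = "\n", na = "")
  invisible(path)
}

.DEFAULT_CLASS_PALETTE <- c("0-25" = "#CA0020", "25-50" = "#F4A582",
                            "50-75" = "#92C5DE", "75-100" = "#0571B0")
.UNRECOGNISED_COLOUR <- "#FFFF00"

#' Render a coverage classification map
#'
#' Colour-codes each fibre by its coverage class (four distinct colours, one
#' per class), paints unrecognised tissue/connective regions yellow, and
#' leaves the background black. The palette is a bijection with the class
#' vocabulary and is configurable.
#'
#' @param labels A `fibre_label_map` (or a bare integer label matrix).
#' @param classes Character vector of coverage classes, one per fibre label
#'   (in label order), using the levels `"0-25"`, `"25-50"`, `"50-75"`,
#'   `"75-100"`; `NA` renders as unrecognised.
#' @param unrecognised Optional logical matrix of tissue that was not
#'   recognised as fibres.
#' @param palette Named colour vector over the four classes.
#' @param path Optional PNG output path.
#' @return `H x W x 3` numeric array in `[0, 1]` (invisibly if written).
#' @export
render_classification_map <- function(labels, classes, unrecognised = NULL,
                                      palette = .DEFAULT_CLASS_PALETTE,
                                      path = NULL) {
  lab <- if (inherits(labels, "fibre_label_map")) labels$labels else labels
  n_lab <- max(lab)
  if (!setequal(names(palette), .COVERAGE_CLASSES) ||
      anyDuplicated(palette) > 0L)
    stop("palette must assign one distinct colour to each of the 4 classes")
  if (n_lab > 0L) {
    if (length(classes) != n_lab)
      stop("need one class per fibre label (labels ",
           paste(setdiff(seq_len(n_lab), seq_along(classes)), collapse = ", "),
           " lack a class)")
    bad <- !is.na(classes) & !classes %in% .COVERAGE_CLASSES
    if (any(bad)) stop("unknown classes: ", paste(unique(classes[bad]), collapse = ", "))
  }
  rgb <- array(0, dim = c(dim(lab), 3L))
  cols_rgb <- grDevices::col2rgb(palette[.COVERAGE_CLASSES]) / 255
  unrec_rgb <- as.numeric(grDevices::col2rgb(.UNRECOGNISED_COLOUR)) / 255
  for (k in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    if (!is.null(unrecognised)) plane[unrecognised & lab == 0L] <- unrec_rgb[k]
    if (n_lab > 0L) {
      cls_idx <- match(classes, .COVERAGE_CLASSES)
      sel <- lab > 0L
      val <- ifelse(is.na(cls_idx[lab[sel]]), unrec_rgb[k],
                    cols_rgb[k, ifelse(is.na(cls_idx[lab[sel]]), 1L, cls_idx[lab[sel]])])
      plane[sel] <- val
    }
    rgb[, , k] <- plane
  }
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' Write a section summary as JSON
#'
#' @param summary A `section_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_section_summary <- function(summary, path) {
  stopifnot(inherits(summary, "section_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
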