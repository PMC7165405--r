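#' Run the full section analysis pipeline
#'
#' Convenience wrapper chaining the three stages: tissue detection and
#' artefact exclusion, fibre segmentation and sarcolemma/sarcoplasm
#' partitioning, and per-fibre characterisation (morphometrics, staining
#' profile, optional myosin classification), ending in the section summary.
#'
#' @param stack A [channel_stack()].
#' @param seg_params A [segmentation_params()].
#' @param quant_params A [quantification_params()].
#' @param myosin_threshold Optional `myosin_threshold` (applies when the
#'   stack's tertiary channel is sarcoplasmic).
#' @return List of class `section_analysis`: `records` (per-fibre table:
#'   morphometrics joined with staining profile and myosin call), `summary`
#'   ([summarise_section()] result), `labels` (`fibre_label_map`),
#'   `partition`, `tissue`, `rejected` (segmentation + partition
#'   rejections).
#' @export
analyse_section <- function(stack,
                            seg_params = segmentation_params(),
                            quant_params = quantification_params(),
                            myosin_threshold = NULL) {
  tissue <- detect_tissue(stack, seg_params)
  tissue <- exclude_artefacts(stack, tissue, seg_params)
  labels <- segment_fibres(stack, tissue, seg_params)
  partition <- partition_fibres(labels, stack, seg_params)
  if (nrow(partition$dropped) > 0L) {
    # remove ring-dominant fibres from the label map and renumber
    drop <- partition$dropped$label
    lab <- labels$labels
    lab[lab %in% drop] <- 0L
    labels$labels <- relabel_raster_order(lab)
    labels$n_fibres <- max(labels$labels)
    labels$rejected <- rbind(labels$rejected,
                             data.frame(candidate = drop, reason = "ring-dominant",
                                        area_um2 = NA_real_))
    old <- as.integer(names(partition$fibres))
    new <- match(old, sort(setdiff(old, drop)))
    names(partition$fibres) <- as.character(new)
    for (i in seq_along(partition$fibres)) partition$fibres[[i]]$label <- new[i]
  }
  morpho <- compute_morphometrics(partition)
  profile <- measure_stain_profile(partition, stack, quant_params)
  records <- merge(morpho, profile, by = "label", sort = TRUE)
  if (!is.null(myosin_threshold) && stack$tertiary_kind == "sarcoplasmic") {
    records$myosin_positive <- classify_myosin(records, myosin_threshold)
  } else {
    records$myosin_positive <- NA
  }
  summary <- summarise_section(records, n_rejected = nrow(labels$rejected),
                               positivity_cutoff = quant_params$positivity_cutoff)
  structure(list(records = records, summary = summary, labels = labels,
                 partition = partition, tissue = tissue,
                 rejected = labels$rejected),
            class = "section_analysis")
}

#' Write all pipeline outputs for one section
#'
#' Emits the per-fibre CSV, the section-summary JSON, the rejected-candidate
#' CSV, and the coverage classification map PNG into a directory.
#'
#' @param analysis A `section_analysis` from [analyse_section()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_section_outputs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "section_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fibre_table(analysis$records, file.path(dir, "fibres.csv"))
  write_section_summary(analysis$summary, file.path(dir, "summary.json"))
  con <- file(file.path(dir, "rejected.csv"), open = "wb")
  utils::write.csv(analysis$rejected, con, row.names = FALSE, eol = "\n")
  close(con)
  rec <- analysis$records
  cls <- rec$primary_coverage_class[order(rec$label)]
  unrec <- analysis$tissue$tissue & analysis$labels$labels == 0L
  render_classification_map(analysis$labels, cls, unrecognised = unrec,
                            path = file.path(dir, "classification_map.png"))
  invisible(dir)
}

#' Load segmentation and quantification parameters from a YAML config
#'
#' Reads `segmentation:` and `quantification:` blocks whose keys mirror the
#' arguments of [segmentation_params()] and [quantification_params()].
#'
#' @param path YAML file path.
#' @return List with elements `segmentation`, `quantification`, and
#'   `channels` (a [channel_config()] built from an optional `channels:`
#'   block with keys `mask`, `primary`, `tertiary`, `tertiary_kind`,
#'   `pixel_size`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, cfg$segmentation %||% list())
  qnt <- do.call(quantification_params, cfg$quantification %||% list())
  ch <- do.call(channel_config, cfg$channels %||% list())
  list(segmentation = seg, quantification = qnt, channels = ch)
}
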