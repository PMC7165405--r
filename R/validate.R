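#' Match analysed fibre labels to ground-truth labels
#'
#' Pairs each ground-truth fibre with the analysed label of maximum pixel
#' overlap and reports the Jaccard index of the pair. Used to validate
#' segmentation and quantification against synthetic sections.
#'
#' @param analysed Integer label matrix (or `fibre_label_map`) produced by
#'   the pipeline.
#' @param truth_labels True integer label matrix (e.g. the `labels` element
#'   of [generate_section()] output).
#' @return Data frame with one row per true label: `true_label`,
#'   `matched_label` (0 if undetected), `jaccard`, `true_area_px`.
#' @export
match_labels <- function(analysed, truth_labels) {
  lab <- if (inherits(analysed, "fibre_label_map")) analysed$labels else analysed
  stopifnot(identical(dim(lab), dim(truth_labels)))
  n_true <- max(truth_labels)
  rows <- lapply(seq_len(n_true), function(i) {
    ti <- truth_labels == i
    ov <- table(lab[ti])
    ov <- ov[names(ov) != "0"]
    if (length(ov) == 0L)
      return(data.frame(true_label = i, matched_label = 0L, jaccard = 0,
                        true_area_px = sum(ti)))
    b <- as.integer(names(ov)[which.max(ov)])
    data.frame(true_label = i, matched_label = b,
               jaccard = sum(ti & lab == b) / sum(ti | lab == b),
               true_area_px = sum(ti))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
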