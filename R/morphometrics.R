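#' Per-fibre morphometrics in physical units
#'
#' Computes, for every fibre in a partition, the morphological descriptors:
#' fibre / sarcoplasm / sarcolemma areas (pixel counts times pixel area),
#' fibre and sarcoplasm widths (minimum caliper, i.e. minimum Feret,
#' diameter — the standard muscle-morphometry width measure, robust to
#' oblique sectioning), mean and maximum sarcolemma thickness (twice the
#' ring's distance-transform value sampled along the ring mid-line), and
#' circumference (corrected mid-line path length).
#'
#' @param partition A `sarcolemma_partition` from [partition_fibres()].
#' @param pixel_size Micrometres per pixel (defaults to the partition's).
#' @return Data frame, one row per fibre: `label`, `centroid_y`,
#'   `centroid_x` (px), `fibre_area`, `sarcoplasm_area`, `sarcolemma_area`
#'   (um^2), `fibre_width`, `sarcoplasm_width`, `mean_ring_thickness`,
#'   `max_ring_thickness`, `circumference` (um).
#' @export
compute_morphometrics <- function(partition, pixel_size = partition$pixel_size) {
  stopifnot(inherits(partition, "sarcolemma_partition"))
  rows <- lapply(partition$fibres, function(f) {
    n_region <- sum(f$region)
    if (n_region < 8L) stop("degenerate fibre mask (label ", f$label, ")")
    rc <- which(f$region, arr.ind = TRUE)
    sc <- which(f$sarcoplasm, arr.ind = TRUE)
    dmap_ring <- matrix(as.numeric(EBImage::distmap(EBImage::Image(f$ring * 1))),
                        nrow = nrow(f$ring))
    ml_local <- cbind(f$midline[, 1L] - f$bbox$r1 + 1L,
                      f$midline[, 2L] - f$bbox$c1 + 1L)
    tvals <- 2 * dmap_ring[ml_local]
    tvals <- tvals[tvals > 0]
    if (length(tvals) == 0L) tvals <- NA_real_
    data.frame(label = f$label,
               centroid_y = f$centroid[1L], centroid_x = f$centroid[2L],
               fibre_area = n_region * pixel_size^2,
               sarcoplasm_area = sum(f$sarcoplasm) * pixel_size^2,
               sarcolemma_area = sum(f$ring) * pixel_size^2,
               fibre_width = min_feret_px(rc) * pixel_size,
               sarcoplasm_width = min_feret_px(sc) * pixel_size,
               mean_ring_thickness = mean(tvals) * pixel_size,
               max_ring_thickness = max(tvals) * pixel_size,
               circumference = f$circumference_px * pixel_size)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
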