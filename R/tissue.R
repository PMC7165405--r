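#' Segmentation parameters
#'
#' Tunable parameters for tissue detection, artefact exclusion and fibre
#' segmentation. Defaults are declared values chosen for transverse-section
#' quality control: the area window excludes debris and small newly
#' regenerating / atrophic profiles below `min_fibre_area` and fused clumps
#' above `max_fibre_area`; the solidity floor rejects non-convex profiles
#' such as longitudinally cut fibres; the ring-thickness cap flags candidates
#' whose membrane band is implausibly thick (mis-recognised regions).
#'
#' @param mask_threshold_method `"otsu"` (within tissue) or `"fixed"`.
#' @param fixed_threshold Threshold in AU when method is `"fixed"`.
#' @param smooth_sigma_um Gaussian smoothing sigma for the mask channel (um).
#' @param min_tissue_area Minimum tissue component area (um^2); kept below
#'   the smallest fibre of interest so that undersized fibre candidates reach
#'   segmentation, where their rejection is recorded with a reason.
#' @param min_tissue_contrast Minimum ratio of mean mask intensity above vs
#'   below the tissue threshold (Otsu method); an image failing it (e.g.
#'   pure background noise) raises "no tissue detected".
#' @param min_fibre_area,max_fibre_area Accepted fibre area window (um^2).
#' @param min_solidity Minimum region solidity in (0, 1].
#' @param max_mean_ring_thickness Maximum mean sarcolemma thickness (um).
#' @param ring_mode `"laminin-band"` (ring = detected membrane band) or
#'   `"fixed-band"` (band of `fixed_band_um` measured inward from the fibre
#'   boundary).
#' @param fixed_band_um Band width for `"fixed-band"` mode (um).
#' @param saturation_fraction Pixels at or above this fraction of full scale
#'   count as saturated for artefact exclusion.
#' @param min_artefact_area Minimum saturated-region area to exclude (um^2).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(mask_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 15000,
                                smooth_sigma_um = 0.5,
                                min_tissue_area = 50,
                                min_tissue_contrast = 1.5,
                                min_fibre_area = 150,
                                max_fibre_area = 12000,
                                min_solidity = 0.80,
                                max_mean_ring_thickness = 5,
                                ring_mode = c("laminin-band", "fixed-band"),
                                fixed_band_um = 1,
                                saturation_fraction = 0.95,
                                min_artefact_area = 20) {
  mask_threshold_method <- match.arg(mask_threshold_method)
  ring_mode <- match.arg(ring_mode)
  if (min_fibre_area >= max_fibre_area) stop("min_fibre_area must be < max_fibre_area")
  if (min_solidity <= 0 || min_solidity > 1) stop("min_solidity must lie in (0, 1]")
  structure(list(mask_threshold_method = mask_threshold_method,
                 fixed_threshold = fixed_threshold,
                 smooth_sigma_um = smooth_sigma_um,
                 min_tissue_area = min_tissue_area,
                 min_tissue_contrast = min_tissue_contrast,
                 min_fibre_area = min_fibre_area, max_fibre_area = max_fibre_area,
                 min_solidity = min_solidity,
                 max_mean_ring_thickness = max_mean_ring_thickness,
                 ring_mode = ring_mode, fixed_band_um = fixed_band_um,
                 saturation_fraction = saturation_fraction,
                 min_artefact_area = min_artefact_area),
            class = "segmentation_params")
}

#' Detect muscle tissue in the mask channel
#'
#' Stage 1 of the pipeline: smooth the laminin mask channel, threshold it
#' (Otsu by default), morphologically close and hole-fill the result so that
#' closed membrane outlines become solid tissue, and drop components smaller
#' than `min_tissue_area`.
#'
#' @param stack A [channel_stack()].
#' @param params A [segmentation_params()].
#' @return A `tissue_mask` list: `tissue` and `excluded` logical matrices and
#'   a `provenance` character vector of applied rules.
#' @export
detect_tissue <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "channel_stack"))
  ps <- stack$pixel_size
  m <- get_channel(stack, "mask")
  sigma <- max(params$smooth_sigma_um / ps, 0.5)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(m / 65535), sigma = sigma))
  if (diff(range(sm)) == 0) {
    # constant channel: either nothing at all, or a uniformly bright field
    # (e.g. fully saturated) to be resolved by artefact exclusion
    if (max(sm) == 0) stop("no tissue detected")
    bin <- matrix(TRUE, nrow(m), ncol(m))
  } else {
    th <- if (params$mask_threshold_method == "otsu")
      otsu_threshold(sm) else params$fixed_threshold / 65535
    bin <- sm > th
    if (params$mask_threshold_method == "otsu" && any(bin) && !all(bin) &&
        mean(sm[bin]) < params$min_tissue_contrast * mean(sm[!bin]))
      stop("no tissue detected (mask channel lacks membrane contrast)")
  }
  brush <- EBImage::makeBrush(5L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(bin * 1), brush)
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  lab <- matrix(as.integer(lab), nrow = nrow(m))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * ps^2 >= params$min_tissue_area)
    tissue <- matrix(lab %in% keep, nrow = nrow(m))
  } else tissue <- matrix(FALSE, nrow(m), ncol(m))
  if (!any(tissue)) stop("no tissue detected")
  structure(list(tissue = tissue,
                 excluded = matrix(FALSE, nrow(m), ncol(m)),
                 provenance = sprintf("mask threshold (%s), close+fill, min area %g um^2",
                                      params$mask_threshold_method,
                                      params$min_tissue_area)),
            class = "tissue_mask")
}

#' Exclude artefact regions from the tissue mask
#'
#' Regions saturated in at least two channels (section folds, bright debris)
#' are moved from `tissue` to `excluded`. A pixel counts as saturated at or
#' above `saturation_fraction` of the stack's saturation value; saturated
#' components smaller than `min_artefact_area` are ignored.
#'
#' @param stack A [channel_stack()].
#' @param tissue A `tissue_mask` from [detect_tissue()].
#' @param params A [segmentation_params()].
#' @return The updated `tissue_mask`.
#' @export
exclude_artefacts <- function(stack, tissue, params = segmentation_params()) {
  stopifnot(inherits(tissue, "tissue_mask"))
  satv <- params$saturation_fraction * stack$saturation_value
  nsat <- (get_channel(stack, "mask") >= satv) +
    (get_channel(stack, "primary") >= satv) +
    (get_channel(stack, "tertiary") >= satv)
  cand <- nsat >= 2
  if (any(cand)) {
    lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
    lab <- matrix(as.integer(lab), nrow = nrow(cand))
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * stack$pixel_size^2 >= params$min_artefact_area)
    excl <- matrix(lab %in% keep, nrow = nrow(cand))
  } else excl <- cand
  tissue$excluded <- tissue$excluded | excl
  tissue$tissue <- tissue$tissue & !tissue$excluded
  tissue$provenance <- c(tissue$provenance,
                         sprintf("excluded regions saturated in >=2 channels (>=%.0f%% full scale, >=%g um^2)",
                                 params$saturation_fraction * 100,
                                 params$min_artefact_area))
  tissue
}
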