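#' Segment individual myofibres from the laminin mask channel
#'
#' Stage 2 of the pipeline. The smoothed laminin channel is thresholded
#' within tissue (Otsu by default) to give the membrane band; enclosed
#' interiors are fibre seeds; seeds are grown across the band by
#' intensity-guided propagation (a seeded watershed on the laminin ridge),
#' which splits shared membrane between touching fibres along the ridge.
#' Candidates are then filtered: area window, solidity floor, mean
#' ring-thickness cap, and image-border contact (incomplete rings cannot
#' support circumference statistics). Every rejected candidate is recorded
#' with a reason.
#'
#' @param stack A [channel_stack()].
#' @param tissue A `tissue_mask` (after [exclude_artefacts()] if desired).
#' @param params A [segmentation_params()].
#' @return A `fibre_label_map` list: `labels` (integer matrix, 0 background,
#'   consecutive labels in raster order), `n_fibres`, `rejected` (data frame
#'   `candidate`, `reason`, `area_um2`), `band` (logical membrane-band
#'   matrix), `pixel_size`.
#' @export
segment_fibres <- function(stack, tissue, params = segmentation_params()) {
  stopifnot(inherits(stack, "channel_stack"), inherits(tissue, "tissue_mask"))
  ps <- stack$pixel_size
  if (!any(tissue$tissue)) {
    return(structure(list(labels = matrix(0L, nrow(tissue$tissue), ncol(tissue$tissue)),
                          n_fibres = 0L,
                          rejected = data.frame(candidate = integer(0),
                                                reason = character(0),
                                                area_um2 = numeric(0)),
                          band = tissue$tissue, pixel_size = ps),
                     class = "fibre_label_map"))
  }
  m <- get_channel(stack, "mask")
  sigma <- max(params$smooth_sigma_um / ps, 0.5)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(m / 65535), sigma = sigma))
  # the membrane band is thresholded on the raw channel: smoothing spreads
  # the band's skirts above threshold and would fatten the ring mask
  th <- if (params$mask_threshold_method == "otsu")
    otsu_threshold(m[tissue$tissue] / 65535) else params$fixed_threshold / 65535
  band <- m / 65535 > th & tissue$tissue

  interiors <- tissue$tissue & !band
  seeds <- EBImage::bwlabel(EBImage::Image(interiors * 1))
  seeds <- matrix(as.integer(seeds), nrow = nrow(m))
  # drop speck seeds (noise), far below any plausible fibre
  sizes <- tabulate(seeds[seeds > 0L])
  specks <- which(sizes * ps^2 < params$min_fibre_area / 10)
  if (length(specks)) seeds[seeds %in% specks] <- 0L
  seeds <- relabel_raster_order(seeds)
  if (max(seeds) == 0L) {
    return(structure(list(labels = matrix(0L, nrow(m), ncol(m)), n_fibres = 0L,
                          rejected = data.frame(candidate = integer(0),
                                                reason = character(0),
                                                area_um2 = numeric(0)),
                          band = band, pixel_size = ps),
                     class = "fibre_label_map"))
  }
  basins <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(seeds),
                               mask = tissue$tissue)
  basins <- matrix(as.integer(basins), nrow = nrow(m))
  # fibre candidate = its basin restricted to interior + membrane band
  cand <- basins
  cand[!(interiors | band)] <- 0L

  n_cand <- max(cand)
  keep <- integer(0)
  rej <- list()
  areas <- tabulate(cand[cand > 0L], nbins = n_cand)
  on_border <- unique(c(cand[1L, ], cand[nrow(cand), ], cand[, 1L], cand[, ncol(cand)]))
  for (k in seq_len(n_cand)) {
    a_um2 <- areas[k] * ps^2
    reason <- NULL
    if (areas[k] == 0L) next
    if (k %in% on_border) reason <- "border"
    else if (a_um2 < params$min_fibre_area || a_um2 > params$max_fibre_area) reason <- "area"
    else {
      coords <- which(cand == k, arr.ind = TRUE)
      if (pixel_solidity(coords) < params$min_solidity) reason <- "shape"
      else {
        ring_px <- sum(band[coords])
        if (ring_px > 0L) {
          # mean band thickness estimate: area / outer contour length
          sub <- matrix(FALSE, nrow(cand), ncol(cand))
          sub[coords] <- TRUE
          bb <- mask_bbox(sub, pad = 2L)
          crop <- sub[bb$r1:bb$r2, bb$c1:bb$c2]
          per <- contour_path_length(trace_contour(crop))
          t_est <- if (per > 0) ring_px / per * ps else Inf
          if (t_est > params$max_mean_ring_thickness) reason <- "ring-thickness"
        }
      }
    }
    if (is.null(reason)) keep <- c(keep, k)
    else rej[[length(rej) + 1L]] <- data.frame(candidate = k, reason = reason,
                                               area_um2 = a_um2)
  }
  labels <- cand
  labels[!(labels %in% keep)] <- 0L
  labels <- relabel_raster_order(labels)
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(candidate = integer(0), reason = character(0), area_um2 = numeric(0))
  structure(list(labels = labels, n_fibres = max(labels), rejected = rejected,
                 band = band, pixel_size = ps),
            class = "fibre_label_map")
}

#' Partition each fibre into sarcolemma ring and sarcoplasm
#'
#' For every labelled fibre, splits the fibre region into a sarcolemma ring
#' mask and a sarcoplasm mask, and traces the ring mid-line — the closed
#' pixel path equidistant between the ring's outer and inner edges — whose
#' corrected path length is the fibre circumference in pixels.
#'
#' In `"laminin-band"` mode the ring is the detected membrane band inside
#' the fibre region (largest connected band component; stray supra-threshold
#' specks in the interior stay in the sarcoplasm). In `"fixed-band"` mode
#' the ring is a band of `fixed_band_um` measured inward from the fibre
#' boundary.
#'
#' Fibres whose ring removal leaves no sarcoplasm are rejected with reason
#' `"ring-dominant"` and dropped from the partition.
#'
#' @param labels A `fibre_label_map` from [segment_fibres()].
#' @param stack A [channel_stack()].
#' @param params A [segmentation_params()].
#' @return A `sarcolemma_partition`: list with `fibres` (named list, one
#'   entry per retained label: `label`, `bbox`, cropped logical matrices
#'   `region`, `ring`, `sarcoplasm`, `midline` (n x 2 full-image (row, col)
#'   path), `circumference_px`, `centroid`), `dropped` (data frame of
#'   ring-dominant rejections), `pixel_size`.
#' @export
partition_fibres <- function(labels, stack, params = segmentation_params()) {
  stopifnot(inherits(labels, "fibre_label_map"))
  ps <- labels$pixel_size
  fibres <- list()
  dropped <- list()
  for (k in seq_len(labels$n_fibres)) {
    sel <- labels$labels == k
    bb <- mask_bbox(sel, pad = 2L)
    region <- sel[bb$r1:bb$r2, bb$c1:bb$c2]
    if (params$ring_mode == "laminin-band") {
      ring <- region & labels$band[bb$r1:bb$r2, bb$c1:bb$c2]
      if (any(ring)) {
        rl <- label_components8(ring)
        main <- which.max(tabulate(rl[rl > 0L]))
        ring <- rl == main
      }
    } else {
      dmap <- matrix(as.numeric(EBImage::distmap(EBImage::Image(region * 1))),
                     nrow = nrow(region))
      ring <- region & dmap <= params$fixed_band_um / ps
    }
    sarco <- region & !ring
    if (!any(sarco) || !any(ring)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(label = k, reason = "ring-dominant")
      next
    }
    # keep the largest sarcoplasm component as the interior; fragments
    # outside the membrane band (tissue halo beyond the laminin outer edge)
    # are dropped so the fibre boundary is the band's outer edge
    sl <- label_components8(sarco)
    sarco <- sl == which.max(tabulate(sl[sl > 0L]))
    if (params$ring_mode == "laminin-band") {
      ring <- ring & !sarco
      region <- sarco | ring
    } else {
      ring <- region & !sarco
    }

    d_out <- matrix(as.numeric(EBImage::distmap(EBImage::Image(region * 1))),
                    nrow = nrow(region))
    d_in <- matrix(as.numeric(EBImage::distmap(EBImage::Image((!sarco) * 1))),
                   nrow = nrow(region))
    midset <- sarco | (ring & d_out >= d_in)
    midset <- matrix(as.integer(EBImage::fillHull(EBImage::Image(midset * 1))) > 0L,
                     nrow = nrow(region))
    path <- trace_contour(midset)
    if (nrow(path) < 4L) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(label = k, reason = "ring-dominant")
      next
    }
    circ <- contour_path_length(path)
    if (circ < 8) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(label = k, reason = "ring-dominant")
      next
    }
    coords <- which(region, arr.ind = TRUE)
    centroid <- c(mean(coords[, 1L]) + bb$r1 - 1, mean(coords[, 2L]) + bb$c1 - 1)
    fibres[[as.character(k)]] <-
      list(label = k, bbox = bb, region = region, ring = ring,
           sarcoplasm = sarco,
           midline = cbind(path[, 1L] + bb$r1 - 1L, path[, 2L] + bb$c1 - 1L),
           circumference_px = circ, centroid = centroid)
  }
  structure(list(fibres = fibres,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else
                   data.frame(label = integer(0), reason = character(0)),
                 pixel_size = ps),
            class = "sarcolemma_partition")
}
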