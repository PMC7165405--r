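#' Quantification parameters
#'
#' @param k Multiplier for the per-fibre positivity threshold
#'   `mean + k * sd` of the fibre's own sarcoplasm pixels (default 3).
#' @param min_object_px Minimum positive-object size in pixels; smaller
#'   supra-threshold components are treated as noise (default 3).
#' @param coverage_estimator `"projection"` (mid-line projection arc length,
#'   the default) or `"literal"` (the border-length formula
#'   `sum((border - 2 * radial_width) / 2)`; see
#'   [circumference_positivity()]).
#' @param positivity_cutoff Coverage percentage above which a fibre is
#'   called protein positive (default 25).
#' @param min_sarcoplasm_px Minimum sarcoplasm pixel count for a reliable
#'   background estimate; below it the fibre is flagged unquantifiable
#'   (default 25).
#' @return A `quantification_params` list.
#' @export
quantification_params <- function(k = 3, min_object_px = 3L,
                                  coverage_estimator = c("projection", "literal"),
                                  positivity_cutoff = 25,
                                  min_sarcoplasm_px = 25L) {
  coverage_estimator <- match.arg(coverage_estimator)
  structure(list(k = k, min_object_px = as.integer(min_object_px),
                 coverage_estimator = coverage_estimator,
                 positivity_cutoff = positivity_cutoff,
                 min_sarcoplasm_px = as.integer(min_sarcoplasm_px)),
            class = "quantification_params")
}

#' Per-fibre positivity threshold from the fibre's own cytoplasm
#'
#' The threshold separating significant sarcolemmal staining from background
#' is computed for each fibre independently as `mean + k * sd` of that
#' fibre's sarcoplasm pixel intensities — the cytoplasm acts as the fibre's
#' own background reference, under the assumption that cytoplasmic and
#' sarcolemmal background levels are equal. No global threshold is used, so
#' the call adapts to staining heterogeneity across the section.
#'
#' @param sarcoplasm_values Numeric vector of sarcoplasm pixel intensities.
#' @param k Standard-deviation multiplier.
#' @param min_pixels Minimum number of pixels required.
#' @return Threshold in AU, or `NA` (with attribute
#'   `unquantifiable = TRUE`) when too few pixels are available.
#' @export
fibre_positive_threshold <- function(sarcoplasm_values, k = 3, min_pixels = 25L) {
  if (length(sarcoplasm_values) < min_pixels) {
    out <- NA_real_
    attr(out, "unquantifiable") <- TRUE
    return(out)
  }
  mean(sarcoplasm_values) + k * stats::sd(sarcoplasm_values)
}

#' Find positive staining objects on a fibre's sarcolemma ring
#'
#' Positive pixels are ring pixels whose intensity strictly exceeds the
#' fibre's threshold; objects are their 8-connected components, discarding
#' components below `min_object_px`. Each object's circumferential extent is
#' measured by projecting its pixels to their nearest ring mid-line vertices
#' and taking the covered fraction of the mid-line.
#'
#' @param fibre One fibre entry of a `sarcolemma_partition`.
#' @param channel Full-image intensity matrix.
#' @param threshold Positivity threshold (AU) from
#'   [fibre_positive_threshold()].
#' @param min_object_px Minimum object size in pixels.
#' @return List of positive objects; each is a list with `n_px`,
#'   `mean_intensity`, `border_length` (corrected contour length, px edge
#'   units), `radial_width` (mean across-ring width, px),
#'   `circumferential_extent` (px along the mid-line), `covered_vertices`
#'   (indices into the mid-line path).
#' @export
find_positive_objects <- function(fibre, channel, threshold, min_object_px = 3L) {
  if (is.na(threshold)) return(list())
  bb <- fibre$bbox
  img <- channel[bb$r1:bb$r2, bb$c1:bb$c2]
  pos <- fibre$ring & img > threshold
  if (!any(pos)) return(list())
  lab <- label_components8(pos)
  n_obj <- max(lab)
  ml_local <- cbind(fibre$midline[, 1L] - bb$r1 + 1L,
                    fibre$midline[, 2L] - bb$c1 + 1L)
  objs <- list()
  for (j in seq_len(n_obj)) {
    idx <- which(lab == j, arr.ind = TRUE)
    if (nrow(idx) < min_object_px) next
    # nearest mid-line vertex for each object pixel
    d2 <- outer(idx[, 1L], ml_local[, 1L], "-")^2 +
      outer(idx[, 2L], ml_local[, 2L], "-")^2
    covered <- unique(max.col(-d2, ties.method = "first"))
    extent <- covered_arc_length(covered, ml_local, fibre$circumference_px)
    objmask <- matrix(FALSE, nrow(img), ncol(img))
    objmask[idx] <- TRUE
    path <- trace_contour(objmask)
    border <- if (nrow(path) >= 3L) contour_path_length(path) else 2 * nrow(idx)
    # an annular object (full ring) also exposes an inner boundary
    filled <- matrix(as.integer(EBImage::fillHull(EBImage::Image(objmask * 1))) > 0L,
                     nrow = nrow(img))
    holes <- filled & !objmask
    if (any(holes)) {
      hl <- label_components8(holes)
      for (h in seq_len(max(hl))) {
        hp <- trace_contour(hl == h)
        if (nrow(hp) >= 3L) border <- border + contour_path_length(hp)
      }
    }
    rad_w <- if (extent > 0) nrow(idx) / extent else border / 4
    objs[[length(objs) + 1L]] <-
      list(n_px = nrow(idx),
           mean_intensity = mean(img[objmask]),
           border_length = border,
           radial_width = rad_w,
           circumferential_extent = extent,
           covered_vertices = covered,
           pixels = cbind(idx[, 1L] + bb$r1 - 1L, idx[, 2L] + bb$c1 - 1L))
  }
  objs
}

#' Circumference Positivity: percent of the sarcolemma covered by staining
#'
#' The coverage statistic: the fraction of a fibre's sarcolemmal
#' circumference covered by positive staining objects, as a percentage in
#' `[0, 100]`.
#'
#' Two estimators are provided. `"projection"` (default) projects object
#' pixels to their nearest mid-line vertices and measures the arc length of
#' the covered portion of the mid-line as a fraction of the circumference.
#' `"literal"` sums, over objects, half the
#' object's border length after subtracting its two radial end segments —
#' `(border_length - 2 * radial_width) / 2` — and divides by the ring
#' circumference; for a thin band-shaped object of arc length `s` and
#' thickness `t` the border is about `2s + 2t`, so the formula recovers `s`.
#' Both are deterministic and cross-validated against each other on
#' synthetic arcs.
#'
#' @param objects List of positive objects from [find_positive_objects()].
#' @param fibre The corresponding fibre entry of the partition.
#' @param estimator `"projection"` or `"literal"`.
#' @return Percentage in `[0, 100]`; 0 when there are no objects.
#' @export
circumference_positivity <- function(objects, fibre,
                                     estimator = c("projection", "literal")) {
  estimator <- match.arg(estimator)
  if (length(objects) == 0L) return(0)
  circ <- fibre$circumference_px
  if (estimator == "projection") {
    covered <- unique(unlist(lapply(objects, `[[`, "covered_vertices")))
    pct <- covered_arc_length(covered, fibre$midline, circ) / circ * 100
  } else {
    s <- sum(vapply(objects, function(o)
      (o$border_length - 2 * o$radial_width) / 2, numeric(1)))
    pct <- s / circ * 100
  }
  clamp(pct, 0, 100)
}

.COVERAGE_CLASSES <- c("0-25", "25-50", "50-75", "75-100")

#' Classify coverage into the four sarcolemmal coverage classes
#'
#' Bins: `[0, 25]` is class `"0-25"` (protein negative), `(25, 50]`,
#' `(50, 75]`, `(75, 100]` are the three positive classes. A fibre is
#' protein positive if and only if its coverage strictly exceeds the cutoff
#' (default 25%), so exactly 25.0% is negative.
#'
#' @param pct Numeric vector of coverage percentages in `[0, 100]`.
#' @param cutoff Positivity cutoff (default 25).
#' @return Data frame with `coverage_class` (factor with the four levels)
#'   and `is_positive` (logical).
#' @export
classify_coverage <- function(pct, cutoff = 25) {
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    stop("coverage percentage outside [0, 100]")
  cls <- cut(pct, breaks = c(0, 25, 50, 75, 100), labels = .COVERAGE_CLASSES,
             include.lowest = TRUE, right = TRUE)
  data.frame(coverage_class = cls, is_positive = !is.na(pct) & pct > cutoff)
}

#' Tertiary intensity in primary-positive vs primary-negative sarcolemma
#'
#' Splits the fibre's ring pixels into the primary-positive set (union of
#' primary positive objects) and the primary-negative remainder, and reports
#' the raw tertiary channel mean over each — a direct per-fibre measurement
#' of colocalisation of the tertiary sarcolemmal stain with the primary.
#' An empty set yields `NA` (flagged missing), never zero.
#'
#' @param fibre One fibre entry of a `sarcolemma_partition`.
#' @param primary_objects Positive objects of the primary channel.
#' @param tertiary Full-image tertiary channel matrix.
#' @return Named list `mean_in_pos`, `mean_in_neg` (AU or `NA`).
#' @export
colocalise_tertiary <- function(fibre, primary_objects, tertiary) {
  bb <- fibre$bbox
  img <- tertiary[bb$r1:bb$r2, bb$c1:bb$c2]
  posmask <- matrix(FALSE, nrow(img), ncol(img))
  for (o in primary_objects) {
    loc <- cbind(o$pixels[, 1L] - bb$r1 + 1L, o$pixels[, 2L] - bb$c1 + 1L)
    posmask[loc] <- TRUE
  }
  posmask <- posmask & fibre$ring
  negmask <- fibre$ring & !posmask
  list(mean_in_pos = if (any(posmask)) mean(img[posmask]) else NA_real_,
       mean_in_neg = if (any(negmask)) mean(img[negmask]) else NA_real_)
}

#' Measure the full per-fibre staining profile
#'
#' For every fibre: raw (unsubtracted) sarcolemma and sarcoplasm means for
#' all three channels; for the primary channel — and for the tertiary
#' channel when it is sarcolemmal — the per-fibre positivity threshold,
#' positive objects, Circumference Positivity, coverage class and positive
#' call; for a sarcolemmal tertiary, the colocalisation pair. Fibres with
#' too few sarcoplasm pixels are flagged unquantifiable: morphometrics and
#' raw means are kept but positivity fields are `NA`.
#'
#' @param partition A `sarcolemma_partition`.
#' @param stack A [channel_stack()].
#' @param params A [quantification_params()].
#' @return Data frame, one row per fibre, plus attribute `objects`: a list
#'   (per fibre label) of the primary channel's positive objects.
#' @export
measure_stain_profile <- function(partition, stack,
                                  params = quantification_params()) {
  stopifnot(inherits(partition, "sarcolemma_partition"),
            inherits(stack, "channel_stack"))
  chans <- list(mask = get_channel(stack, "mask"),
                primary = get_channel(stack, "primary"),
                tertiary = get_channel(stack, "tertiary"))
  tert_sarcolemmal <- stack$tertiary_kind == "sarcolemmal"
  all_objects <- list()
  rows <- lapply(partition$fibres, function(f) {
    bb <- f$bbox
    ring_i <- f$ring; sarco_i <- f$sarcoplasm
    vals <- lapply(chans, function(ch) {
      crop <- ch[bb$r1:bb$r2, bb$c1:bb$c2]
      list(ring = crop[ring_i], sarco = crop[sarco_i])
    })
    quantifiable <- length(vals$primary$sarco) >= params$min_sarcoplasm_px
    row <- data.frame(label = f$label,
                      quantifiable = quantifiable,
                      mask_sarcolemma_mean = mean(vals$mask$ring),
                      mask_sarcoplasm_mean = mean(vals$mask$sarco),
                      primary_sarcolemma_mean = mean(vals$primary$ring),
                      primary_sarcoplasm_mean = mean(vals$primary$sarco),
                      tertiary_sarcolemma_mean = mean(vals$tertiary$ring),
                      tertiary_sarcoplasm_mean = mean(vals$tertiary$sarco))
    quant_channel <- function(chname) {
      th <- fibre_positive_threshold(vals[[chname]]$sarco, k = params$k,
                                     min_pixels = params$min_sarcoplasm_px)
      objs <- find_positive_objects(f, chans[[chname]], th,
                                    min_object_px = params$min_object_px)
      cp <- if (is.na(th)) NA_real_ else
        circumference_positivity(objs, f, estimator = params$coverage_estimator)
      cc <- classify_coverage(cp, cutoff = params$positivity_cutoff)
      list(threshold = as.numeric(th), objects = objs, cp = cp,
           class = as.character(cc$coverage_class),
           positive = if (is.na(cp)) NA else cc$is_positive)
    }
    pq <- quant_channel("primary")
    all_objects[[as.character(f$label)]] <<- pq$objects
    row$primary_threshold <- pq$threshold
    row$primary_circumference_positivity <- pq$cp
    row$primary_coverage_class <- pq$class
    row$primary_is_positive <- pq$positive
    if (tert_sarcolemmal) {
      tq <- quant_channel("tertiary")
      row$tertiary_threshold <- tq$threshold
      row$tertiary_circumference_positivity <- tq$cp
      row$tertiary_coverage_class <- tq$class
      row$tertiary_is_positive <- tq$positive
      cl <- colocalise_tertiary(f, pq$objects, chans$tertiary)
      row$tertiary_mean_in_primary_pos <- cl$mean_in_pos
      row$tertiary_mean_in_primary_neg <- cl$mean_in_neg
    } else {
      row$tertiary_threshold <- NA_real_
      row$tertiary_circumference_positivity <- NA_real_
      row$tertiary_coverage_class <- NA_character_
      row$tertiary_is_positive <- NA
      row$tertiary_mean_in_primary_pos <- NA_real_
      row$tertiary_mean_in_primary_neg <- NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "objects") <- all_objects
  out
}
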