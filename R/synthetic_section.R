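#' Specification of a synthetic muscle section
#'
#' Defines the layout and staining of a simulated multiplexed
#' immunofluorescence section of transverse muscle: packed convex-polygonal
#' fibres with a bright laminin ring, a primary sarcolemmal arc of controlled
#' angular coverage (emulating dystrophin from trace to revertant), a tertiary
#' channel that is either sarcolemmal (DAP coupled to primary presence) or
#' sarcoplasmic (f/d myosin in a controlled fraction of fibres), additive
#' Gaussian noise, and optional injected artefacts.
#'
#' Defaults model a 20x-scan-like acquisition of a paediatric biopsy:
#' 0.5 um/px, fibre diameters 25-60 um, ring thickness 1.5-2.5 um,
#' cytoplasmic background 8000 AU (the weak-fluorescence floor), stain
#' intensities ~30000 AU in mid dynamic range, noise sd 500 AU.
#'
#' @param n_fibres Number of fibres to draw.
#' @param pixel_size Micrometres per pixel.
#' @param fibre_diameter_range Min/max fibre diameter (um).
#' @param ring_thickness_range Min/max laminin ring thickness (um).
#' @param mask_ring_intensity Laminin ring mean intensity (AU).
#' @param primary_arc_intensity Primary stain arc mean intensity (AU).
#' @param primary_coverage_fractions Per-fibre fraction of the ring
#'   circumference covered by the primary arc, in `[0,1]`. Recycled to
#'   `n_fibres`; `NULL` draws uniform fractions.
#' @param tertiary_mode `"sarcolemmal"` or `"sarcoplasmic"`.
#' @param tertiary_intensity_pos,tertiary_intensity_neg Tertiary means on
#'   primary-positive / primary-negative ring arcs (sarcolemmal mode), or the
#'   positive-fibre sarcoplasm mean (sarcoplasmic mode, `_pos` only; default
#'   4x background). `NULL` picks the mode default (24000/12000 sarcolemmal;
#'   4x background sarcoplasmic).
#' @param myosin_positive_fraction Fraction of fibres carrying sarcoplasmic
#'   tertiary signal (sarcoplasmic mode only).
#' @param sarcoplasm_background Background fluorescence mean (AU), applied to
#'   all channels off their stained compartments.
#' @param noise_sd Additive Gaussian noise sd (AU); clipped to `[0, 65535]`.
#' @param artefact_spec Optional list of artefacts; each element is a list
#'   with `type = "fold"` (full-canvas high-intensity streak saturating all
#'   channels; fields `width_um`, `intensity`) or `type = "debris"`
#'   (off-fibre blob; fields `diameter_um`, `intensity`).
#' @param canvas_size `NULL` to auto-size a jittered grid, or `c(H, W)` px.
#' @param seed Integer seed; identical specs give bit-identical sections.
#' @return A `section_spec` list.
#' @export
section_spec <- function(n_fibres = 100L,
                         pixel_size = 0.5,
                         fibre_diameter_range = c(25, 60),
                         ring_thickness_range = c(1.5, 2.5),
                         mask_ring_intensity = 30000,
                         primary_arc_intensity = 30000,
                         primary_coverage_fractions = NULL,
                         tertiary_mode = c("sarcolemmal", "sarcoplasmic"),
                         tertiary_intensity_pos = NULL,
                         tertiary_intensity_neg = NULL,
                         myosin_positive_fraction = 0,
                         sarcoplasm_background = 8000,
                         noise_sd = 500,
                         artefact_spec = list(),
                         canvas_size = NULL,
                         seed = 1L) {
  tertiary_mode <- match.arg(tertiary_mode)
  if (is.null(tertiary_intensity_pos))
    tertiary_intensity_pos <- if (tertiary_mode == "sarcolemmal") 24000 else
      4 * sarcoplasm_background
  if (is.null(tertiary_intensity_neg))
    tertiary_intensity_neg <- if (tertiary_mode == "sarcolemmal") 12000 else
      sarcoplasm_background
  ints <- c(mask_ring_intensity, primary_arc_intensity, tertiary_intensity_pos,
            tertiary_intensity_neg, sarcoplasm_background)
  if (any(ints < 0 | ints > 65535)) stop("intensities must lie in [0, 65535]")
  if (!is.null(primary_coverage_fractions)) {
    if (any(primary_coverage_fractions < 0 | primary_coverage_fractions > 1))
      stop("coverage fractions must lie in [0, 1]")
    primary_coverage_fractions <- rep_len(primary_coverage_fractions, n_fibres)
  }
  if (myosin_positive_fraction < 0 || myosin_positive_fraction > 1)
    stop("myosin_positive_fraction must lie in [0, 1]")
  if (diff(fibre_diameter_range) < 0 || diff(ring_thickness_range) < 0)
    stop("ranges must be (min, max)")
  structure(list(n_fibres = as.integer(n_fibres), pixel_size = pixel_size,
                 fibre_diameter_range = fibre_diameter_range,
                 ring_thickness_range = ring_thickness_range,
                 mask_ring_intensity = mask_ring_intensity,
                 primary_arc_intensity = primary_arc_intensity,
                 primary_coverage_fractions = primary_coverage_fractions,
                 tertiary_mode = tertiary_mode,
                 tertiary_intensity_pos = tertiary_intensity_pos,
                 tertiary_intensity_neg = tertiary_intensity_neg,
                 myosin_positive_fraction = myosin_positive_fraction,
                 sarcoplasm_background = sarcoplasm_background,
                 noise_sd = noise_sd, artefact_spec = artefact_spec,
                 canvas_size = canvas_size, seed = as.integer(seed)),
            class = "section_spec")
}

# Radius-vs-angle lookup (fine grid) for a convex polygon star-shaped about
# the origin: for each grid angle, the ray/edge intersection distance.
#' @noRd
polygon_radius_lut <- function(verts, n_theta = 2048L) {
  theta <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  ux <- cos(theta); uy <- sin(theta)
  r <- rep(Inf, n_theta)
  nv <- nrow(verts)
  for (i in seq_len(nv)) {
    p <- verts[i, ]; q <- verts[if (i == nv) 1L else i + 1L, ]
    d <- q - p
    den <- ux * d[2L] - uy * d[1L]
    ri <- (p[1L] * d[2L] - p[2L] * d[1L]) / den
    ti <- (p[1L] * uy - p[2L] * ux) / den
    ok <- is.finite(ri) & ri > 0 & ti >= -1e-9 & ti <= 1 + 1e-9
    r[ok] <- pmin(r[ok], ri[ok])
  }
  list(theta = theta, r = r)
}

# Draw one fibre outline: a convex polygon perturbed from a rotated ellipse,
# 8-16 vertices, max radius capped at r_cap. Vertices relative to centroid.
#' @noRd
random_fibre_polygon <- function(r_base, r_cap) {
  k <- sample(8:16, 1L)
  # jittered regular spacing keeps the centroid strictly inside the polygon
  ang <- sort(((seq_len(k) - 1) / k + stats::runif(k, 0, 0.6 / k)) * 2 * pi)
  q <- stats::runif(1, 0.75, 1)          # ellipse axis ratio
  phi <- stats::runif(1, 0, pi)
  re <- r_base * q / sqrt((q * cos(ang - phi))^2 + (sin(ang - phi))^2)
  rr <- re * (1 + stats::runif(k, -0.07, 0.07))
  rr <- pmin(rr, r_cap)
  v <- cbind(rr * cos(ang), rr * sin(ang))
  hull <- grDevices::chull(v[, 1L], v[, 2L])
  v[hull[length(hull):1], , drop = FALSE]  # counter-clockwise
}

#' Generate a synthetic section with exact ground truth
#'
#' Renders the three channels described by a [section_spec()] and returns
#' them together with a per-fibre ground-truth table and the true label
#' image. The primary channel carries, per fibre, one contiguous arc along
#' the laminin ring subtending exactly `true_coverage_fraction` of the ring
#' mid-line angle, starting at a uniform random angle.
#'
#' @param spec A [section_spec()].
#' @return A list of class `synthetic_section`:
#'   `stack` ([channel_stack()]), `truth` (data frame, one row per fibre:
#'   `label`, `centroid_y`, `centroid_x` (px), `true_coverage_fraction`,
#'   `true_primary_intensity`, `true_tertiary_pos_intensity`,
#'   `true_tertiary_neg_intensity`, `true_myosin_positive`,
#'   `ring_thickness_um`, `diameter_um`, and a `polygon` list-column of
#'   vertex matrices), `labels` (integer matrix, true fibre labels over
#'   ring+interior), `artefact_mask` (logical matrix).
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  withr::with_seed(spec$seed, .generate_section_impl(spec))
}

#' @noRd
.generate_section_impl <- function(spec) {
  ps <- spec$pixel_size
  n <- spec$n_fibres
  rmax_px <- spec$fibre_diameter_range[2L] / 2 / ps
  gap_px <- 6
  cell <- ceiling(2 * rmax_px + gap_px)
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  margin <- ceiling(rmax_px * 0.2) + 4L
  if (is.null(spec$canvas_size)) {
    H <- nrow_g * cell + 2L * margin
    W <- ncol_g * cell + 2L * margin
  } else {
    H <- spec$canvas_size[1L]; W <- spec$canvas_size[2L]
    cell_h <- (H - 2L * margin) / nrow_g
    cell_w <- (W - 2L * margin) / ncol_g
    cell <- floor(min(cell_h, cell_w))
  }

  bg <- spec$sarcoplasm_background
  ch_mask <- matrix(bg, H, W)
  ch_prim <- matrix(bg, H, W)
  ch_tert <- matrix(bg, H, W)
  labels <- matrix(0L, H, W)

  cov <- spec$primary_coverage_fractions
  if (is.null(cov)) cov <- stats::runif(n)
  myo <- rep(FALSE, n)
  if (spec$tertiary_mode == "sarcoplasmic" && spec$myosin_positive_fraction > 0) {
    n_pos <- round(spec$myosin_positive_fraction * n)
    myo[sample.int(n, n_pos)] <- TRUE
  }

  truth <- vector("list", n)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    gi <- (i - 1L) %/% ncol_g; gj <- (i - 1L) %% ncol_g
    d_um <- stats::runif(1, spec$fibre_diameter_range[1L], spec$fibre_diameter_range[2L])
    t_um <- stats::runif(1, spec$ring_thickness_range[1L], spec$ring_thickness_range[2L])
    r_base <- d_um / 2 / ps
    t_px <- max(t_um / ps, 2)
    r_cap <- (cell - gap_px) / 2
    if (r_cap < r_base * 0.6 || r_cap < 4)
      stop(sprintf("canvas too small to place fibre %d without overlap", i))
    poly <- random_fibre_polygon(min(r_base, r_cap), r_cap)
    lut <- polygon_radius_lut(poly)
    rmax_i <- max(lut$r[is.finite(lut$r)])
    slack <- cell / 2 - rmax_i - 1
    cy <- margin + gi * cell + cell / 2 + stats::runif(1, -slack, slack)
    cx <- margin + gj * cell + cell / 2 + stats::runif(1, -slack, slack)

    # render within the bounding box using the radial lookup
    r1 <- max(floor(cy - rmax_i) - 1L, 1L); r2 <- min(ceiling(cy + rmax_i) + 1L, H)
    c1 <- max(floor(cx - rmax_i) - 1L, 1L); c2 <- min(ceiling(cx + rmax_i) + 1L, W)
    yy <- r1:r2; xx <- c1:c2
    dy <- matrix(yy - cy, length(yy), length(xx))
    dx <- matrix(xx - cx, length(yy), length(xx), byrow = TRUE)
    dist <- sqrt(dy^2 + dx^2)
    ang <- atan2(dx, dy) %% (2 * pi)   # angle measured in (row, col) frame
    bin <- pmin(floor(ang / (2 * pi) * length(lut$r)) + 1L, length(lut$r))
    r_at <- matrix(lut$r[bin], length(yy), length(xx))
    inside <- dist <= r_at
    ring <- inside & dist > (r_at - t_px)
    sarco <- inside & !ring

    # paint the arc over an angular window sized so that it subtends
    # arc_f of the ring MID-LINE ARC LENGTH (the coverage statistic is a
    # proportion of circumference, not of subtended angle)
    arc_f <- cov[i]
    nb <- length(lut$r)
    rm <- pmax(lut$r - t_px / 2, 0.1)
    drm <- (rm[c(2:nb, 1L)] - rm[c(nb, 1:(nb - 1L))]) / (2 * (2 * pi / nb))
    dL <- sqrt(rm^2 + drm^2) * (2 * pi / nb)
    b0 <- sample.int(nb, 1L)
    if (arc_f >= 1) {
      cov_bins <- rep(TRUE, nb)
      arc_f_true <- 1
    } else if (arc_f <= 0) {
      cov_bins <- rep(FALSE, nb)
      arc_f_true <- 0
    } else {
      ord <- ((b0 - 1L) + 0:(nb - 1L)) %% nb + 1L
      cl <- cumsum(dL[ord])
      n_take <- max(findInterval(arc_f * sum(dL), cl) + 1L, 1L)
      cov_bins <- rep(FALSE, nb)
      cov_bins[ord[seq_len(min(n_take, nb))]] <- TRUE
      arc_f_true <- sum(dL[cov_bins]) / sum(dL)
    }
    arc <- ring & matrix(cov_bins[bin], length(yy), length(xx))

    mm <- ch_mask[yy, xx]; mm[ring] <- spec$mask_ring_intensity
    ch_mask[yy, xx] <- mm
    mm <- ch_prim[yy, xx]; mm[arc] <- spec$primary_arc_intensity
    ch_prim[yy, xx] <- mm
    if (spec$tertiary_mode == "sarcolemmal") {
      mm <- ch_tert[yy, xx]
      mm[ring & !arc] <- spec$tertiary_intensity_neg
      mm[arc] <- spec$tertiary_intensity_pos
      ch_tert[yy, xx] <- mm
    } else if (myo[i]) {
      mm <- ch_tert[yy, xx]; mm[sarco] <- spec$tertiary_intensity_pos
      ch_tert[yy, xx] <- mm
    }
    mm <- labels[yy, xx]; mm[inside] <- i
    labels[yy, xx] <- mm

    truth[[i]] <- data.frame(label = i, centroid_y = cy, centroid_x = cx,
                             true_coverage_fraction = arc_f_true,
                             true_primary_intensity = spec$primary_arc_intensity,
                             true_tertiary_pos_intensity = spec$tertiary_intensity_pos,
                             true_tertiary_neg_intensity = spec$tertiary_intensity_neg,
                             true_myosin_positive = myo[i],
                             ring_thickness_um = t_px * ps,
                             diameter_um = d_um)
    polys[[i]] <- sweep(poly, 2L, c(-cy, -cx))  # absolute (row, col) vertices
  }

  artefact_mask <- matrix(FALSE, H, W)
  for (a in spec$artefact_spec) {
    if (identical(a$type, "fold")) {
      w_px <- max((a$width_um %||% 4) / ps, 2)
      inten <- a$intensity %||% 65000
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(1, -0.25, 0.25) * min(H, W)
      nv <- c(cos(th), sin(th))
      rr <- matrix(seq_len(H) - H / 2, H, W)
      cc <- matrix(seq_len(W) - W / 2, H, W, byrow = TRUE)
      sel <- abs(rr * nv[1L] + cc * nv[2L] - off) <= w_px / 2
      ch_mask[sel] <- inten; ch_prim[sel] <- inten; ch_tert[sel] <- inten
      artefact_mask <- artefact_mask | sel
    } else if (identical(a$type, "debris")) {
      d_px <- max((a$diameter_um %||% 15) / ps, 3)
      inten <- a$intensity %||% 63000
      cy <- stats::runif(1, d_px, H - d_px); cx <- stats::runif(1, d_px, W - d_px)
      rr <- matrix(seq_len(H) - cy, H, W)
      cc <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
      sel <- rr^2 + cc^2 <= (d_px / 2)^2
      ch_mask[sel] <- inten; ch_prim[sel] <- inten; ch_tert[sel] <- inten
      artefact_mask <- artefact_mask | sel
    } else stop("unknown artefact type: ", a$type)
  }

  if (spec$noise_sd > 0) {
    npx <- H * W
    ch_mask <- ch_mask + stats::rnorm(npx, 0, spec$noise_sd)
    ch_prim <- ch_prim + stats::rnorm(npx, 0, spec$noise_sd)
    ch_tert <- ch_tert + stats::rnorm(npx, 0, spec$noise_sd)
  }
  cl <- function(m) matrix(clamp(round(m), 0, 65535), H, W)

  truth <- do.call(rbind, truth)
  truth$polygon <- polys
  structure(list(stack = channel_stack(cl(ch_mask), cl(ch_prim), cl(ch_tert),
                                       tertiary_kind = spec$tertiary_mode,
                                       pixel_size = ps),
                 truth = truth, labels = labels,
                 artefact_mask = artefact_mask, spec = spec),
            class = "synthetic_section")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate replicate negative-control sections
#'
#' Emulates serial sections of a healthy control stained for the
#' sarcoplasmic f/d myosin marker: replicate independent draws of the same
#' section specification (differing only by derived sub-seeds) in which no
#' fibre carries myosin signal above background. Used to derive the myosin
#' positivity threshold.
#'
#' @param spec A [section_spec()] with `tertiary_mode = "sarcoplasmic"` and
#'   `myosin_positive_fraction = 0`.
#' @param n_sections Number of replicate sections.
#' @return List of `synthetic_section` objects.
#' @export
generate_control_panel <- function(spec, n_sections) {
  stopifnot(inherits(spec, "section_spec"))
  if (spec$tertiary_mode != "sarcoplasmic")
    stop("control panel requires tertiary_mode = 'sarcoplasmic'")
  if (spec$myosin_positive_fraction != 0)
    stop("controls must be a negative baseline (myosin_positive_fraction = 0)")
  lapply(seq_len(n_sections), function(i) {
    s <- spec
    s$seed <- as.integer((spec$seed + 1000003 * i) %% .Machine$integer.max)
    generate_section(s)
  })
}

#' Write a synthetic section to disk
#'
#' Writes the channel stack as a multi-page 16-bit TIFF, the ground truth as
#' CSV (polygons serialised as `"y1 x1;y2 x2;..."`), and a label overlay PNG.
#'
#' @param section A `synthetic_section`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_section <- function(section, dir) {
  stopifnot(inherits(section, "synthetic_section"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_channel_stack(section$stack, file.path(dir, "section.tiff"))
  tr <- section$truth
  tr$polygon <- vapply(tr$polygon, function(p)
    paste(apply(round(p, 2), 1L, paste, collapse = " "), collapse = ";"), character(1))
  utils::write.csv(tr, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  lab <- section$labels
  pal <- grDevices::hcl.colors(max(max(lab), 1L), "Spectral")
  rgb <- col2rgb_array(lab, pal)
  png::writePNG(rgb, file.path(dir, "true_labels.png"))
  invisible(dir)
}

# integer label matrix -> H x W x 3 array in [0,1]; background black
#' @noRd
col2rgb_array <- function(lab, pal) {
  rgb <- array(0, dim = c(dim(lab), 3L))
  cols <- grDevices::col2rgb(pal) / 255
  sel <- lab > 0L
  for (k in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[sel] <- cols[k, lab[sel]]
    rgb[, , k] <- plane
  }
  rgb
}
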