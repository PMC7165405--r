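# Shared fixtures (generated once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) assign(key, maker(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 25-fibre default-noise section with graded coverages, plus its analysis
fixture_small <- function() cached_fixture("small", function() {
  spec <- section_spec(n_fibres = 25,
                       primary_coverage_fractions = seq(0, 1, length.out = 25),
                       seed = 42)
  sec <- generate_section(spec)
  list(spec = spec, sec = sec, an = analyse_section(sec$stack))
})

# noise-free near-circular section over the coverage grid (2 fibres per step)
fixture_noisefree_grid <- function() cached_fixture("nfgrid", function() {
  spec <- section_spec(n_fibres = 22,
                       primary_coverage_fractions = rep(seq(0, 1, 0.1), 2),
                       fibre_diameter_range = c(40, 60),
                       ring_thickness_range = c(1.5, 1.5),
                       noise_sd = 0, seed = 11)
  sec <- generate_section(spec)
  list(spec = spec, sec = sec, an = analyse_section(sec$stack))
})

# Brute-force coverage oracle, independent of the partition/mid-line code:
# sweep angular bins around the true centroid, flag a bin positive when any
# true ring pixel in it exceeds `threshold` in `img`, and weight bins by
# their mean ring radius (local arc length ~ r * dtheta).
sweep_coverage_oracle <- function(sec, fibre, img, threshold, n_bins = 256L) {
  mask_ch <- get_channel(sec$stack, "mask")
  ring_th <- (sec$spec$mask_ring_intensity + sec$spec$sarcoplasm_background) / 2
  sel <- sec$labels == fibre & mask_ch > ring_th
  rp <- which(sel, arr.ind = TRUE)
  if (nrow(rp) == 0L) return(NA_real_)
  cy <- sec$truth$centroid_y[fibre]; cx <- sec$truth$centroid_x[fibre]
  ang <- atan2(rp[, 2L] - cx, rp[, 1L] - cy) %% (2 * pi)
  rr <- sqrt((rp[, 1L] - cy)^2 + (rp[, 2L] - cx)^2)
  b <- floor(ang / (2 * pi) * n_bins) + 1L
  rbar <- tapply(rr, b, mean)
  posbin <- tapply(img[sel] > threshold, b, any)
  sum(rbar[posbin %in% TRUE]) / sum(rbar) * 100
}

# Analytic annulus-arc area of a fibre from its truth polygon: numerical
# polar integral 0.5 * int( r^2 - max(r - t, 0)^2 ) dtheta with the radius
# found by fresh ray/segment intersection (independent of package internals).
analytic_ring_area_px <- function(poly_abs, centroid, t_px, n_theta = 4096L) {
  v <- sweep(poly_abs, 2L, centroid)          # vertices relative to centroid
  theta <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  r <- rep(NA_real_, n_theta)
  nv <- nrow(v)
  A <- cbind(cos(theta), sin(theta))
  for (i in seq_len(nv)) {
    p <- v[i, ]; q <- v[if (i == nv) 1L else i + 1L, ]
    # solve r*u - s*(q-p) = p for each theta via 2x2 determinants
    d <- q - p
    den <- A[, 1L] * d[2L] - A[, 2L] * d[1L]
    ri <- (p[1L] * d[2L] - p[2L] * d[1L]) / den
    si <- (p[1L] * A[, 2L] - p[2L] * A[, 1L]) / den
    ok <- is.finite(ri) & ri > 0 & si >= -1e-9 & si <= 1 + 1e-9
    r[ok] <- pmin(r[ok], ri[ok], na.rm = TRUE)
  }
  inner <- pmax(r - t_px, 0)
  sum(0.5 * (r^2 - inner^2) * (2 * pi / n_theta))
}

# Hand-built circular fibre: one circle of radius r_px with a band of
# band_px painted inward from the boundary; arcs list gives angular windows
# (start, end in radians) painted in the primary channel.
make_circle_stack <- function(r_px = 40, band_px = 3, size = 2 * r_px + 21,
                              arcs = list(), bg = 8000, ring_int = 30000,
                              arc_int = 30000, pixel_size = 0.5) {
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size) - ctr, size, size)
  cc <- matrix(seq_len(size) - ctr, size, size, byrow = TRUE)
  dist <- sqrt(rr^2 + cc^2)
  ang <- atan2(cc, rr) %% (2 * pi)
  ring <- dist <= r_px & dist > r_px - band_px
  mask <- matrix(bg, size, size); mask[ring] <- ring_int
  prim <- matrix(bg, size, size)
  for (a in arcs) {
    span <- a[2L] - a[1L]
    w <- if (span >= 2 * pi) ring else
      (ang - a[1L]) %% (2 * pi) <= span %% (2 * pi)
    prim[ring & w] <- arc_int
  }
  tert <- matrix(bg, size, size)
  channel_stack(mask, prim, tert, tertiary_kind = "sarcolemmal",
                pixel_size = pixel_size)
}

# Match analysed records to truth rows; returns truth with matched record idx
match_records <- function(an, sec) {
  mm <- match_labels(an$labels, sec$labels)
  mm$rec_idx <- match(mm$matched_label, an$records$label)
  mm
}
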