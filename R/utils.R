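# Internal geometry and labelling helpers shared across the pipeline.

# Chain-code step weights for digital perimeter estimation (Kulpa correction):
# axis-parallel steps count 0.948, diagonal steps 1.340. On smooth convex
# shapes this estimator is accurate to ~1%, whereas naive 1/sqrt(2) step
# counting overestimates perimeters by up to 8%.
.KULPA_STRAIGHT <- 0.948
.KULPA_DIAGONAL <- 1.340

#' @noRd
contour_path_length <- function(path, closed = TRUE) {
  n <- nrow(path)
  if (n < 2L) return(0)
  idx2 <- if (closed) c(2:n, 1L) else 2:n
  idx1 <- if (closed) 1:n else 1:(n - 1L)
  d1 <- abs(path[idx2, 1L] - path[idx1, 1L])
  d2 <- abs(path[idx2, 2L] - path[idx1, 2L])
  diag <- d1 > 0 & d2 > 0
  straight <- xor(d1 > 0, d2 > 0)
  # non-adjacent jumps (contour artefacts) fall back to euclidean length
  jump <- (d1 > 1) | (d2 > 1)
  w <- ifelse(jump, sqrt(d1^2 + d2^2),
              ifelse(diag, .KULPA_DIAGONAL, ifelse(straight, .KULPA_STRAIGHT, 0)))
  sum(w)
}

# Ordered outer contour of the largest object in a binary matrix.
# Returns an n x 2 matrix of 1-based (row, col) pixel coordinates.
#' @noRd
trace_contour <- function(mask) {
  img <- EBImage::Image(mask * 1)
  oc <- EBImage::ocontour(img)
  if (length(oc) == 0L) return(matrix(numeric(0), ncol = 2L))
  best <- which.max(vapply(oc, nrow, integer(1)))
  p <- oc[[best]]
  # ocontour is 0-based in (dim1, dim2) order; our matrices are (row, col)
  cbind(p[, 1L] + 1L, p[, 2L] + 1L)
}

# Connected-component labelling with 8-connectivity, built on the 4-connected
# EBImage::bwlabel by merging labels that touch diagonally. Deterministic:
# components are relabelled 1..n in raster order of their first pixel.
#' @noRd
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nl <- max(lab)
  if (nl > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour pairs (down-right and down-left shifts)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    parent <- seq_len(nl)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    if (nrow(pairs) > 0L) {
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    root <- vapply(seq_len(nl), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel_raster_order(lab)
}

# Relabel positive integer labels to consecutive 1..n by raster order of
# first occurrence (column-major, matching R matrix storage).
#' @noRd
relabel_raster_order <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u) == 0L) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# Otsu threshold on a raw vector of pixel values (maximises between-class
# variance over a binned histogram). Used so thresholding can be restricted
# to pixels inside the tissue mask.
#' @noRd
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) < 2L || diff(range(v)) == 0) return(max(v, 0))
  h <- hist(v, breaks = seq(min(v), max(v), length.out = n_bins + 1L), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Minimum caliper (Feret) diameter of a pixel set, in pixel units.
# Rotating calipers over the convex hull of pixel centres, plus one pixel of
# extent so that an axis-aligned square of side n pixels measures n.
#' @noRd
min_feret_px <- function(coords) {
  if (nrow(coords) == 0L) return(NA_real_)
  if (nrow(coords) == 1L) return(1)
  hull <- grDevices::chull(coords[, 1L], coords[, 2L])
  hp <- coords[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m == 2L) return(1)  # collinear set: width one pixel
  widths <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2L], e[1L]) / len
    proj <- coords[, 1L] * nrm[1L] + coords[, 2L] * nrm[2L]
    max(proj) - min(proj)
  }, numeric(1))
  min(widths) + 1
}

# Shoelace area of a polygon given as an n x 2 vertex matrix.
#' @noRd
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L])) / 2
}

# Solidity of a pixel set: area / convex hull area, with a half-perimeter
# correction for the hull of pixel centres so compact digital shapes score ~1.
#' @noRd
pixel_solidity <- function(coords) {
  npx <- nrow(coords)
  if (npx < 3L) return(1)
  hull <- grDevices::chull(coords[, 1L], coords[, 2L])
  hp <- coords[hull, , drop = FALSE]
  ha <- polygon_area(hp)
  per <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1L), , drop = FALSE])^2)))
  min(npx / (ha + per / 2 + 1), 1)
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Arc length of the covered portion of a closed contour path: full weight for
# steps with both endpoints covered, half weight where coverage starts/ends.
# covered_idx indexes rows of path; returns length in (corrected) px.
#' @noRd
covered_arc_length <- function(covered_idx, path, circumference) {
  n <- nrow(path)
  cov <- rep(FALSE, n)
  cov[covered_idx] <- TRUE
  if (all(cov)) return(circumference)
  if (!any(cov)) return(0)
  i2 <- c(2:n, 1L)
  d1 <- abs(path[i2, 1L] - path[, 1L]); d2 <- abs(path[i2, 2L] - path[, 2L])
  s <- ifelse(d1 > 0 & d2 > 0, .KULPA_DIAGONAL,
              ifelse(d1 > 0 | d2 > 0, .KULPA_STRAIGHT, 0))
  b <- cov[i2]
  min(sum(s[cov & b]) + 0.5 * sum(s[xor(cov, b)]), circumference)
}

# Bounding box of TRUE pixels, padded and clipped to the matrix extent.
#' @noRd
mask_bbox <- function(mask, pad = 1L) {
  w <- which(mask, arr.ind = TRUE)
  list(r1 = max(min(w[, 1L]) - pad, 1L), r2 = min(max(w[, 1L]) + pad, nrow(mask)),
       c1 = max(min(w[, 2L]) - pad, 1L), c2 = min(max(w[, 2L]) + pad, ncol(mask)))
}
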