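#' Multichannel immunofluorescence image with channel roles
#'
#' A `channel_stack` bundles three co-registered 16-bit fluorescence channels
#' with the metadata the pipeline needs: which channel is the membrane
#' *mask* stain (laminin alpha-2), which is the *primary* sarcolemmal stain
#' (dystrophin), and which is the *tertiary* stain — either a second
#' sarcolemmal marker (alpha-sarcoglycan / beta-dystroglycan) or a
#' sarcoplasmic regeneration marker (fetal/developmental myosin).
#'
#' Pixels are stored as numeric `H x W` matrices indexed `[row, col]`
#' (1-based); intensities are arbitrary units (AU) on the 16-bit scale
#' `[0, 65535]`.
#'
#' @param mask,primary,tertiary Numeric matrices of identical dimensions.
#' @param tertiary_kind `"sarcolemmal"` or `"sarcoplasmic"`.
#' @param pixel_size Pixel pitch in micrometres per pixel.
#' @param saturation_value Full-scale intensity (default 65535).
#' @return An object of class `channel_stack` with elements `pixels`
#'   (H x W x 3 array), `channel_roles`, `tertiary_kind`, `pixel_size`,
#'   `saturation_value`.
#' @export
channel_stack <- function(mask, primary, tertiary,
                          tertiary_kind = c("sarcolemmal", "sarcoplasmic"),
                          pixel_size = 0.5, saturation_value = 65535) {
  tertiary_kind <- match.arg(tertiary_kind)
  dims <- dim(mask)
  if (!identical(dims, dim(primary)) || !identical(dims, dim(tertiary)))
    stop("channel dimensions differ")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  px <- array(0, dim = c(dims, 3L))
  px[, , 1L] <- mask; px[, , 2L] <- primary; px[, , 3L] <- tertiary
  if (min(px) < 0 || max(px) > saturation_value)
    stop("pixel intensities outside [0, saturation_value]")
  structure(list(pixels = px,
                 channel_roles = c(mask = 1L, primary = 2L, tertiary = 3L),
                 tertiary_kind = tertiary_kind,
                 pixel_size = pixel_size,
                 saturation_value = saturation_value),
            class = "channel_stack")
}

#' Extract one channel of a stack by role
#'
#' @param stack A [channel_stack()].
#' @param role One of `"mask"`, `"primary"`, `"tertiary"`.
#' @return The channel as an `H x W` numeric matrix.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "channel_stack"))
  idx <- stack$channel_roles[[role]]
  stack$pixels[, , idx]
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("channel_stack: %d x %d px, 3 channels (tertiary: %s), %.3f um/px\n",
              d[1L], d[2L], x$tertiary_kind, x$pixel_size))
  invisible(x)
}

#' Channel-role configuration for reading image files
#'
#' Maps TIFF page indices to the three channel roles. Page indices are
#' 1-based. In acquisition terms the default corresponds to page order
#' 488 (primary), 568 (mask), 647 (tertiary).
#'
#' @param mask,primary,tertiary 1-based page indices.
#' @param tertiary_kind `"sarcolemmal"` or `"sarcoplasmic"`.
#' @param pixel_size Micrometres per pixel; if `NA` a default of 0.325
#'   (typical 20x scan) is used with a warning when the file carries no
#'   resolution metadata.
#' @return A `channel_config` list.
#' @export
channel_config <- function(mask = 2L, primary = 1L, tertiary = 3L,
                           tertiary_kind = c("sarcolemmal", "sarcoplasmic"),
                           pixel_size = NA_real_) {
  tertiary_kind <- match.arg(tertiary_kind)
  idx <- c(mask = as.integer(mask), primary = as.integer(primary),
           tertiary = as.integer(tertiary))
  if (anyDuplicated(idx)) stop("channel page indices must be distinct")
  if (any(idx < 1L)) stop("channel page indices must be >= 1")
  structure(list(pages = idx, tertiary_kind = tertiary_kind,
                 pixel_size = pixel_size),
            class = "channel_config")
}

.DEFAULT_PIXEL_SIZE <- 0.325

#' Read a multichannel TIFF into a channel stack
#'
#' Reads a multi-page (or single-page-per-file) TIFF / OME-TIFF and binds
#' pages to channel roles according to `config`. 8-bit input is promoted to
#' the 16-bit scale by left shift (x257) with a warning.
#'
#' @param path Path to a TIFF file with at least as many pages as the
#'   largest configured index.
#' @param config A [channel_config()].
#' @param max_pixels Guard against accidental whole-slide-scale input: images
#'   with more pixels per page are rejected with guidance to tile upstream.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(path, config = channel_config(),
                               max_pixels = 3e7) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (role in names(config$pages)) {
    if (config$pages[[role]] > length(pages))
      stop(sprintf("config assigns role '%s' to page %d but file has %d page(s)",
                   role, config$pages[[role]], length(pages)))
  }
  pick <- function(role) {
    p <- pages[[config$pages[[role]]]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first sample of RGB page
    storage.mode(p) <- "double"
    p
  }
  chans <- lapply(c("mask", "primary", "tertiary"), pick)
  dims <- lapply(chans, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("configured pages have mismatched shapes")
  if (prod(dims[[1L]]) > max_pixels)
    stop("image exceeds max_pixels; tile whole-slide input before analysis")
  if (max(unlist(lapply(chans, max))) <= 255) {
    warning("8-bit input promoted to 16-bit scale (x257)")
    chans <- lapply(chans, function(m) m * 257)
  }
  ps <- config$pixel_size
  if (is.na(ps)) {
    warning(sprintf("no pixel size configured; assuming %.3f um/px",
                    .DEFAULT_PIXEL_SIZE))
    ps <- .DEFAULT_PIXEL_SIZE
  }
  channel_stack(chans[[1L]], chans[[2L]], chans[[3L]],
                tertiary_kind = config$tertiary_kind, pixel_size = ps)
}

#' Write a channel stack as a multi-page 16-bit TIFF
#'
#' One page per channel in acquisition wavelength order 488, 568, 647 —
#' i.e. primary, mask, tertiary — matching the default [channel_config()].
#' Pixel values are rounded to integers; the round trip through
#' [read_channel_stack()] with the default config is bit-identical.
#'
#' @param stack A [channel_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  pages <- lapply(c("primary", "mask", "tertiary"), function(r)
    round(get_channel(stack, r)) / 65535)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (ok != 3L) stop("failed to write TIFF: ", path)
  invisible(path)
}
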