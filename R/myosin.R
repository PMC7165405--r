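#' Derive the f/d myosin positivity threshold from negative controls
#'
#' Regenerating fibres are identified by sarcoplasmic fetal/developmental
#' myosin intensity above a threshold derived from control sections in which
#' the protein is absent (a negative baseline). The threshold is computed
#' from the distribution of per-fibre sarcoplasm tertiary means across
#' control fibres, either as a high percentile (default 99.5, robust to
#' occasional outlier control fibres) or as `mean + k * sd` (default k = 5).
#'
#' @param control_profiles Data frame(s) of control fibre profiles from
#'   [measure_stain_profile()] (a single data frame or a list of them),
#'   measured on sections with a sarcoplasmic tertiary channel.
#' @param method `"percentile"` or `"mean_plus_ksd"`.
#' @param param Percentile (default 99.5) or k (default 5) accordingly.
#' @param provenance Optional character vector of control section ids.
#' @return A `myosin_threshold` list: `value` (AU), `method`, `param`,
#'   `n_control_fibres`, `provenance`.
#' @export
derive_myosin_threshold <- function(control_profiles,
                                    method = c("percentile", "mean_plus_ksd"),
                                    param = NULL, provenance = character(0)) {
  method <- match.arg(method)
  if (is.null(param)) param <- if (method == "percentile") 99.5 else 5
  if (is.data.frame(control_profiles)) control_profiles <- list(control_profiles)
  means <- unlist(lapply(control_profiles, function(p)
    p$tertiary_sarcoplasm_mean[p$quantifiable]))
  means <- means[is.finite(means)]
  if (length(means) < 50L)
    stop("need at least 50 quantifiable control fibres (got ", length(means), ")")
  value <- if (method == "percentile")
    as.numeric(stats::quantile(means, param / 100, type = 7)) else
      mean(means) + param * stats::sd(means)
  structure(list(value = value, method = method, param = param,
                 n_control_fibres = length(means), provenance = provenance),
            class = "myosin_threshold")
}

#' Classify fibres as f/d myosin positive
#'
#' A fibre is positive if and only if its average sarcoplasmic tertiary
#' intensity strictly exceeds the control-derived threshold; a mean exactly
#' at the threshold is negative. Fibres with a missing sarcoplasm mean are
#' returned as `NA` (unquantifiable).
#'
#' @param profiles Data frame from [measure_stain_profile()] on a section
#'   with a sarcoplasmic tertiary channel.
#' @param threshold A `myosin_threshold` from [derive_myosin_threshold()].
#' @return Logical vector, one element per fibre row.
#' @export
classify_myosin <- function(profiles, threshold) {
  stopifnot(inherits(threshold, "myosin_threshold"))
  m <- profiles$tertiary_sarcoplasm_mean
  out <- m > threshold$value
  out[!is.finite(m) | !profiles$quantifiable] <- NA
  out
}

#' Persist / load a myosin threshold as JSON
#'
#' @param threshold A `myosin_threshold`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_myosin_threshold()` returns the object.
#' @export
write_myosin_threshold <- function(threshold, path) {
  stopifnot(inherits(threshold, "myosin_threshold"))
  jsonlite::write_json(unclass(threshold), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_myosin_threshold
#' @export
read_myosin_threshold <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(value = x$value, method = x$method, param = x$param,
                 n_control_fibres = x$n_control_fibres,
                 provenance = x$provenance %||% character(0)),
            class = "myosin_threshold")
}
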