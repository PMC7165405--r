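#' Aggregate per-fibre records into a section-level summary
#'
#' Section endpoints over the quantifiable analysed fibres: percent
#' protein-positive fibres, mean sarcolemmal intensity (unweighted mean over
#' fibres of the per-fibre raw ring means, so large fibres do not dominate),
#' four-class coverage histogram, cumulative-frequency tables for intensity
#' and coverage at one-percentile resolution, section colocalisation means,
#' and percent myosin-positive fibres where a myosin call is present.
#' Missing colocalisation values are excluded from their means, never
#' counted as zero. Denominators are the quantifiable analysed fibres;
#' rejected and unquantifiable counts are reported alongside.
#'
#' @param records Per-fibre data frame (typically the `records` element of
#'   [analyse_section()], or [measure_stain_profile()] output).
#' @param n_rejected Count of segmentation-rejected candidates to carry
#'   into the report.
#' @param positivity_cutoff Coverage percent above which a fibre counts as
#'   positive (default 25).
#' @return A `section_summary` list.
#' @export
summarise_section <- function(records, n_rejected = 0L, positivity_cutoff = 25) {
  q <- records[records$quantifiable & is.finite(records$primary_circumference_positivity), ]
  if (nrow(q) == 0L) stop("no quantifiable fibres")
  cp <- q$primary_circumference_positivity
  cls <- classify_coverage(cp, cutoff = positivity_cutoff)$coverage_class
  class_counts <- table(factor(cls, levels = .COVERAGE_CLASSES))
  cumfreq <- function(v, grid) {
    vapply(grid, function(g) mean(v <= g) * 100, numeric(1))
  }
  int_grid <- as.numeric(stats::quantile(q$primary_sarcolemma_mean,
                                         probs = seq(0, 1, 0.01), type = 7))
  cov_grid <- 0:100
  coloc_pos <- records$tertiary_mean_in_primary_pos
  coloc_neg <- records$tertiary_mean_in_primary_neg
  has_myosin <- "myosin_positive" %in% names(records)
  structure(list(
    n_fibres_analysed = nrow(q),
    n_unquantifiable = sum(!records$quantifiable |
                             !is.finite(records$primary_circumference_positivity)),
    n_rejected = n_rejected,
    pct_positive = mean(cp > positivity_cutoff) * 100,
    mean_sarcolemma_intensity = mean(q$primary_sarcolemma_mean),
    tertiary_pct_positive = if (all(is.na(q$tertiary_circumference_positivity)))
      NA_real_ else
        mean(q$tertiary_circumference_positivity > positivity_cutoff, na.rm = TRUE) * 100,
    tertiary_mean_sarcolemma_intensity = if (all(is.na(q$tertiary_sarcolemma_mean)))
      NA_real_ else mean(q$tertiary_sarcolemma_mean, na.rm = TRUE),
    class_counts = as.integer(class_counts),
    class_labels = .COVERAGE_CLASSES,
    cumulative_frequency_intensity = data.frame(intensity = int_grid,
                                                pct_fibres_le = seq(0, 100, 1)),
    cumulative_frequency_coverage = data.frame(coverage_pct = cov_grid,
                                               pct_fibres_le = cumfreq(cp, cov_grid)),
    colocalisation_mean_in_pos = if (all(is.na(coloc_pos))) NA_real_ else
      mean(coloc_pos, na.rm = TRUE),
    colocalisation_mean_in_neg = if (all(is.na(coloc_neg))) NA_real_ else
      mean(coloc_neg, na.rm = TRUE),
    pct_myosin_positive = if (has_myosin && any(!is.na(records$myosin_positive)))
      mean(records$myosin_positive, na.rm = TRUE) * 100 else NA_real_,
    positivity_cutoff = positivity_cutoff),
    class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("section_summary: %d fibres analysed (%d unquantifiable, %d rejected)\n",
              x$n_fibres_analysed, x$n_unquantifiable, x$n_rejected))
  cat(sprintf("  %% positive (> %g%% coverage): %.1f\n", x$positivity_cutoff,
              x$pct_positive))
  cat(sprintf("  mean sarcolemmal intensity: %.0f AU\n", x$mean_sarcolemma_intensity))
  cat(sprintf("  coverage classes (%s): %s\n", paste(x$class_labels, collapse = "/"),
              paste(x$class_counts, collapse = "/")))
  if (!is.na(x$pct_myosin_positive))
    cat(sprintf("  %% f/d myosin positive: %.1f\n", x$pct_myosin_positive))
  invisible(x)
}

#' Compare replicate section summaries
#'
#' Reproducibility report over replicate sections of the same sample: for
#' each numeric endpoint, the minimum, maximum, mean, and percent
#' variability `(max - min) / mean * 100`.
#'
#' @param summaries List of at least two `section_summary` objects.
#' @return Data frame with one row per endpoint: `endpoint`, `n`, `min`,
#'   `max`, `mean`, `pct_variability`.
#' @export
compare_replicates <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 summaries")
  stopifnot(all(vapply(summaries, inherits, logical(1), "section_summary")))
  endpoints <- c("pct_positive", "mean_sarcolemma_intensity",
                 "tertiary_pct_positive", "tertiary_mean_sarcolemma_intensity",
                 "colocalisation_mean_in_pos", "colocalisation_mean_in_neg",
                 "pct_myosin_positive")
  rows <- lapply(endpoints, function(e) {
    v <- vapply(summaries, function(s) s[[e]] %||% NA_real_, numeric(1))
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NULL)
    data.frame(endpoint = e, n = length(v), min = min(v), max = max(v),
               mean = mean(v),
               pct_variability = if (mean(v) == 0) 0 else
                 (max(v) - min(v)) / mean(v) * 100)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
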