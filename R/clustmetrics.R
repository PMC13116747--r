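# Per-read clustering statistics from long-read hit sets: copy number,
# total span (interval union) and coverage per read, summarized per family
# as MCNPR, MTSPR and MCOPR, with the 10 kb MTSPR clustering threshold.

#' Per-read satDNA statistics
#'
#' From the (non-redundant) hits of one family on one read: the copy
#' number (hit count), the total span (bases covered by the union of hit
#' intervals) and the coverage fraction of the read.
#'
#' @param hits hit data frame for a single read (subject coordinates on
#'   the read); collapsed again defensively with the >50%-overlap rule.
#' @param read_length read length in bp (> 0).
#' @return data frame row: copy_number, total_span, coverage_fraction.
#' @export
per_read_stats <- function(hits, read_length) {
  if (read_length <= 0) stop("read_length must be positive")
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(copy_number = 0L, total_span = 0L,
                      coverage_fraction = 0))
  # copy number counts non-redundant hits; the span covers every reported
  # base, so it is taken over the hits as given
  span <- interval_union_length(hits$s_start, hits$s_end)
  data.frame(copy_number = nrow(collapse_hits(hits)), total_span = span,
             coverage_fraction = span / read_length)
}

#' Family clustering metrics: MCNPR, MTSPR, MCOPR
#'
#' Maxima over reads of the per-read copy number (MCNPR), total span in bp
#' (MTSPR) and read coverage as a percentage (MCOPR). The three maxima are
#' taken independently and may come from different reads.
#'
#' @param hits hit data frame from [long_read_hits()] (columns `read`,
#'   `read_length`, subject coordinates on each read).
#' @param family family name recorded in the output.
#' @param threshold_bp MTSPR clustering threshold (default 10,000 bp).
#' @return one-row data frame: family, mcnpr, mtspr, mcopr, clustered.
#' @export
family_metrics <- function(hits, family = "family", threshold_bp = 10000) {
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(family = family, mcnpr = 0L, mtspr = 0L, mcopr = 0,
                      clustered = FALSE, stringsAsFactors = FALSE))
  per_read <- lapply(split(hits, hits$read), function(h)
    per_read_stats(h, h$read_length[1]))
  pr <- do.call(rbind, per_read)
  data.frame(family = family,
             mcnpr = max(pr$copy_number),
             mtspr = max(pr$total_span),
             mcopr = 100 * max(pr$coverage_fraction),
             clustered = classify_clustered(max(pr$total_span),
                                            threshold_bp),
             stringsAsFactors = FALSE)
}

#' Classify a family as genomically clustered
#'
#' A family is clustered when its maximum total span per read strictly
#' exceeds the threshold (default 10 kb); a span of exactly the threshold
#' is not clustered.
#'
#' @param mtspr maximum total span per read, bp.
#' @param threshold_bp clustering threshold in bp.
#' @return logical (vectorized).
#' @export
classify_clustered <- function(mtspr, threshold_bp = 10000) {
  mtspr > threshold_bp
}

#' Per-read statistics table for a family
#'
#' @param hits hit data frame from [long_read_hits()].
#' @return data frame: read, read_length, copy_number, total_span,
#'   coverage_fraction.
#' @export
per_read_stats_table <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(read = character(), read_length = integer(),
                      copy_number = integer(), total_span = integer(),
                      coverage_fraction = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(hits, hits$read), function(h) {
    cbind(data.frame(read = h$read[1], read_length = h$read_length[1],
                     stringsAsFactors = FALSE),
          per_read_stats(h, h$read_length[1]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
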