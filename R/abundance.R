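# Abundance and copy-number estimation: short-read mapping, the 2C
# copy-number formula and its inverse, long-read hit counting, copy-number
# cross-validation (CNCV) and the geometric-mean adjusted copy number.

#' Genome constants for copy-number normalization
#'
#' @param two_c_size diploid (2C) genome size in bp.
#' @param species_prefix two-letter species code used in family names.
#' @return an object of class `"genome_constants"`.
#' @export
genome_constants <- function(two_c_size, species_prefix = "Xx") {
  stopifnot(two_c_size > 0, nchar(species_prefix) >= 1)
  structure(list(two_c_size = two_c_size, species_prefix = species_prefix),
            class = "genome_constants")
}

#' Map short reads to a satellitome (best hit per read)
#'
#' Sensitive local mapping: each read is aligned against the tandemized
#' consensus of every family sharing a seed k-mer (both strands) and
#' assigned to at most one family, its best-scoring local alignment with
#' score >= `min_score`. Genomic abundance of a family is the percentage of
#' total reads assigned to it.
#'
#' @param reads character vector of reads (non-empty).
#' @param satellitome named character vector of consensus monomers.
#' @param params an [alignment_params()] object.
#' @param min_score minimum accepted alignment score.
#' @return list of class `"short_read_map"`: `counts`, `abundance_pct`
#'   (named per family), `assignments` (read, family, strand, score,
#'   s_start, s_end on the tandemized reference), `total_reads`,
#'   `ref_length` (single-family case only).
#' @export
map_short_reads <- function(reads, satellitome,
                            params = alignment_params(), min_score = 30L) {
  if (length(reads) == 0) stop("empty read set")
  stopifnot(length(satellitome) >= 1, !is.null(names(satellitome)))
  fam <- names(satellitome)
  max_rl <- max(nchar(reads))
  tandem <- vapply(satellitome, function(s) {
    L <- nchar(s)
    reps <- max(2L, ceiling((3 * L + max_rl + 40) / L))
    strrep(s, reps)
  }, character(1))
  refs <- c(tandem, revcomp(tandem))
  ref_fam <- c(fam, fam)
  ref_strand <- c(rep("+", length(fam)), rep("-", length(fam)))
  hits <- .map_reads_cpp(unname(reads), unname(refs), params$seed_kmer,
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend, as.integer(min_score),
                         as.integer(max_rl + 40))
  assignments <- data.frame(
    read = if (nrow(hits)) names(reads)[hits$read] %||%
      as.character(hits$read) else character(0),
    read_idx = hits$read,
    family = ref_fam[hits$ref], strand = ref_strand[hits$ref],
    score = hits$score, s_start = hits$s_start, s_end = hits$s_end,
    stringsAsFactors = FALSE)
  counts <- table(factor(assignments$family, levels = fam))
  counts <- setNames(as.integer(counts), fam)
  structure(list(counts = counts,
                 abundance_pct = 100 * counts / length(reads),
                 assignments = assignments,
                 total_reads = length(reads),
                 ref_length = if (length(fam) == 1) nchar(tandem[[1]])
                              else NA_integer_),
            class = "short_read_map")
}

#' Copy number per 2C genome from read abundance
#'
#' `CN = 2C_size (bp) * abundance (%) / (monomer_length (bp) * 100)`.
#'
#' @param abundance_pct percentage of total reads mapped to the family.
#' @param constants a [genome_constants()] object.
#' @param monomer_length consensus monomer length in bp.
#' @param integer round down to whole copies (the reported convention);
#'   set `FALSE` for the exact value.
#' @return copies per 2C (vectorized).
#' @export
cn_from_abundance <- function(abundance_pct, constants, monomer_length,
                              integer = TRUE) {
  stopifnot(all(abundance_pct >= 0), all(monomer_length > 0))
  cn <- constants$two_c_size * abundance_pct / (monomer_length * 100)
  if (integer) floor(cn) else cn
}

#' Genomic abundance from copy number
#'
#' Percentage of the genome occupied by all copies of a family:
#' `pct = CN * monomer_length / 2C_size * 100`. Exact inverse of
#' [cn_from_abundance()] (pre-rounding).
#'
#' @param cn copies per 2C.
#' @param monomer_length monomer length in bp.
#' @param constants a [genome_constants()] object.
#' @return percentage of the genome (vectorized).
#' @export
abundance_from_cn <- function(cn, monomer_length, constants) {
  stopifnot(all(cn >= 0), all(monomer_length > 0))
  cn * monomer_length / constants$two_c_size * 100
}

#' All thresholded hits of one family across a set of long reads
#'
#' @param family_seq consensus monomer.
#' @param long_reads character vector of long reads.
#' @param params an [alignment_params()] object.
#' @param thresholds a [hit_thresholds()] object (defaults: E <= 1e-5,
#'   identity >= 70%, query coverage >= 70%).
#' @return hit data frame with a `read` column and a `read_length` column.
#' @export
long_read_hits <- function(family_seq, long_reads,
                           params = alignment_params(),
                           thresholds = hit_thresholds()) {
  check_dna(family_seq, "family_seq")
  m <- nchar(family_seq)
  rc <- unname(revcomp(family_seq))
  rn <- names(long_reads) %||% as.character(seq_along(long_reads))
  rlen <- nchar(long_reads)
  empty <- {
    e <- empty_hits(); e$read <- character(0); e$read_length <- integer(0)
    e
  }
  # batch the R layer: collect raw window hits from all reads first, then
  # compute statistics, thresholds and collapsing vectorized (building a
  # data frame per read would dominate the runtime)
  acc <- vector("list", 2L * length(long_reads))
  ai <- 0L
  for (i in seq_along(long_reads)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") family_seq else rc
      df <- .scan_windows_cpp(q, long_reads[[i]], params$seed_kmer,
                              params$match, params$mismatch,
                              params$gap_open, params$gap_extend, 1L)
      if (length(df$score) == 0) next
      ai <- ai + 1L
      df$strand_minus <- strand == "-"
      df$read_i <- i
      acc[[ai]] <- df
    }
  }
  if (ai == 0) return(empty)
  acc <- acc[seq_len(ai)]
  col <- function(nm) unlist(lapply(acc, `[[`, nm), use.names = FALSE)
  qs <- col("q_start"); qe <- col("q_end")
  neg <- col("strand_minus")
  qs2 <- ifelse(neg, m - qe + 1L, qs)
  qe2 <- ifelse(neg, m - qs + 1L, qe)
  read_i <- col("read_i")
  score <- col("score"); matches <- col("matches")
  columns <- col("columns")
  hits <- data.frame(
    query_id = "query", subject_id = rn[read_i],
    q_start = qs2, q_end = qe2,
    s_start = col("s_start"), s_end = col("s_end"),
    strand = ifelse(neg, "-", "+"),
    identity_pct = 100 * matches / columns,
    query_coverage_pct = 100 * (qe2 - qs2 + 1) / m,
    score = score,
    evalue = params$karlin_k * m * rlen[read_i] *
      exp(-params$karlin_lambda * score),
    matches = matches, mismatches = col("mismatches"),
    gap_opens = col("gap_opens"), columns = columns,
    read = rn[read_i], read_length = rlen[read_i],
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= thresholds$max_evalue &
               hits$identity_pct >= thresholds$min_identity_pct &
               hits$query_coverage_pct >= thresholds$min_query_coverage_pct, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  parts <- split(hits, hits$read)
  parts <- lapply(parts, function(h) {
    h <- collapse_hits(h)
    if (nrow(h) > thresholds$max_hits) {
      keep <- order(h$score, decreasing = TRUE)[seq_len(thresholds$max_hits)]
      h <- h[sort(keep), , drop = FALSE]
    }
    h[order(h$s_start, h$s_end), , drop = FALSE]
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Long-read copy number of a family
#'
#' Total number of thresholded, non-redundant hits of the consensus across
#' all long reads, divided by `depth` (the long-read fold coverage of the
#' 2C genome). With `depth = 1` — reads totalling about one 2C equivalent —
#' the raw hit count itself estimates copies per 2C.
#'
#' @param family_seq consensus monomer.
#' @param long_reads character vector of long reads.
#' @param params,thresholds see [long_read_hits()].
#' @param depth long-read fold coverage of the 2C genome used for
#'   normalization (default 1).
#' @return estimated copies per 2C.
#' @export
pacbio_cn <- function(family_seq, long_reads, params = alignment_params(),
                      thresholds = hit_thresholds(), depth = 1) {
  stopifnot(depth > 0)
  nrow(long_read_hits(family_seq, long_reads, params, thresholds)) / depth
}

#' Copy-number cross-validation between platforms
#'
#' Families whose long-read and short-read copy-number estimates disagree
#' by more than one order of magnitude (|log10 ratio| > `log10_threshold`)
#' are flagged as putative consensus artifacts and excluded from the fit;
#' the agreement of the rest is summarized as the squared Pearson
#' correlation of the log10 copy numbers.
#'
#' @param records data frame with columns `family`, `illumina_cn`,
#'   `pacbio_cn`.
#' @param log10_threshold discrepancy threshold on |log10(pacbio/illumina)|.
#' @return list: `records` (with `log10_ratio` and `discrepant` columns),
#'   `r_squared`, `n_used`.
#' @export
cncv <- function(records, log10_threshold = 1.0) {
  stopifnot(all(c("family", "illumina_cn", "pacbio_cn") %in%
                names(records)))
  lr <- ifelse(records$illumina_cn > 0 & records$pacbio_cn > 0,
               log10(records$pacbio_cn / records$illumina_cn), Inf)
  records$log10_ratio <- lr
  records$discrepant <- !is.finite(lr) | abs(lr) > log10_threshold
  ok <- !records$discrepant
  if (sum(ok) < 3)
    stop("fewer than 3 families with concordant positive copy numbers")
  r <- cor(log10(records$illumina_cn[ok]), log10(records$pacbio_cn[ok]))
  list(records = records, r_squared = r^2, n_used = sum(ok))
}

#' Adjusted copy number (geometric mean of the two platforms)
#'
#' `ACN = exp((ln a + ln b) / 2)`, i.e. sqrt(a * b); symmetric and always
#' between the two estimates.
#'
#' @param illumina_cn,pacbio_cn positive copy-number estimates
#'   (vectorized).
#' @return adjusted copies per 2C.
#' @export
adjusted_cn <- function(illumina_cn, pacbio_cn) {
  stopifnot(all(illumina_cn > 0), all(pacbio_cn > 0))
  exp((log(illumina_cn) + log(pacbio_cn)) / 2)
}
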