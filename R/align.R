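#' Alignment scoring and statistics parameters
#'
#' Scoring scheme and Karlin-Altschul constants for the local-alignment
#' engine. Defaults follow the classic nucleotide scheme match +1,
#' mismatch -2, for which the published ungapped Karlin-Altschul constants
#' are lambda = 1.33 and K = 0.621. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match match reward (positive integer).
#' @param mismatch mismatch penalty (positive integer).
#' @param gap_open gap opening penalty (positive integer).
#' @param gap_extend gap extension penalty (positive integer),
#'   `gap_open >= gap_extend >= 0`.
#' @param karlin_lambda,karlin_k Karlin-Altschul constants matching the
#'   scoring scheme; used by [estimate_evalue()].
#' @param seed_kmer word size used to seed hit scans (>= 5).
#' @return an object of class `"alignment_params"`.
#' @export
alignment_params <- function(match = 1L, mismatch = 2L, gap_open = 5L,
                             gap_extend = 2L, karlin_lambda = 1.33,
                             karlin_k = 0.621, seed_kmer = 11L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= gap_extend, gap_extend >= 0,
            karlin_lambda > 0, karlin_k > 0, seed_kmer >= 5)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 seed_kmer = as.integer(seed_kmer)),
            class = "alignment_params")
}

#' Hit admission thresholds
#'
#' The three-way filter (E-value, percent identity, query coverage) applied
#' to every similarity search, with defaults matching the long-read and
#' assembly scans: E <= 1e-5, identity >= 70%, query coverage >= 70%.
#'
#' @param max_evalue maximum E-value.
#' @param min_identity_pct minimum percent identity in \[0, 100\].
#' @param min_query_coverage_pct minimum query coverage in \[0, 100\].
#' @param max_hits maximum number of hits returned (>= 1).
#' @return an object of class `"hit_thresholds"`.
#' @export
hit_thresholds <- function(max_evalue = 1e-5, min_identity_pct = 70,
                           min_query_coverage_pct = 70, max_hits = 1e7) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            min_query_coverage_pct >= 0, min_query_coverage_pct <= 100,
            max_hits >= 1)
  structure(list(max_evalue = max_evalue,
                 min_identity_pct = min_identity_pct,
                 min_query_coverage_pct = min_query_coverage_pct,
                 max_hits = max_hits),
            class = "hit_thresholds")
}

check_dna <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0)
    stop(sprintf("'%s' must be a single non-empty DNA string", arg))
  if (grepl("[^ACGTNacgtn]", x))
    stop(sprintf("'%s' contains characters outside {A,C,G,T,N}", arg))
  invisible(x)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), identity_pct = numeric(),
             query_coverage_pct = numeric(), score = integer(),
             evalue = numeric(), matches = integer(), mismatches = integer(),
             gap_opens = integer(), columns = integer(),
             stringsAsFactors = FALSE)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of local
#' alignments of at least that score between random sequences of lengths
#' `m` and `n`. Strictly decreasing in the score.
#'
#' @param score alignment raw score (>= 0).
#' @param m query length.
#' @param n subject length.
#' @param params an [alignment_params()] object supplying lambda and K.
#' @return numeric E-value (vectorized over `score`).
#' @export
estimate_evalue <- function(score, m, n, params = alignment_params()) {
  stopifnot(all(score >= 0), m > 0, n > 0)
  params$karlin_k * m * n * exp(-params$karlin_lambda * score)
}

bit_score <- function(score, params) {
  (params$karlin_lambda * score - log(params$karlin_k)) / log(2)
}

#' Best local alignment of two sequences
#'
#' Maximum-scoring Smith-Waterman local alignment under affine gap costs.
#' Returns `NULL` when the best score is not positive.
#'
#' @param a query sequence (non-empty, over A/C/G/T/N).
#' @param b subject sequence.
#' @param params an [alignment_params()] object.
#' @param query_id,subject_id identifiers recorded in the hit.
#' @param traceback if `TRUE` the gapped alignment strings are attached as
#'   attribute `"alignment"`.
#' @return a one-row hit data frame (coordinates 1-based inclusive, plus
#'   `identity_pct`, `query_coverage_pct`, `score`, `evalue`) or `NULL`.
#' @export
local_align <- function(a, b, params = alignment_params(),
                        query_id = "query", subject_id = "subject",
                        traceback = FALSE) {
  check_dna(a, "a"); check_dna(b, "b")
  r <- .sw_align_cpp(a, b, params$match, params$mismatch,
                     params$gap_open, params$gap_extend, traceback)
  if (r$score <= 0) return(NULL)
  hit <- data.frame(query_id = query_id, subject_id = subject_id,
                    q_start = r$q_start, q_end = r$q_end,
                    s_start = r$s_start, s_end = r$s_end,
                    strand = "+",
                    identity_pct = 100 * r$matches / r$columns,
                    query_coverage_pct =
                      100 * (r$q_end - r$q_start + 1) / nchar(a),
                    score = r$score,
                    evalue = estimate_evalue(r$score, nchar(a), nchar(b),
                                             params),
                    matches = r$matches, mismatches = r$mismatches,
                    gap_opens = r$gap_opens, columns = r$columns,
                    stringsAsFactors = FALSE)
  if (traceback) attr(hit, "alignment") <- list(q = r$q_aln, s = r$s_aln)
  hit
}

# Collapse hits overlapping by more than half of the shorter hit on the same
# subject strand, keeping the higher score. Iterated sweep over hits ordered
# by subject start; near-duplicates from adjacent scan windows are adjacent
# in that order, so the sweep converges in a handful of passes.
collapse_hits <- function(hits, max_overlap_frac = 0.5) {
  if (nrow(hits) < 2) return(hits)
  parts <- split(hits, hits$strand)
  parts <- lapply(parts, function(h) {
    repeat {
      if (nrow(h) < 2) return(h)
      o <- order(h$s_start, h$s_end)
      h <- h[o, , drop = FALSE]
      s1 <- h$s_start[-nrow(h)]; e1 <- h$s_end[-nrow(h)]
      s2 <- h$s_start[-1]; e2 <- h$s_end[-1]
      ov <- pmin(e1, e2) - pmax(s1, s2) + 1
      shorter <- pmin(e1 - s1 + 1, e2 - s2 + 1)
      bad <- which(ov > max_overlap_frac * shorter)
      if (length(bad) == 0) return(h)
      drop <- integer(0)
      for (i in bad) {
        loser <- if (h$score[i] >= h$score[i + 1]) i + 1L else i
        drop <- c(drop, loser)
      }
      h <- h[-unique(drop), , drop = FALSE]
    }
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Scan a subject sequence for all thresholded hits of a query
#'
#' Seed-and-extend search on both strands: positions of the subject sharing
#' a `seed_kmer`-word with the query are merged into candidate regions,
#' tiled with windows of twice the query length, and each window is refined
#' by a full local alignment. Hits passing the thresholds are made
#' non-redundant (same-strand hits overlapping by more than 50% of the
#' shorter are collapsed, keeping the higher score) and returned sorted by
#' subject position. Minus-strand hits are reported on subject forward
#' coordinates.
#'
#' @param query query sequence (e.g. a consensus monomer).
#' @param subject subject sequence (may be chromosome-scale).
#' @param params an [alignment_params()] object.
#' @param thresholds a [hit_thresholds()] object.
#' @param query_id,subject_id identifiers recorded per hit.
#' @return a hit data frame, one row per hit (possibly zero rows).
#' @export
scan_hits <- function(query, subject, params = alignment_params(),
                      thresholds = hit_thresholds(),
                      query_id = "query", subject_id = "subject") {
  check_dna(query, "query"); check_dna(subject, "subject")
  m <- nchar(query); n <- nchar(subject)
  one_strand <- function(q, strand) {
    df <- .scan_windows_cpp(q, subject, params$seed_kmer, params$match,
                            params$mismatch, params$gap_open,
                            params$gap_extend, 1L)
    if (nrow(df) == 0) return(empty_hits())
    qs <- df$q_start; qe <- df$q_end
    if (strand == "-") { # map back to original query coordinates
      qs2 <- m - qe + 1L; qe <- m - df$q_start + 1L; qs <- qs2
    }
    data.frame(query_id = query_id, subject_id = subject_id,
               q_start = qs, q_end = qe,
               s_start = df$s_start, s_end = df$s_end,
               strand = strand,
               identity_pct = 100 * df$matches / df$columns,
               query_coverage_pct = 100 * (qe - qs + 1) / m,
               score = df$score,
               evalue = estimate_evalue(df$score, m, n, params),
               matches = df$matches, mismatches = df$mismatches,
               gap_opens = df$gap_opens, columns = df$columns,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(one_strand(query, "+"), one_strand(revcomp(query), "-"))
  hits <- hits[hits$evalue <= thresholds$max_evalue &
               hits$identity_pct >= thresholds$min_identity_pct &
               hits$query_coverage_pct >= thresholds$min_query_coverage_pct, ,
               drop = FALSE]
  hits <- collapse_hits(hits)
  if (nrow(hits) > thresholds$max_hits) {
    keep <- order(hits$score, decreasing = TRUE)[seq_len(thresholds$max_hits)]
    hits <- hits[sort(keep), , drop = FALSE]
  }
  hits <- hits[order(hits$s_start, hits$s_end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Best circular-aware local alignment between two monomers: the shorter is
# aligned against the doubled longer, on both strands. Returns a one-row
# hit with identity, coverage of the shorter sequence, score and strand.
circular_align <- function(a, b, params = alignment_params()) {
  check_dna(a, "a"); check_dna(b, "b")
  if (nchar(a) <= nchar(b)) { q <- a; s <- b; swapped <- FALSE }
  else { q <- b; s <- a; swapped <- TRUE }
  ss <- paste0(s, s)
  fw <- .sw_align_cpp(q, ss, params$match, params$mismatch, params$gap_open,
                      params$gap_extend, FALSE)
  rv <- .sw_align_cpp(revcomp(q), ss, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, FALSE)
  r <- if (rv$score > fw$score) rv else fw
  strand <- if (rv$score > fw$score) "-" else "+"
  if (r$score <= 0)
    return(list(identity_pct = 0, coverage_shorter_pct = 0, score = 0,
                strand = strand, swapped = swapped))
  list(identity_pct = 100 * r$matches / r$columns,
       coverage_shorter_pct = 100 * (r$q_end - r$q_start + 1) / nchar(q),
       score = r$score, strand = strand, swapped = swapped)
}

#' Rotation-invariant percent identity between two monomers
#'
#' Tandem monomers are rotation-ambiguous, so the shorter monomer is
#' aligned against the doubled partner (both strands) and the identity of
#' the best local alignment is returned. A rotation of a sequence therefore
#' scores 100%.
#'
#' @param a,b monomer sequences.
#' @param params an [alignment_params()] object.
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity_circular <- function(a, b, params = alignment_params()) {
  circular_align(a, b, params)$identity_pct
}

#' Export hits as 12-column tabular text
#'
#' Standard tab-separated hit table: query, subject, identity, alignment
#' length, mismatches, gap opens, q. start, q. end, s. start, s. end,
#' evalue, score.
#'
#' @param hits a hit data frame from [scan_hits()].
#' @param path output path.
#' @export
write_hits_tabular <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.3f", hits$identity_pct), hits$columns,
                    hits$mismatches, hits$gap_opens,
                    hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                    format(hits$evalue, digits = 3), hits$score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
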