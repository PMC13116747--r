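# De-novo tandem-array detection by k-mer recurrence distances, multi-round
# masking, monomer extraction, strand re-orientation and consensus building
# with a k-mer-coverage quality score.

shuffle_seq <- function(x, seed = 1L) {
  with_seed(seed, paste(sample(strsplit(x, "", fixed = TRUE)[[1]]),
                        collapse = ""))
}

# Distances (to the previous occurrence of the same k-mer) within a range,
# as positions + distance pairs. Positions are 1-based k-mer starts.
dist_in_range <- function(seq, k, period_range) {
  d <- .kmer_dist_profile_cpp(seq, k)
  idx <- which(d >= period_range[1] & d <= period_range[2])
  list(pos = idx, dist = d[idx])
}

# Support events: runs of consecutive supporting positions collapse to one
# event, so a single chance repeat (which yields a short run of adjacent
# positions) cannot mimic a tandem array. Returns the event count and the
# longest run length.
support_events <- function(pos) {
  if (length(pos) == 0) return(list(events = 0L, longest_run = 0L))
  breaks <- c(TRUE, diff(pos) > 1)
  run_id <- cumsum(breaks)
  list(events = max(run_id),
       longest_run = max(tabulate(run_id)))
}

#' Detect the tandem period of a window
#'
#' The modal distance between successive occurrences of repeated k-mers,
#' accepted only if its support (count of the modal distance) reaches
#' `min_support` and exceeds `null_factor` times the corresponding count in
#' a shuffled copy of the window.
#'
#' @param window DNA string, at least twice `period_range[2]` long.
#' @param k word size for the recurrence profile.
#' @param period_range numeric `(min, max)` period in bp.
#' @param min_support minimum count of the modal distance.
#' @param null_factor required ratio over the shuffled-sequence null.
#' @param null_seed seed for the shuffle (fixed so the call is
#'   deterministic).
#' @return the period in bp, or `NULL` if no significant periodicity.
#' @export
detect_periodicity <- function(window, k = 13L, period_range = c(10, 200),
                               min_support = 5L, null_factor = 3,
                               null_seed = 1L) {
  check_dna(window, "window")
  if (nchar(window) < 2 * period_range[2])
    stop("window shorter than twice the maximum period")
  obs <- dist_in_range(window, k, period_range)
  if (length(obs$dist) == 0) return(NULL)
  tab <- table(obs$dist)
  mode_d <- as.integer(names(tab)[which.max(tab)])
  se <- support_events(obs$pos[obs$dist == mode_d])
  support <- se$events
  nul <- dist_in_range(shuffle_seq(window, null_seed), k, period_range)
  null_count <- if (length(nul$dist) == 0) 0 else {
    ntab <- table(nul$dist)
    nmode <- as.integer(names(ntab)[which.max(ntab)])
    support_events(nul$pos[nul$dist == nmode])$events
  }
  ok <- (support >= min_support || se$longest_run >= 2 * mode_d) &&
    support >= null_factor * max(null_count, 1)
  if (ok) mode_d else NULL
}

segment_one_scaffold <- function(seq, chrom, k, period_range, min_support,
                                 null_factor, null_seed) {
  obs <- dist_in_range(seq, k, period_range)
  if (length(obs$pos) == 0) return(NULL)
  pos <- obs$pos; dst <- obs$dist
  # break into segments where consecutive supporting positions are near
  gap_limit <- 3 * pmax(dst[-1], dst[-length(dst)])
  brk <- which(diff(pos) > gap_limit)
  seg_id <- cumsum(c(1L, as.integer(seq_along(pos)[-1] %in% (brk + 1L))))
  calls <- list()
  for (sid in unique(seg_id)) {
    sel <- seg_id == sid
    p <- pos[sel]; d <- dst[sel]
    tab <- table(d)
    period <- as.integer(names(tab)[which.max(tab)])
    tol <- max(2, round(0.1 * period))
    core <- abs(d - period) <= tol
    se <- support_events(p[core])
    support <- se$events
    if (support < min_support && se$longest_run < 2 * period) next
    start <- max(1L, min(p[core]) - period)
    end <- min(nchar(seq), max(p[core]) + k - 1L)
    span <- end - start + 1L
    if (span < 2 * period) next
    # significance against a shuffled copy of the segment itself
    nul <- dist_in_range(shuffle_seq(substr(seq, start, end), null_seed),
                         k, period_range)
    null_count <- if (length(nul$dist) == 0) 0 else {
      ntab <- table(nul$dist)
      nmode <- as.integer(names(ntab)[which.max(ntab)])
      support_events(nul$pos[nul$dist == nmode])$events
    }
    if (support < null_factor * max(null_count, 1)) next
    calls[[length(calls) + 1]] <- data.frame(
      chromosome = chrom, start = start, end = end, period = period,
      n_copies_est = span %/% period, support = support,
      stringsAsFactors = FALSE)
  }
  if (length(calls)) do.call(rbind, calls) else NULL
}

merge_adjacent_calls <- function(calls, max_gap_periods = 2) {
  if (is.null(calls) || nrow(calls) < 2) return(calls)
  calls <- calls[order(calls$chromosome, calls$start), , drop = FALSE]
  out <- calls[1, , drop = FALSE]
  for (i in 2:nrow(calls)) {
    cur <- calls[i, ]
    last <- out[nrow(out), ]
    same_period <- abs(cur$period - last$period) <=
      0.1 * max(cur$period, last$period)
    gap <- cur$start - last$end - 1
    if (cur$chromosome == last$chromosome && same_period &&
        gap <= max_gap_periods * max(cur$period, last$period)) {
      out$end[nrow(out)] <- max(last$end, cur$end)
      out$support[nrow(out)] <- last$support + cur$support
      out$n_copies_est[nrow(out)] <-
        (out$end[nrow(out)] - out$start[nrow(out)] + 1) %/% last$period
    } else {
      out <- rbind(out, cur)
    }
  }
  rownames(out) <- NULL
  out
}

#' Segment a genome into tandem-array calls
#'
#' Maximal runs of positions whose k-mers recur at a consistent distance
#' inside `period_range` become array calls; adjacent calls with periods
#' within 10% of each other are merged.
#'
#' @param genome named character vector of scaffold sequences.
#' @param k word size.
#' @param period_range numeric `(min, max)` period in bp.
#' @param min_support,null_factor,null_seed significance floor, see
#'   [detect_periodicity()].
#' @return data frame of array calls (chromosome, start, end, period,
#'   n_copies_est, support), 1-based inclusive coordinates.
#' @export
segment_arrays <- function(genome, k = 13L, period_range = c(10, 200),
                           min_support = 5L, null_factor = 3,
                           null_seed = 1L) {
  calls <- list()
  for (chrom in names(genome)) {
    cc <- segment_one_scaffold(genome[[chrom]], chrom, k, period_range,
                               min_support, null_factor, null_seed)
    if (!is.null(cc)) calls[[length(calls) + 1]] <- cc
  }
  empty <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), period = integer(),
                      n_copies_est = integer(), support = integer(),
                      stringsAsFactors = FALSE)
  if (length(calls) == 0) return(empty)
  merge_adjacent_calls(do.call(rbind, calls))
}

#' Multi-round tandem detection with masking
#'
#' Detection rounds with increasing period ranges; every region called in a
#' round is hard-masked (N) before the next round, so long-period arrays
#' are found without re-calling short-period ones.
#'
#' @param genome named character vector.
#' @param rounds list of `(min, max)` period ranges, one per round.
#' @param ... further arguments passed to [segment_arrays()].
#' @return array-call data frame with a `source_round` column.
#' @export
run_rounds <- function(genome,
                       rounds = list(c(10, 200), c(150, 1000),
                                     c(800, 3000)), ...) {
  masked <- genome
  all_calls <- list()
  for (r in seq_along(rounds)) {
    calls <- segment_arrays(masked, period_range = rounds[[r]], ...)
    if (nrow(calls) > 0) {
      calls$source_round <- r
      all_calls[[length(all_calls) + 1]] <- calls
      for (i in seq_len(nrow(calls))) {
        ch <- calls$chromosome[i]
        substr(masked[[ch]], calls$start[i], calls$end[i]) <-
          strrep("N", calls$end[i] - calls$start[i] + 1)
      }
    }
  }
  if (length(all_calls) == 0) {
    out <- segment_arrays(genome["__none__" == names(genome)])
    out$source_round <- integer(0)
    return(out)
  }
  out <- do.call(rbind, all_calls)
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Extract phase-standardized monomer units from an array call
#'
#' The called interval is partitioned into period-length units; each unit
#' is rotated to the rotation minimizing Hamming distance to the first
#' unit, so indel-induced phase drift does not break column alignment.
#'
#' @param call one row of an array-call data frame.
#' @param genome named character vector.
#' @return character vector of monomer units.
#' @export
extract_monomers <- function(call, genome) {
  seq <- substr(genome[[call$chromosome]], call$start, call$end)
  p <- call$period
  n <- nchar(seq) %/% p
  if (n < 1) return(character(0))
  starts <- (seq_len(n) - 1L) * p + 1L
  units <- substring(seq, starts, starts + p - 1L)
  if (n == 1) return(units)
  ref <- units[1]
  vapply(units, function(u) {
    r <- .best_rotation_cpp(u, ref)
    if (r == 0) u else paste0(substr(u, r + 1, nchar(u)), substr(u, 1, r))
  }, character(1), USE.NAMES = FALSE)
}

kmer_multiset <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

#' Re-orient monomers to a consistent strand
#'
#' Each monomer keeps the orientation (forward or reverse complement)
#' sharing more k-mers with the running aggregate k-mer profile of the
#' monomers already accepted; ties (e.g. perfect palindromes, or the first
#' monomer) go to the lexicographically smaller sequence.
#'
#' @param monomers character vector.
#' @param k word size of the orientation profile.
#' @return character vector of strand-consistent monomers.
#' @export
reorient_monomers <- function(monomers, k = 7L) {
  if (length(monomers) == 0) return(monomers)
  profile <- character(0) # distinct k-mers seen in accepted monomers
  out <- character(length(monomers))
  for (i in seq_along(monomers)) {
    fwd <- monomers[[i]]; rev <- revcomp(fwd)
    kf <- kmer_multiset(fwd, k); kr <- kmer_multiset(rev, k)
    sf <- sum(kf %in% profile); sr <- sum(kr %in% profile)
    # the first monomer anchors the profile and keeps its orientation;
    # later ties (e.g. palindromes) go to the lexicographically smaller
    keep <- if (length(profile) == 0 || sf > sr) fwd
      else if (sr > sf) rev
      else if (fwd <= rev) fwd else rev
    out[i] <- keep
    profile <- unique(c(profile, kmer_multiset(keep, k)))
  }
  out
}

# Per-column bases of `monomer` over the positions of `medoid`, from a
# local alignment with traceback; positions outside the alignment are NA.
aligned_columns <- function(monomer, medoid, params) {
  r <- .sw_align_cpp(monomer, medoid, params$match, params$mismatch,
                     params$gap_open, params$gap_extend, TRUE)
  col <- rep(NA_character_, nchar(medoid))
  if (r$score <= 0) return(col)
  qa <- strsplit(r$q_aln, "", fixed = TRUE)[[1]]
  sa <- strsplit(r$s_aln, "", fixed = TRUE)[[1]]
  spos <- r$s_start - 1L
  for (j in seq_along(sa)) {
    if (sa[j] != "-") {
      spos <- spos + 1L
      col[spos] <- qa[j]
    }
  }
  col
}

#' Build a consensus monomer with a k-mer-coverage score
#'
#' The medoid monomer (smallest summed alignment distance to the others) is
#' used as the column frame; the consensus is the column-wise majority base
#' (majority-deletion columns are dropped). The k-mer coverage is the
#' fraction of the monomer pool's k-mer instances whose k-mer occurs in the
#' consensus; candidates below 0.5 are conventionally rejected downstream.
#'
#' @param monomers character vector of (re-oriented) monomer units.
#' @param k word size of the coverage score.
#' @param params an [alignment_params()] object.
#' @param max_align maximum number of monomers aligned for the column vote
#'   (an evenly spaced subset is used beyond that; the coverage score
#'   always uses the full pool).
#' @return list with `sequence`, `kmer_coverage` and `n_monomers`.
#' @export
build_consensus <- function(monomers, k = 7L, params = alignment_params(),
                            max_align = NULL) {
  if (length(monomers) == 0) stop("empty monomer list")
  if (length(monomers) == 1)
    return(list(sequence = monomers[[1]], kmer_coverage = 1.0,
                n_monomers = 1L))
  n <- length(monomers)
  L <- max(nchar(monomers))
  # column-vote panel scaled down for long monomers (alignment cost ~ L^2)
  if (is.null(max_align))
    max_align <- min(40L, max(12L, ceiling(2e7 / (L * L))))
  sub <- monomers[unique(round(seq(1, n, length.out = min(n, max_align))))]
  # medoid among a small evenly spaced panel
  panel <- sub[unique(round(seq(1, length(sub),
                                length.out = min(length(sub), 8))))]
  np <- length(panel)
  dmat <- matrix(0, np, np)
  if (np > 1) for (i in 1:(np - 1)) for (j in (i + 1):np) {
    r <- .sw_align_cpp(panel[[i]], panel[[j]], params$match,
                       params$mismatch, params$gap_open,
                       params$gap_extend, FALSE)
    d <- if (r$columns == 0) 100 else 100 * (1 - r$matches / r$columns)
    dmat[i, j] <- dmat[j, i] <- d
  }
  medoid <- panel[[which.min(rowSums(dmat))]]
  cols <- vapply(sub, aligned_columns, character(nchar(medoid)),
                 medoid = medoid, params = params)
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = nchar(medoid))
  # columns voted on by fewer than half the panel (frame edges, partial
  # units) are unreliable and dropped rather than decided by a minority
  col_support <- apply(cols, 1, function(cc) sum(!is.na(cc)))
  consensus_chars <- apply(cols, 1, function(cc) {
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0) return(NA_character_)
    tb <- sort(table(cc), decreasing = TRUE)
    names(tb)[1]
  })
  consensus_chars[col_support < 0.5 * ncol(cols)] <- NA_character_
  consensus_chars <- consensus_chars[!is.na(consensus_chars) &
                                     consensus_chars != "-"]
  consensus <- paste(consensus_chars, collapse = "")
  pool <- unlist(lapply(monomers, kmer_multiset, k = k))
  cons_set <- unique(kmer_multiset(consensus, k))
  kcov <- if (length(pool) == 0) 0 else mean(pool %in% cons_set)
  list(sequence = consensus, kmer_coverage = kcov, n_monomers = n)
}

#' De-novo satellite candidates from a genome
#'
#' Full detection stage: multi-round array calling, monomer extraction and
#' re-orientation, consensus building, and the k-mer-coverage >= 0.5
#' acceptance filter.
#'
#' @param genome named character vector (preprocess with
#'   [preprocess_assembly()] first).
#' @param rounds list of period ranges, see [run_rounds()].
#' @param min_kmer_coverage minimum consensus k-mer coverage.
#' @param assembly,detector provenance labels recorded per candidate.
#' @param params an [alignment_params()] object.
#' @param ... passed to [segment_arrays()].
#' @return candidate data frame: candidate_id, sequence, length,
#'   kmer_coverage, source_round, assembly, detector, chromosome, start,
#'   end, period.
#' @export
detect_satellites <- function(genome,
                              rounds = list(c(10, 200), c(150, 1000),
                                            c(800, 3000)),
                              min_kmer_coverage = 0.5,
                              assembly = "asm1", detector = "kmer-period",
                              params = alignment_params(), ...) {
  calls <- run_rounds(genome, rounds, ...)
  out <- list()
  if (nrow(calls) > 0) for (i in seq_len(nrow(calls))) {
    mono <- extract_monomers(calls[i, ], genome)
    if (length(mono) == 0) next
    mono <- reorient_monomers(mono)
    cons <- build_consensus(mono, params = params)
    if (nchar(cons$sequence) < 10) next
    if (cons$kmer_coverage < min_kmer_coverage) next
    out[[length(out) + 1]] <- data.frame(
      candidate_id = sprintf("%s_%s_%d_%d", detector, calls$chromosome[i],
                             calls$start[i], calls$period[i]),
      sequence = cons$sequence, length = nchar(cons$sequence),
      kmer_coverage = cons$kmer_coverage,
      source_round = calls$source_round[i],
      assembly = assembly, detector = detector,
      chromosome = calls$chromosome[i], start = calls$start[i],
      end = calls$end[i], period = calls$period[i],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(candidate_id = character(), sequence = character(),
                      length = integer(), kmer_coverage = numeric(),
                      source_round = integer(), assembly = character(),
                      detector = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      period = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write array calls as BED
#'
#' Coordinates are converted to BED's 0-based half-open convention on
#' output.
#'
#' @param calls array-call data frame.
#' @param path output path.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(calls$chromosome, calls$start - 1L, calls$end,
                    sprintf("period=%d;copies=%d", calls$period,
                            calls$n_copies_est))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
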