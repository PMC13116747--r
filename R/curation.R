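# Redundancy removal within and across assemblies/detectors, merging with a
# known-satDNA library, Markov clustering of the similarity graph, and
# coverage-profile evidence for manual curation.

#' Greedy two-pass deduplication by circular identity
#'
#' Greedy centroid clustering, longest-first: a candidate joins an existing
#' representative when its rotation-invariant identity reaches
#' `identity_threshold` and the alignment covers at least
#' `min_coverage_pct` of the shorter monomer (the coverage guard prevents a
#' short monomer embedded in an unrelated long one from being absorbed).
#' Pass 1 deduplicates within each assembly of origin; pass 2 removes
#' redundancy between detectors/assemblies.
#'
#' @param candidates candidate data frame with columns `candidate_id`,
#'   `sequence` and (for pass grouping) `assembly`.
#' @param identity_threshold percent identity for merging (default 80).
#' @param min_coverage_pct minimum alignment coverage of the shorter
#'   monomer.
#' @param passes 1 (global) or 2 (per-assembly, then global).
#' @param params an [alignment_params()] object.
#' @return the representative subset of `candidates`, with `n_merged`
#'   counting cluster members.
#' @export
dedup_identity <- function(candidates, identity_threshold = 80,
                           min_coverage_pct = 80, passes = 2,
                           params = alignment_params()) {
  if (nrow(candidates) <= 1) {
    if (nrow(candidates) == 1) candidates$n_merged <- 1L
    return(candidates)
  }
  greedy <- function(df) {
    df <- df[order(-nchar(df$sequence)), , drop = FALSE]
    rep_idx <- integer(0)
    members <- integer(nrow(df))
    for (i in seq_len(nrow(df))) {
      assigned <- FALSE
      for (r in rep_idx) {
        ca <- circular_align(df$sequence[i], df$sequence[r], params)
        if (ca$identity_pct >= identity_threshold &&
            ca$coverage_shorter_pct >= min_coverage_pct) {
          members[r] <- members[r] + df$n_merged[i]
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        rep_idx <- c(rep_idx, i)
        members[i] <- df$n_merged[i]
      }
    }
    out <- df[rep_idx, , drop = FALSE]
    out$n_merged <- members[rep_idx]
    out
  }
  if (is.null(candidates$n_merged)) candidates$n_merged <- 1L
  if (passes >= 2 && !is.null(candidates$assembly)) {
    parts <- split(candidates, candidates$assembly)
    candidates <- do.call(rbind, lapply(parts, greedy))
  }
  out <- greedy(candidates)
  rownames(out) <- NULL
  out
}

#' Build a sequence-similarity graph over candidates
#'
#' All-versus-all rotation-invariant local alignment; an undirected edge is
#' admitted only when the E-value, identity and coverage-of-the-shorter
#' thresholds all pass, weighted by the alignment bit score.
#'
#' @param candidates candidate data frame (`candidate_id`, `sequence`).
#' @param params an [alignment_params()] object.
#' @param max_evalue,min_identity_pct,min_coverage_pct admission
#'   thresholds (defaults E <= 1e-5, identity >= 80%, coverage >= 80% of
#'   the shorter sequence).
#' @return an object of class `"similarity_graph"`: `nodes`, `edges`
#'   (`i`, `j`, `weight`), and the thresholds used.
#' @export
build_similarity_graph <- function(candidates, params = alignment_params(),
                                   max_evalue = 1e-5, min_identity_pct = 80,
                                   min_coverage_pct = 80) {
  n <- nrow(candidates)
  edges <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- candidates$sequence[i]; b <- candidates$sequence[j]
    ca <- circular_align(a, b, params)
    if (ca$score <= 0) next
    m <- min(nchar(a), nchar(b)); nn <- max(nchar(a), nchar(b))
    ev <- estimate_evalue(ca$score, m, nn, params)
    if (ev <= max_evalue && ca$identity_pct >= min_identity_pct &&
        ca$coverage_shorter_pct >= min_coverage_pct) {
      edges[[length(edges) + 1]] <- data.frame(
        i = candidates$candidate_id[i], j = candidates$candidate_id[j],
        weight = bit_score(ca$score, params), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(i = character(), j = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  structure(list(nodes = candidates$candidate_id, edges = edges,
                 thresholds = list(max_evalue = max_evalue,
                                   min_identity_pct = min_identity_pct,
                                   min_coverage_pct = min_coverage_pct)),
            class = "similarity_graph")
}

#' Markov clustering of a weighted similarity graph
#'
#' Classic MCL on the column-normalized weight matrix: expansion is matrix
#' squaring, inflation is entrywise power followed by renormalization,
#' iterated to convergence; clusters are the connected components of the
#' converged attractor matrix. Self-loops (weight = node's maximum incident
#' weight, or 1 for isolated nodes) are added before normalization to
#' stabilize the iteration.
#'
#' @param graph a [build_similarity_graph()] object.
#' @param inflation inflation exponent (default 2.0).
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the maximum entry change.
#' @param prune entries below this are zeroed each iteration.
#' @return named integer vector: cluster id per node, deterministic
#'   (clusters numbered by first member).
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 100L,
                        tol = 1e-9, prune = 1e-6) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(setNames(integer(0), character(0)))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0) for (r in seq_len(nrow(e))) {
    A[e$i[r], e$j[r]] <- A[e$i[r], e$j[r]] + e$weight[r]
    A[e$j[r], e$i[r]] <- A[e$j[r], e$i[r]] + e$weight[r]
  }
  loops <- apply(A, 1, max)
  diag(A) <- ifelse(loops > 0, loops, 1)
  normalize <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.xmin),
                                 "/")
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("MCL did not converge in %d iterations (last delta %.3g)",
                 max_iter, delta))
  # clusters: connected components of the attractor structure
  B <- (M > 1e-6) | t(M > 1e-6)
  diag(B) <- TRUE
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(cluster[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(cluster[v])) next
      cluster[v] <- cid
      queue <- c(queue, which(B[v, ] & is.na(cluster)))
    }
  }
  setNames(cluster, nodes)
}

#' Merge candidates with a known-satDNA library
#'
#' Known entries join the candidate pool before final clustering; they are
#' prior knowledge and are never removed by quality filters, only merged.
#' When a final cluster contains a known entry, its original name is kept
#' in the family's provenance.
#'
#' @param candidates candidate data frame.
#' @param known_library named character vector of known consensus
#'   sequences (names are the original published names), or `NULL`.
#' @return the combined candidate data frame with `known` and
#'   `original_name` columns.
#' @export
merge_with_known <- function(candidates, known_library = NULL) {
  if (is.null(candidates$known)) candidates$known <- FALSE
  if (is.null(candidates$original_name))
    candidates$original_name <- NA_character_
  if (is.null(known_library) || length(known_library) == 0)
    return(candidates)
  kdf <- data.frame(candidate_id = paste0("known_", names(known_library)),
                    sequence = unname(known_library),
                    length = nchar(known_library),
                    kmer_coverage = NA_real_, source_round = NA_integer_,
                    assembly = "library", detector = "known",
                    chromosome = NA_character_, start = NA_integer_,
                    end = NA_integer_, period = NA_integer_,
                    stringsAsFactors = FALSE)
  kdf$known <- TRUE
  kdf$original_name <- names(known_library)
  common <- intersect(names(candidates), names(kdf))
  extra <- setdiff(names(candidates), names(kdf))
  for (cc in extra) kdf[[cc]] <- NA
  out <- rbind(candidates[, c(common, extra), drop = FALSE],
               kdf[, c(common, extra), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Collapse candidates into final families via MCL
#'
#' Builds the similarity graph, runs Markov clustering, and keeps one
#' representative per cluster: the member with the highest short-read
#' abundance (ties to the longer sequence). Known-library names of cluster
#' members are collected as provenance.
#'
#' @param candidates candidate data frame (after screening and known-library
#'   merge).
#' @param abundance named numeric vector (percent of reads) per
#'   candidate_id; sequence length is used when `NULL`.
#' @param params,inflation,... passed to [build_similarity_graph()] and
#'   [mcl_cluster()].
#' @return family data frame: family_id, sequence, length, gc_pct, suffix,
#'   provenance, n_cluster_members.
#' @export
cluster_families <- function(candidates, abundance = NULL,
                             params = alignment_params(), inflation = 2.0,
                             ...) {
  if (nrow(candidates) == 0)
    return(data.frame(family_id = character(), sequence = character(),
                      length = integer(), gc_pct = numeric(),
                      suffix = character(), provenance = character(),
                      n_cluster_members = integer(),
                      stringsAsFactors = FALSE))
  g <- build_similarity_graph(candidates, params, ...)
  cl <- mcl_cluster(g, inflation = inflation)
  ab <- if (is.null(abundance))
    setNames(nchar(candidates$sequence), candidates$candidate_id)
  else abundance[candidates$candidate_id]
  ab[is.na(ab)] <- 0
  out <- lapply(split(seq_len(nrow(candidates)),
                      cl[candidates$candidate_id]), function(idx) {
    sub <- candidates[idx, , drop = FALSE]
    o <- order(-ab[sub$candidate_id], -nchar(sub$sequence))
    rep_row <- sub[o[1], , drop = FALSE]
    prov <- sub$original_name[!is.na(sub$original_name)]
    data.frame(family_id = rep_row$candidate_id,
               sequence = rep_row$sequence,
               length = nchar(rep_row$sequence),
               gc_pct = 100 * gc_fraction(rep_row$sequence),
               suffix = "none",
               provenance = paste(prov, collapse = ";"),
               n_cluster_members = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-position read depth over a consensus monomer
#'
#' Short reads are mapped with the package's sensitive local mapper against
#' the tandemized consensus; subject intervals are folded modulo the
#' monomer length into a per-position depth vector, the evidence used for
#' manual curation of chimeric or partial consensuses.
#'
#' @param family_seq consensus monomer sequence.
#' @param reads character vector of short reads.
#' @param params an [alignment_params()] object.
#' @param min_score minimum local alignment score to accept a read.
#' @return integer depth vector of length `nchar(family_seq)`.
#' @export
coverage_profile <- function(family_seq, reads, params = alignment_params(),
                             min_score = 30L) {
  check_dna(family_seq, "family_seq")
  L <- nchar(family_seq)
  if (length(reads) == 0) return(integer(L))
  mp <- map_short_reads(reads, setNames(family_seq, "family"), params,
                        min_score = min_score)
  a <- mp$assignments
  if (nrow(a) == 0) return(integer(L))
  tlen <- mp$ref_length
  # minus-strand assignments carry coordinates on the reverse-complement
  # reference; mirror them onto forward coordinates before folding
  neg <- a$strand == "-"
  s1 <- ifelse(neg, tlen - a$s_end + 1L, a$s_start)
  s2 <- ifelse(neg, tlen - a$s_start + 1L, a$s_end)
  acc <- numeric(tlen + 1)
  for (r in seq_len(nrow(a))) {
    acc[s1[r]] <- acc[s1[r]] + 1
    acc[s2[r] + 1] <- acc[s2[r] + 1] - 1
  }
  depth_t <- cumsum(acc[seq_len(tlen)])
  folded <- rowSums(matrix(depth_t, nrow = L))
  as.integer(folded)
}

#' Flag a suspicious (chimera-like) coverage profile
#'
#' A consensus whose depth collapses over a sizeable fraction of its length
#' (while the rest is well covered) is flagged for curation: flagged when
#' more than `max_low_frac` of positions fall below `low_frac` times the
#' upper-quartile depth.
#'
#' @param depth integer depth vector from [coverage_profile()].
#' @param low_frac depth fraction defining "low" (default 0.1).
#' @param max_low_frac tolerated fraction of low positions (default 0.25).
#' @return logical flag.
#' @export
flag_chimeric <- function(depth, low_frac = 0.1, max_low_frac = 0.25) {
  if (length(depth) == 0) return(FALSE)
  ref <- quantile(depth, 0.75, names = FALSE)
  if (ref <= 0) return(FALSE)
  mean(depth < low_frac * ref) > max_low_frac
}
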