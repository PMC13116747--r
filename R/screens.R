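# Contamination screens: protein-coding, transposable-element, organellar
# and rDNA sequences are removed from the candidate pool before the final
# satellitome is assembled. The cascade order (coding -> TE -> organelle ->
# rDNA) is fixed; a candidate is removed for exactly the first matching
# reason.

screen_result_row <- function(candidate_id, screen, removed, reason,
                              evalue = NA_real_, coverage_pct = NA_real_) {
  data.frame(candidate_id = candidate_id, screen = screen,
             removed = removed, reason = reason, evalue = evalue,
             coverage_pct = coverage_pct, stringsAsFactors = FALSE)
}

six_frame_peptides <- function(seq) {
  # translate the doubled candidate so reading frames broken by the
  # arbitrary rotation of a tandem monomer are restored
  dd <- paste0(seq, seq)
  frames <- c(dd, substr(dd, 2, nchar(dd)), substr(dd, 3, nchar(dd)))
  frames <- c(frames, revcomp(frames))
  vapply(frames, function(f) {
    f <- substr(f, 1, 3 * (nchar(f) %/% 3))
    as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(f),
                            if.fuzzy.codon = "X")))
  }, character(1), USE.NAMES = FALSE)
}

#' Screen candidates for protein-coding content
#'
#' Each candidate is translated in six frames (over the doubled monomer, so
#' rotation cannot split an ORF) and every peptide is locally aligned to
#' each reference protein (BLOSUM62, gap open 11 / extend 1). A candidate
#' is removed when any frame reaches E <= `max_evalue` with at least
#' `min_protein_cov_pct` of the reference protein covered. Protein E-values
#' use the gapped BLOSUM62 Karlin-Altschul constants (lambda = 0.267,
#' K = 0.041).
#'
#' @param candidates candidate data frame (`candidate_id`, `sequence`).
#' @param protein_refs named character vector of amino-acid sequences.
#' @param max_evalue E-value threshold (default 1e-5).
#' @param min_protein_cov_pct minimum coverage of the reference protein.
#' @return screen-result data frame, one row per candidate.
#' @export
screen_coding <- function(candidates, protein_refs, max_evalue = 1e-5,
                          min_protein_cov_pct = 50) {
  if (length(protein_refs) == 0)
    return(screen_result_row(candidates$candidate_id, "coding", FALSE,
                             "empty reference set"))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    peps <- six_frame_peptides(candidates$sequence[i])
    best <- list(evalue = Inf, cov = 0, ref = NA_character_)
    for (p in peps) {
      p <- gsub("[^ACDEFGHIKLMNPQRSTVWY*X]", "X", p)
      if (nchar(p) < 10) next
      for (rn in names(protein_refs)) {
        ref <- protein_refs[[rn]]
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(p), Biostrings::AAString(ref),
          type = "local", substitutionMatrix = mat,
          gapOpening = 11, gapExtension = 1, scoreOnly = FALSE)
        sc <- Biostrings::score(al)
        if (sc <= 0) next
        ev <- 0.041 * nchar(p) * nchar(ref) * exp(-0.267 * sc)
        scov <- 100 * Biostrings::width(Biostrings::subject(al)) / nchar(ref)
        if (ev < best$evalue) best <- list(evalue = ev, cov = scov, ref = rn)
      }
    }
    removed <- is.finite(best$evalue) && best$evalue <= max_evalue &&
      best$cov >= min_protein_cov_pct
    out[[i]] <- screen_result_row(
      candidates$candidate_id[i], "coding", removed,
      if (removed) sprintf("protein match to %s (E=%.2g, cov=%.0f%%)",
                           best$ref, best$evalue, best$cov)
      else "no qualifying protein match",
      if (is.finite(best$evalue)) best$evalue else NA_real_, best$cov)
  }
  do.call(rbind, out)
}

#' Screen candidates against a transposable-element library
#'
#' Nucleotide similarity search of each candidate against the TE
#' references; a candidate is removed when any hit reaches
#' E <= `max_evalue` (default 1e-3). The screen stands in for
#' profile-based TE scanning, so it uses the conservative gapped-style
#' Karlin-Altschul constants (lambda = 0.267, K = 0.041): short chance
#' matches of ~20 bp do not reach significance.
#'
#' @param candidates candidate data frame.
#' @param te_refs named character vector of TE nucleotide sequences.
#' @param max_evalue E-value threshold.
#' @param params alignment parameters; the scoring scheme is taken from
#'   here but lambda/K are overridden as documented.
#' @return screen-result data frame.
#' @export
screen_te <- function(candidates, te_refs, max_evalue = 1e-3,
                      params = alignment_params()) {
  if (length(te_refs) == 0)
    return(screen_result_row(candidates$candidate_id, "te", FALSE,
                             "empty reference set"))
  p2 <- params
  p2$karlin_lambda <- 0.267
  p2$karlin_k <- 0.041
  thr <- hit_thresholds(max_evalue = max_evalue, min_identity_pct = 0,
                        min_query_coverage_pct = 0, max_hits = 1e7)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    best <- list(evalue = Inf, ref = NA_character_)
    for (rn in names(te_refs)) {
      h <- scan_hits(candidates$sequence[i], te_refs[[rn]], p2, thr,
                     query_id = candidates$candidate_id[i], subject_id = rn)
      if (nrow(h) > 0 && min(h$evalue) < best$evalue)
        best <- list(evalue = min(h$evalue), ref = rn)
    }
    removed <- is.finite(best$evalue) && best$evalue <= max_evalue
    out[[i]] <- screen_result_row(
      candidates$candidate_id[i], "te", removed,
      if (removed) sprintf("TE match to %s (E=%.2g)", best$ref, best$evalue)
      else "no qualifying TE match",
      if (is.finite(best$evalue)) best$evalue else NA_real_)
  }
  do.call(rbind, out)
}

#' Screen candidates against organellar / rDNA references
#'
#' Similarity search with E <= `max_evalue` (default 0.01); a candidate is
#' removed when, for some single reference, the union of its hit intervals
#' on the candidate covers at least `min_coverage_pct` of the candidate
#' length. The union (not the best single hit) is used because fragmented
#' hits to the same reference still indicate shared origin.
#'
#' @param candidates candidate data frame.
#' @param refs named character vector of organelle or rDNA sequences.
#' @param max_evalue E-value threshold.
#' @param min_coverage_pct merged query-coverage threshold (default 80).
#' @param screen label recorded in the result (`"organelle"` or `"rdna"`).
#' @param params an [alignment_params()] object.
#' @return screen-result data frame.
#' @export
screen_organelle_rdna <- function(candidates, refs, max_evalue = 0.01,
                                  min_coverage_pct = 80,
                                  screen = "organelle",
                                  params = alignment_params()) {
  if (length(refs) == 0)
    return(screen_result_row(candidates$candidate_id, screen, FALSE,
                             "empty reference set"))
  thr <- hit_thresholds(max_evalue = max_evalue, min_identity_pct = 0,
                        min_query_coverage_pct = 0, max_hits = 1e7)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    clen <- nchar(candidates$sequence[i])
    best <- list(cov = 0, ref = NA_character_)
    for (rn in names(refs)) {
      h <- scan_hits(candidates$sequence[i], refs[[rn]], params, thr,
                     query_id = candidates$candidate_id[i], subject_id = rn)
      if (nrow(h) == 0) next
      cov <- 100 * interval_union_length(h$q_start, h$q_end) / clen
      if (cov > best$cov) best <- list(cov = cov, ref = rn)
    }
    removed <- best$cov >= min_coverage_pct
    out[[i]] <- screen_result_row(
      candidates$candidate_id[i], screen, removed,
      if (removed) sprintf("%s match to %s (merged cov=%.0f%%)", screen,
                           best$ref, best$cov)
      else sprintf("merged coverage %.0f%% below threshold", best$cov),
      NA_real_, best$cov)
  }
  do.call(rbind, out)
}

#' Contamination screening cascade
#'
#' Runs the screens in the fixed order coding -> TE -> organelle -> rDNA;
#' a candidate is removed for exactly one (the first matching) reason.
#' Known-library entries (column `known`) are prior knowledge and are never
#' removed.
#'
#' @param candidates candidate data frame.
#' @param refs list with any of `protein`, `te`, `organelle`, `rdna`
#'   (named character vectors; missing or empty sets are skipped).
#' @param params an [alignment_params()] object.
#' @return list: `results` (all screen rows, in cascade order), `retained`
#'   and `removed` candidate subsets.
#' @export
screen_cascade <- function(candidates, refs = list(),
                           params = alignment_params()) {
  results <- list()
  alive <- rep(TRUE, nrow(candidates))
  protected <- if (!is.null(candidates$known)) candidates$known else
    rep(FALSE, nrow(candidates))
  run_one <- function(fun, which_alive, ...) {
    sub <- candidates[which_alive, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    fun(sub, ...)
  }
  stages <- list(
    list(name = "coding", fun = function(sub) screen_coding(
      sub, refs$protein %||% character(0))),
    list(name = "te", fun = function(sub) screen_te(
      sub, refs$te %||% character(0), params = params)),
    list(name = "organelle", fun = function(sub) screen_organelle_rdna(
      sub, refs$organelle %||% character(0), screen = "organelle",
      params = params)),
    list(name = "rdna", fun = function(sub) screen_organelle_rdna(
      sub, refs$rdna %||% character(0), screen = "rdna", params = params)))
  for (st in stages) {
    idx <- which(alive)
    if (length(idx) == 0) break
    res <- st$fun(candidates[idx, , drop = FALSE])
    if (is.null(res)) next
    res$removed <- res$removed & !protected[idx]
    results[[length(results) + 1]] <- res
    alive[idx[res$removed]] <- FALSE
  }
  results <- if (length(results)) do.call(rbind, results) else
    screen_result_row(character(0), character(0), logical(0), character(0))
  rownames(results) <- NULL
  list(results = results,
       retained = candidates[alive, , drop = FALSE],
       removed = candidates[!alive, , drop = FALSE])
}
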