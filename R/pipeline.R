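# End-to-end orchestration: assembly -> candidates -> curation -> screens
# -> satellitome -> abundance, clustering metrics, chromosome specificity
# and nomenclature.

#' Run the full satellitome construction and characterization pipeline
#'
#' Detection (multi-round k-mer periodicity), consensus filtering,
#' two-pass deduplication, contamination screening, known-library merge,
#' MCL-based family collapse, short-read abundance and copy number,
#' long-read copy number (normalized by the long-read fold coverage of
#' 2C), copy-number cross-validation (discrepant families are excluded),
#' geometric-mean adjusted copy number, per-read clustering metrics,
#' per-chromosome counting with correspondence analysis and Mahalanobis
#' ranking, and nomenclature assignment.
#'
#' @param assembly named character vector of scaffold sequences
#'   (chromosomes named with `chromosome_prefix`).
#' @param short_reads character vector of short reads.
#' @param long_reads character vector of long reads (>= 10 kb).
#' @param constants a [genome_constants()] object.
#' @param known_library optional named character vector of known consensus
#'   sequences.
#' @param contaminant_refs optional list with `protein`, `te`, `organelle`,
#'   `rdna` reference sets.
#' @param rounds detection period ranges, see [run_rounds()].
#' @param params an [alignment_params()] object.
#' @param long_thresholds a [hit_thresholds()] object for long-read and
#'   assembly scans.
#' @param min_score minimum short-read mapping score.
#' @param suffixes optional named suffix annotations (family_id ->
#'   "cen"/"subtel").
#' @param chromosome_prefix scaffold-name prefix identifying chromosomes.
#' @param mtspr_threshold_bp clustering threshold (default 10,000).
#' @param verbose print stage progress.
#' @return object of class `"satellitome_run"`.
#' @export
run_satellitome <- function(assembly, short_reads, long_reads, constants,
                            known_library = NULL, contaminant_refs = NULL,
                            rounds = list(c(10, 200), c(150, 1000),
                                          c(800, 3000)),
                            params = alignment_params(),
                            long_thresholds = hit_thresholds(),
                            min_score = 30L, suffixes = NULL,
                            chromosome_prefix = "chr",
                            mtspr_threshold_bp = 10000,
                            verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("preprocessing assembly (%d scaffolds)", length(assembly))
  assembly <- preprocess_assembly(assembly)
  astats <- assembly_stats(assembly)

  say("detecting tandem arrays")
  candidates <- detect_satellites(assembly, rounds = rounds,
                                  params = params)
  say("  %d candidates with k-mer coverage >= 0.5", nrow(candidates))

  say("deduplicating (two passes, 80%% circular identity)")
  candidates <- dedup_identity(candidates, params = params)
  say("  %d candidates after dedup", nrow(candidates))

  screen_results <- NULL
  if (!is.null(contaminant_refs)) {
    say("screening contaminants (coding -> TE -> organelle -> rDNA)")
    sc <- screen_cascade(candidates, contaminant_refs, params)
    screen_results <- sc$results
    candidates <- sc$retained
    say("  %d candidates retained", nrow(candidates))
  }

  candidates <- merge_with_known(candidates, known_library)

  if (nrow(candidates) == 0) stop("no candidates survived curation")

  say("estimating candidate abundances for representative choice")
  cand_seqs <- setNames(candidates$sequence, candidates$candidate_id)
  # representative choice needs only relative abundances, so an evenly
  # spaced read subsample is enough; the satellitome abundances below
  # always use the full read set
  sub_reads <- if (length(short_reads) > 50000)
    short_reads[round(seq(1, length(short_reads), length.out = 50000))]
  else short_reads
  cand_map <- map_short_reads(sub_reads, cand_seqs, params, min_score)

  say("collapsing families (similarity graph + MCL)")
  families <- cluster_families(candidates,
                               abundance = cand_map$abundance_pct,
                               params = params)
  say("  %d families", nrow(families))

  say("mapping short reads to the satellitome")
  fam_seqs <- setNames(families$sequence, families$family_id)
  smap <- map_short_reads(short_reads, fam_seqs, params, min_score)
  families$illumina_mapped_reads <- smap$counts[families$family_id]
  families$illumina_abundance_pct <- smap$abundance_pct[families$family_id]
  families$illumina_cn <- cn_from_abundance(
    families$illumina_abundance_pct, constants, families$length,
    integer = FALSE)

  say("scanning long reads (%d reads)", length(long_reads))
  depth <- sum(nchar(long_reads)) / constants$two_c_size
  lr_hits <- lapply(fam_seqs, long_read_hits, long_reads = long_reads,
                    params = params, thresholds = long_thresholds)
  families$pacbio_cn <- vapply(lr_hits, nrow, numeric(1))[
    families$family_id] / depth

  cncv_out <- NULL
  families$discrepant <- FALSE
  if (sum(families$illumina_cn > 0 & families$pacbio_cn > 0) >= 3) {
    say("copy-number cross-validation")
    cncv_out <- cncv(data.frame(family = families$family_id,
                                illumina_cn = families$illumina_cn,
                                pacbio_cn = families$pacbio_cn))
    families$discrepant <- cncv_out$records$discrepant
    say("  R^2 = %.3f over %d families; %d discrepant", cncv_out$r_squared,
        cncv_out$n_used, sum(families$discrepant))
  }
  removed_families <- families[families$discrepant, , drop = FALSE]
  families <- families[!families$discrepant, , drop = FALSE]
  if (nrow(families) == 0) stop("all families discrepant in CNCV")

  families$acn <- adjusted_cn(pmax(families$illumina_cn, 1e-9),
                              pmax(families$pacbio_cn, 1e-9))
  families$final_abundance_pct <- abundance_from_cn(
    families$acn, families$length, constants)

  say("computing clustering metrics")
  cm <- do.call(rbind, lapply(families$family_id, function(f)
    family_metrics(lr_hits[[f]], family = f,
                   threshold_bp = mtspr_threshold_bp)))
  families$mcnpr <- cm$mcnpr
  families$mtspr <- cm$mtspr
  families$mcopr <- cm$mcopr
  families$clustered <- cm$clustered
  prs <- do.call(rbind, lapply(families$family_id, function(f) {
    t <- per_read_stats_table(lr_hits[[f]])
    if (nrow(t)) cbind(family = f, t) else NULL
  }))

  say("counting hits per chromosome")
  profiles <- lapply(families$family_id, function(f)
    count_hits_per_chromosome(fam_seqs[[f]], assembly, params,
                              long_thresholds, chromosome_prefix,
                              family = f))
  names(profiles) <- families$family_id
  M <- profile_matrix(profiles)
  families$unplaced_count <- attr(M, "unplaced")[families$family_id]
  families$fully_anchored <- families$unplaced_count == 0
  pcn <- lapply(profiles, call_pcn_and_specificity)
  families$pcn_chromosomes <- vapply(pcn, function(p)
    paste(p$pcn_chromosomes, collapse = ","), character(1))
  families$strict_level <- vapply(pcn, `[[`, character(1), "strict_level")

  ca <- NULL
  families$mahalanobis <- NA_real_
  if (nrow(M) >= 2 && ncol(M) >= 2 && sum(rowSums(M) > 0) >= 2) {
    say("correspondence analysis + Mahalanobis ranking")
    ca <- tryCatch(correspondence_analysis(M), error = function(e) NULL)
    if (!is.null(ca)) {
      md <- mahalanobis_from_origin(ca)
      families$mahalanobis <- md[families$family_id]
    }
  }

  say("assigning names")
  families <- assign_names(families, constants$species_prefix, suffixes)

  out <- structure(list(
    families = families,
    removed_families = removed_families,
    candidates = candidates,
    screen_results = screen_results,
    cncv = cncv_out,
    ca = ca,
    count_matrix = M,
    profiles = profiles,
    per_read_stats = prs,
    long_read_hits = lr_hits,
    short_read_map = smap,
    long_read_depth = depth,
    assembly_stats = astats,
    anchored_fraction = anchored_fraction(profiles),
    settings = list(rounds = rounds, params = unclass(params),
                    long_thresholds = unclass(long_thresholds),
                    min_score = min_score,
                    mtspr_threshold_bp = mtspr_threshold_bp,
                    two_c_size = constants$two_c_size),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "satellitome_run")
  say("done in %.1f s", out$elapsed)
  out
}

#' @export
print.satellitome_run <- function(x, ...) {
  f <- x$families
  cat(sprintf("satellitome run: %d families (%d excluded by CNCV)\n",
              nrow(f), nrow(x$removed_families)))
  cat(sprintf("  total final abundance: %.3f%% of the genome\n",
              sum(f$final_abundance_pct)))
  if (!is.null(x$cncv))
    cat(sprintf("  CNCV R^2 (log10 CNs): %.3f over %d families\n",
                x$cncv$r_squared, x$cncv$n_used))
  cat(sprintf("  clustered families (MTSPR > %d bp): %d\n",
              x$settings$mtspr_threshold_bp, sum(f$clustered)))
  cat(sprintf("  fully anchored in chromosomes: %.0f%%\n",
              100 * x$anchored_fraction))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' @export
summary.satellitome_run <- function(object, ...) {
  cols <- intersect(c("name", "length", "gc_pct", "illumina_cn",
                      "pacbio_cn", "acn", "final_abundance_pct", "mcnpr",
                      "mtspr", "mcopr", "clustered", "mahalanobis",
                      "strict_level", "fully_anchored"),
                    names(object$families))
  object$families[, cols]
}
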