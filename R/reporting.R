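# Reporting: nomenclature, cross-species homology, in-silico PCR, assembly
# statistics, assembly preprocessing and tabular/FASTA outputs.

#' Assign nomenclature names to a satellitome
#'
#' Families are ranked 1..N by decreasing final genomic abundance (ties:
#' longer monomer, then lexicographic sequence) and named
#' `<prefix>Sat<rank>-<length>[-<suffix>]`. An old-to-new mapping is
#' attached for families carrying known-library provenance.
#'
#' @param families family data frame with columns `sequence`, `length`,
#'   `final_abundance_pct`, optional `suffix` and `provenance`.
#' @param prefix species code (e.g. `"Ac"`).
#' @param suffixes optional named character vector (family_id -> `"cen"` /
#'   `"subtel"`) of user-supplied functional annotations.
#' @return the data frame ordered by rank with `rank` and `name` columns;
#'   attribute `"name_mapping"` maps original names to new names.
#' @export
assign_names <- function(families, prefix, suffixes = NULL) {
  stopifnot(nrow(families) >= 1)
  if (is.null(families$suffix)) families$suffix <- "none"
  if (!is.null(suffixes)) {
    idx <- match(names(suffixes), families$family_id)
    families$suffix[idx[!is.na(idx)]] <- suffixes[!is.na(idx)]
  }
  o <- order(-families$final_abundance_pct, -families$length,
             families$sequence)
  families <- families[o, , drop = FALSE]
  families$rank <- seq_len(nrow(families))
  families$name <- sprintf("%sSat%d-%d%s", prefix, families$rank,
                           families$length,
                           ifelse(families$suffix == "none", "",
                                  paste0("-", families$suffix)))
  mapping <- do.call(rbind, lapply(seq_len(nrow(families)), function(i) {
    prov <- families$provenance[i]
    if (is.null(prov) || is.na(prov) || prov == "") return(NULL)
    data.frame(original_name = strsplit(prov, ";", fixed = TRUE)[[1]],
               new_name = families$name[i], stringsAsFactors = FALSE)
  }))
  rownames(families) <- NULL
  attr(families, "name_mapping") <- mapping
  families
}

#' Cross-species satellitome homology
#'
#' Each family of one satellitome is compared to every family of the other
#' by rotation-invariant local alignment; a family is `"shared"` when some
#' partner reaches `min_identity_pct` identity with at least
#' `min_cov_shorter_pct` of the shorter consensus aligned, recording the
#' best such partner, and `"specific"` otherwise. The classification is
#' symmetric by construction.
#'
#' @param sat_a,sat_b named character vectors of consensus monomers.
#' @param params an [alignment_params()] object.
#' @param min_identity_pct identity floor for shared families (default 80).
#' @param min_cov_shorter_pct coverage floor on the shorter consensus
#'   (default 50).
#' @return list with data frames `a` and `b` (`family`, `status`,
#'   `partner`, `identity_pct`) and the full pair table `pairs`.
#' @export
cross_species_homology <- function(sat_a, sat_b,
                                   params = alignment_params(),
                                   min_identity_pct = 80,
                                   min_cov_shorter_pct = 50) {
  pairs <- expand.grid(a = names(sat_a), b = names(sat_b),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ca <- circular_align(sat_a[[pairs$a[i]]], sat_b[[pairs$b[i]]], params)
    data.frame(a = pairs$a[i], b = pairs$b[i],
               identity_pct = ca$identity_pct,
               coverage_shorter_pct = ca$coverage_shorter_pct,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, res)
  pairs$passes <- pairs$identity_pct >= min_identity_pct &
    pairs$coverage_shorter_pct >= min_cov_shorter_pct
  classify <- function(fams, key, other) {
    do.call(rbind, lapply(fams, function(f) {
      sub <- pairs[pairs[[key]] == f & pairs$passes, , drop = FALSE]
      if (nrow(sub) == 0)
        return(data.frame(family = f, status = "specific",
                          partner = NA_character_,
                          identity_pct = NA_real_, stringsAsFactors = FALSE))
      best <- sub[which.max(sub$identity_pct), ]
      data.frame(family = f, status = "shared", partner = best[[other]],
                 identity_pct = best$identity_pct, stringsAsFactors = FALSE)
    }))
  }
  list(a = classify(names(sat_a), "a", "b"),
       b = classify(names(sat_b), "b", "a"),
       pairs = pairs)
}

#' In-silico PCR product prediction
#'
#' The forward primer is matched on the plus strand and the reverse
#' primer's reverse complement downstream on the plus strand (plus the
#' symmetric case with the roles swapped, i.e. products read from the
#' minus strand). Product length is the distance between the two primer
#' 5' ends, inclusive. In circular mode the doubled template is searched
#' and products longer than the template are discarded.
#'
#' @param template template sequence.
#' @param forward,reverse primer sequences, 5'->3', each >= 15 bp.
#' @param max_mismatches mismatches tolerated per primer site (default 0).
#' @param circular treat the template as circular (e.g. a tandem monomer).
#' @param max_product longest product reported (default 20 kb).
#' @return sorted integer vector of product lengths (possibly empty).
#' @export
in_silico_pcr <- function(template, forward, reverse, max_mismatches = 0L,
                          circular = FALSE, max_product = 20000L) {
  check_dna(template, "template")
  if (nchar(forward) < 15 || nchar(reverse) < 15)
    stop("primers must be at least 15 bp for PCR mode")
  L <- nchar(template)
  tpl <- if (circular) paste0(template, template) else template
  site_starts <- function(p) .primer_match_cpp(tpl, toupper(p),
                                               as.integer(max_mismatches))
  products <- integer(0)
  combos <- list(c(forward, reverse), c(reverse, forward))
  for (cb in combos) {
    p1 <- cb[[1]]; p2 <- cb[[2]]
    s1 <- site_starts(p1)                      # plus-strand sites of p1
    s2 <- site_starts(revcomp(toupper(p2)))    # minus-strand sites of p2
    if (length(s1) == 0 || length(s2) == 0) next
    e2 <- s2 + nchar(p2) - 1L                  # p2 5' end on plus strand
    for (a in s1) {
      ok <- s2 > (a + nchar(p1) - 1L)          # non-overlapping, facing
      len <- e2[ok] - a + 1L
      len <- len[len <= max_product]
      if (circular) {
        len <- len[a <= L & len <= L]
      }
      products <- c(products, len)
    }
  }
  sort(products)
}

#' Assembly summary statistics
#'
#' Standard N50/L50 over scaffold lengths and GC content over non-N bases.
#'
#' @param assembly named character vector of scaffold sequences, or a path
#'   to a FASTA file.
#' @return list: `gc_pct`, `n_scaffolds`, `n50_bp`, `l50_count`,
#'   `total_bp`.
#' @export
assembly_stats <- function(assembly) {
  if (is.character(assembly) && length(assembly) == 1 &&
      file.exists(assembly))
    assembly <- read_seqs(assembly)
  lens <- unname(nchar(assembly))
  stopifnot(length(lens) >= 1)
  o <- sort(lens, decreasing = TRUE)
  csum <- cumsum(o)
  i50 <- which(csum >= sum(o) / 2)[1]
  counts <- Reduce(`+`, lapply(assembly, tabulate_bases))
  informative <- sum(counts[c("A", "C", "G", "T")])
  if (informative == 0) {
    warning("no informative (non-N) bases; GC reported as 0")
    gc <- 0
  } else gc <- 100 * sum(counts[c("G", "C")]) / informative
  list(gc_pct = gc, n_scaffolds = length(lens), n50_bp = o[i50],
       l50_count = i50, total_bp = sum(lens))
}

#' Normalize an assembly for analysis
#'
#' Soft-masked (lowercase) bases are unmasked and every character outside
#' A/C/G/T becomes N; sequence lengths are preserved exactly.
#'
#' @param seqs named character vector of scaffold sequences.
#' @return normalized named character vector.
#' @export
preprocess_assembly <- function(seqs) {
  out <- toupper(seqs)
  out <- gsub("[^ACGT]", "N", out)
  names(out) <- names(seqs)
  out
}

#' Write the full report set of a satellitome run
#'
#' Satellitome FASTA (headers name|suffix|provenance), the master
#' per-family TSV, per-read clustering statistics, the chromosome count
#' matrix, and a run log with thresholds and seeds.
#'
#' @param run a `satellitome_run` object from [run_satellitome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- run$families
  seqs <- setNames(fam$sequence,
                   sprintf("%s|%s|%s", fam$name, fam$suffix,
                           ifelse(is.na(fam$provenance) |
                                  fam$provenance == "", "-",
                                  fam$provenance)))
  write_fasta(seqs, file.path(dir, "satellitome.fasta"))
  write.table(fam, file.path(dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(run$per_read_stats))
    write.table(run$per_read_stats, file.path(dir, "per_read_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$count_matrix)) {
    M <- cbind(as.data.frame(run$count_matrix),
               unplaced = attr(run$count_matrix, "unplaced"))
    write.table(cbind(family = rownames(M), M),
                file.path(dir, "chromosome_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  log_lines <- c(sprintf("satellitome run log - %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("families: %d", nrow(fam)),
                 sprintf("thresholds: %s",
                         paste(deparse(run$settings), collapse = " ")))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
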