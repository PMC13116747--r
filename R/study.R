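# The canonical synthetic study: five planted satDNA families with
# contrasting monomer lengths (40-2500 bp), copy numbers (50-5000),
# chromosomal distributions (1 to 8 of 8 chromosomes) and clustering
# levels, plus planted organelle/rDNA/TE/coding contaminants, on a ~5 Mb
# eight-chromosome genome with unplaced scaffolds. These defaults are the
# study conditions the validation suite measures against; they are not
# tuning knobs.

aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(aa_alphabet, n, replace = TRUE),
                                    collapse = "")

# Reverse-translate an amino-acid sequence (first codon per residue).
reverse_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(res, function(r) names(gc)[match(r, gc)], character(1)),
        collapse = "")
}

#' Synthetic contaminant reference sets
#'
#' Random stand-ins for the reference databases used by the screens:
#' protein references (amino acids), TE nucleotide references, one
#' organelle-like and one rDNA-like reference. Deterministic under `seed`.
#'
#' @param seed integer seed.
#' @return list: `protein`, `te`, `organelle`, `rdna` (named character
#'   vectors).
#' @export
synthetic_contaminant_refs <- function(seed = 1L) {
  with_seed(seed, list(
    protein = setNames(c(random_protein(150), random_protein(200)),
                       c("prot1", "prot2")),
    te = setNames(c(random_dna(3000, 0.42), random_dna(2500, 0.40)),
                  c("te1", "te2")),
    organelle = setNames(random_dna(8000, 0.37), "organelle1"),
    rdna = setNames(random_dna(4000, 0.55), "rdna1")))
}

#' Family specifications of the canonical synthetic study
#'
#' Five families spanning the design space: an abundant subtelomeric-like
#' 377 bp family on all chromosomes (with unplaced copies), a short 40 bp
#' family enriched 4:1 on one chromosome, a 2500 bp family strictly
#' confined to chromosome 1, a 750 bp family on two chromosomes, and a
#' dispersed 180 bp family planted as many short (4-copy) arrays that
#' never reach the 10 kb clustering threshold.
#'
#' @param chromosomes chromosome names (default chr1..chr8).
#' @return list of [family_spec()] objects.
#' @export
study_family_specs <- function(chromosomes = paste0("chr", 1:8)) {
  all_chr <- setNames(rep(250L, length(chromosomes)), chromosomes)
  f40 <- setNames(rep(400L, length(chromosomes)), chromosomes)
  f40[["chr4"]] <- 1600L
  disp <- setNames(rep(12L, length(chromosomes)), chromosomes)
  list(
    family_spec("SF377", 377, 0.40, all_chr, unplaced_copies = 150,
                substitution_rate = 0.05, indel_rate = 0.002,
                n_arrays_per_chromosome = 2, suffix = "subtel"),
    family_spec("SF40", 40, 0.35, f40, unplaced_copies = 400,
                substitution_rate = 0.02, indel_rate = 0.001),
    family_spec("SF2500", 2500, 0.42, c(chr1 = 50L),
                substitution_rate = 0.02, indel_rate = 0.001,
                n_arrays_per_chromosome = 2),
    family_spec("SF750", 750, 0.36, c(chr2 = 200L, chr6 = 200L),
                substitution_rate = 0.03, indel_rate = 0.002),
    family_spec("SF180", 180, 0.38, disp,
                substitution_rate = 0.02, indel_rate = 0.001,
                n_arrays_per_chromosome = 3))
}

# Contaminant plants: tandemized segments of the reference sets, so the
# detector picks them up and the screens must remove them.
study_contaminant_specs <- function(refs) {
  cds <- reverse_translate(substr(refs$protein[["prot1"]], 1, 100))
  cds_monomer <- paste0(cds, random_dna(150, 0.38))
  list(
    family_spec("CONT_ORG", 300, monomer = substr(refs$organelle[[1]],
                                                  1001, 1300),
                per_chromosome_copies = c(chr3 = 40L),
                substitution_rate = 0.01, indel_rate = 0,
                is_contaminant = TRUE),
    family_spec("CONT_RDNA", 300, monomer = substr(refs$rdna[[1]],
                                                   501, 800),
                per_chromosome_copies = c(chr5 = 50L),
                substitution_rate = 0.01, indel_rate = 0,
                is_contaminant = TRUE),
    family_spec("CONT_TE", 400, monomer = substr(refs$te[["te1"]],
                                                 501, 900),
                per_chromosome_copies = c(chr7 = 40L),
                substitution_rate = 0.01, indel_rate = 0,
                is_contaminant = TRUE),
    family_spec("CONT_CDS", nchar(cds_monomer), monomer = cds_monomer,
                per_chromosome_copies = c(chr8 = 40L),
                substitution_rate = 0.01, indel_rate = 0,
                is_contaminant = TRUE))
}

#' Build the canonical synthetic study
#'
#' Generates the eight-chromosome genome with the five planted families
#' and four planted contaminants, uniform-coverage short reads (10x,
#' 150 bp) and length-filtered long reads (15x, lognormal mean 25 kb,
#' floor 10 kb), the contaminant reference sets, and the genome constants
#' (2C size = total genome length, so planted copies are copies per 2C).
#'
#' @param seed integer master seed; genome, contaminants and reads use
#'   derived sub-seeds.
#' @param short_coverage,long_coverage fold coverages of the read sets.
#' @return list: `specs`, `contaminant_specs`, `refs`, `genome`, `truth`,
#'   `short_reads`, `long_reads`, `constants`, `read_params`,
#'   `true_copies` (named planted copies per family incl. unplaced).
#' @export
synthetic_study <- function(seed = 1L, short_coverage = 10,
                            long_coverage = 15) {
  chroms <- setNames(rep(600000L, 8), paste0("chr", 1:8))
  refs <- synthetic_contaminant_refs(seed + 11L)
  specs <- study_family_specs(names(chroms))
  cspecs <- with_seed(seed + 13L, study_contaminant_specs(refs))
  g <- build_genome(c(specs, cspecs), chroms, seed = seed + 17L)
  rp <- read_sim_params(short_coverage = short_coverage,
                        long_coverage = long_coverage, seed = seed + 19L)
  true_copies <- vapply(specs, function(sp)
    sum(sp$per_chromosome_copies) + sp$unplaced_copies, numeric(1))
  names(true_copies) <- vapply(specs, `[[`, character(1), "family_id")
  list(specs = specs, contaminant_specs = cspecs, refs = refs,
       genome = g$genome, truth = g$truth,
       short_reads = simulate_short_reads(g$genome, rp),
       long_reads = simulate_long_reads(g$genome, rp),
       constants = genome_constants(sum(nchar(g$genome)), "Sy"),
       read_params = rp, true_copies = true_copies)
}

#' Match recovered families to planted truth
#'
#' Each true monomer is matched to the recovered family with the highest
#' rotation-invariant identity, reporting identity and consensus/monomer
#' length ratio.
#'
#' @param families family data frame (columns `family_id` or `name`, and
#'   `sequence`).
#' @param true_monomers named character vector of planted monomers.
#' @param params an [alignment_params()] object.
#' @return data frame: truth_id, family, identity_pct, length_ratio.
#' @export
match_families_to_truth <- function(families, true_monomers,
                                    params = alignment_params()) {
  key <- families$name %||% families$family_id
  do.call(rbind, lapply(names(true_monomers), function(tn) {
    al <- lapply(families$sequence, function(s)
      circular_align(true_monomers[[tn]], s, params))
    # identity alone is meaningless across length mismatches (a short
    # perfect local match scores 100%); weight by aligned coverage
    score <- vapply(al, function(a)
      a$identity_pct * a$coverage_shorter_pct / 100, numeric(1))
    best <- which.max(score)
    data.frame(truth_id = tn, family = key[best],
               identity_pct = al[[best]]$identity_pct,
               coverage_shorter_pct = al[[best]]$coverage_shorter_pct,
               length_ratio = nchar(families$sequence[best]) /
                 nchar(true_monomers[[tn]]),
               stringsAsFactors = FALSE)
  }))
}
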