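# Synthetic genomes, reads and contaminants with ground-truth manifests.
# Everything is generated under an explicit seed through a scoped RNG, so
# the same inputs are bit-reproducible and never disturb the caller's RNG.

#' Specification of one planted satDNA family
#'
#' @param family_id identifier.
#' @param monomer_length monomer length in bp (>= 10).
#' @param gc_fraction monomer GC fraction in \[0, 1\].
#' @param per_chromosome_copies named integer vector, copies per chromosome.
#' @param unplaced_copies copies placed on an unplaced scaffold.
#' @param substitution_rate per-base substitution probability per copy,
#'   in \[0, 0.3\].
#' @param indel_rate per-base indel initiation probability per copy, in
#'   \[0, 0.05\]; indel lengths are geometric (mean 2).
#' @param n_arrays_per_chromosome number of contiguous arrays the copies of
#'   a chromosome are split into.
#' @param suffix functional annotation: `"none"`, `"cen"` or `"subtel"`.
#' @param monomer optional explicit monomer sequence (otherwise drawn
#'   randomly at genome build time); used to plant contaminant-derived
#'   arrays.
#' @param is_contaminant logical; marks planted contaminant arrays in the
#'   truth manifest.
#' @return an object of class `"family_spec"`.
#' @export
family_spec <- function(family_id, monomer_length, gc_fraction = 0.38,
                        per_chromosome_copies = integer(),
                        unplaced_copies = 0L,
                        substitution_rate = 0.02, indel_rate = 0.002,
                        n_arrays_per_chromosome = 1L,
                        suffix = c("none", "cen", "subtel"),
                        monomer = NULL, is_contaminant = FALSE) {
  suffix <- match.arg(suffix)
  stopifnot(monomer_length >= 10, gc_fraction >= 0, gc_fraction <= 1,
            substitution_rate >= 0, substitution_rate <= 0.3,
            indel_rate >= 0, indel_rate <= 0.05,
            sum(per_chromosome_copies) + unplaced_copies >= 1,
            n_arrays_per_chromosome >= 1)
  if (!is.null(monomer)) stopifnot(nchar(monomer) == monomer_length)
  structure(list(family_id = family_id,
                 monomer_length = as.integer(monomer_length),
                 gc_fraction = gc_fraction,
                 per_chromosome_copies = per_chromosome_copies,
                 unplaced_copies = as.integer(unplaced_copies),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 n_arrays_per_chromosome = as.integer(n_arrays_per_chromosome),
                 suffix = suffix, monomer = monomer,
                 is_contaminant = isTRUE(is_contaminant)),
            class = "family_spec")
}

#' Read-simulation parameters
#'
#' @param short_read_length short-read length in bp.
#' @param short_coverage short-read fold coverage of the genome.
#' @param short_error_rate per-base substitution error rate of short reads.
#' @param long_coverage long-read fold coverage.
#' @param long_read_mean target mean long-read length in bp (lognormal).
#' @param long_read_sdlog lognormal sdlog of long-read lengths.
#' @param long_read_min minimum emitted long-read length; reads below this
#'   floor are excluded (>= 10,000 bp).
#' @param long_error_rate per-base error rate of long reads in \[0, 0.05\]
#'   (90% substitutions, 10% single-base indels).
#' @param seed integer seed controlling all read sampling.
#' @return an object of class `"read_sim_params"`.
#' @export
read_sim_params <- function(short_read_length = 150L, short_coverage = 10,
                            short_error_rate = 0.002,
                            long_coverage = 15, long_read_mean = 25000,
                            long_read_sdlog = 0.5, long_read_min = 10000L,
                            long_error_rate = 0.01, seed = 1L) {
  stopifnot(short_read_length >= 20, short_coverage >= 0,
            long_read_min >= 10000, long_error_rate >= 0,
            long_error_rate <= 0.05, long_read_mean >= long_read_min)
  structure(list(short_read_length = as.integer(short_read_length),
                 short_coverage = short_coverage,
                 short_error_rate = short_error_rate,
                 long_coverage = long_coverage,
                 long_read_mean = long_read_mean,
                 long_read_sdlog = long_read_sdlog,
                 long_read_min = as.integer(long_read_min),
                 long_error_rate = long_error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a random monomer with a target GC fraction
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2, so the expected GC equals
#' `gc_fraction`. Deterministic under `seed`.
#'
#' @param length monomer length (>= 10).
#' @param gc_fraction target GC fraction in \[0, 1\].
#' @param seed integer seed.
#' @return a DNA string.
#' @export
make_monomer <- function(length, gc_fraction, seed) {
  if (length < 10) stop("monomer length must be >= 10")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  with_seed(seed, random_dna(length, gc_fraction))
}

# One mutated copy of a monomer: i.i.d. substitutions plus geometric-length
# indels. Operates on a character vector, returns a string.
mutate_copy <- function(monomer_chars, substitution_rate, indel_rate) {
  n <- length(monomer_chars)
  x <- monomer_chars
  nsub <- rbinom(1, n, substitution_rate)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), x[p])
      x[p] <- alt[sample.int(3, 1)]
    }
  }
  nind <- rbinom(1, n, indel_rate)
  if (nind > 0) {
    pos <- sort(sample.int(length(x), nind), decreasing = TRUE)
    for (p in pos) {
      len <- rgeom(1, 0.5) + 1L
      if (runif(1) < 0.5) { # insertion after p
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        x <- append(x, ins, after = p)
      } else {             # deletion starting at p
        x <- x[-(p:min(length(x), p + len - 1L))]
      }
    }
  }
  paste(x, collapse = "")
}

# Build one tandem array of mutated copies; returns list(seq, n_copies).
build_array <- function(monomer, n_copies, substitution_rate, indel_rate) {
  mc <- strsplit(monomer, "", fixed = TRUE)[[1]]
  copies <- vapply(seq_len(n_copies), function(i)
    mutate_copy(mc, substitution_rate, indel_rate), character(1))
  list(seq = paste(copies, collapse = ""), n_copies = n_copies)
}

split_copies <- function(total, n_arrays) {
  base <- total %/% n_arrays
  extra <- total %% n_arrays
  counts <- rep(base, n_arrays) + c(rep(1L, extra), rep(0L, n_arrays - extra))
  counts[counts > 0]
}

#' Build a synthetic genome with planted tandem arrays
#'
#' Each family is planted as `n_arrays_per_chromosome` contiguous arrays of
#' mutated copies on the chromosomes named in `per_chromosome_copies`;
#' families with `unplaced_copies > 0` additionally get one array on an
#' automatically created unplaced scaffold (`scaffold_<i>`). Returns the
#' genome and a complete ground-truth manifest.
#'
#' @param specs list of [family_spec()] objects (contaminant plants
#'   included).
#' @param chromosome_lengths named integer vector (names become scaffold
#'   names; chromosome scaffolds should use the `"chr"` prefix).
#' @param background_gc GC fraction of the random background sequence.
#' @param unplaced_margin background padding added around unplaced arrays.
#' @param seed integer seed.
#' @return list with `genome` (named character vector) and `truth` (list:
#'   `chromosome_lengths`, `array_intervals`, `contaminant_intervals`,
#'   `true_monomers`).
#' @export
build_genome <- function(specs, chromosome_lengths, background_gc = 0.35,
                         unplaced_margin = 10000L, seed = 1L) {
  stopifnot(length(chromosome_lengths) >= 1,
            !is.null(names(chromosome_lengths)))
  with_seed(seed, {
    # draw monomers first so they are stable regardless of placement
    monomers <- lapply(specs, function(sp)
      sp$monomer %||% random_dna(sp$monomer_length, sp$gc_fraction))
    names(monomers) <- vapply(specs, `[[`, character(1), "family_id")

    # plan arrays per chromosome
    plan <- list()
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      for (chrom in names(sp$per_chromosome_copies)) {
        total <- sp$per_chromosome_copies[[chrom]]
        if (total <= 0) next
        if (!chrom %in% names(chromosome_lengths))
          stop("unknown chromosome in spec: ", chrom)
        for (nc in split_copies(total, sp$n_arrays_per_chromosome))
          plan[[length(plan) + 1]] <- list(family = si, chrom = chrom,
                                           n_copies = nc)
      }
    }

    intervals <- list()
    genome <- character(0)
    for (chrom in names(chromosome_lengths)) {
      clen <- chromosome_lengths[[chrom]]
      items <- Filter(function(p) p$chrom == chrom, plan)
      segs <- lapply(items, function(it) {
        sp <- specs[[it$family]]
        build_array(monomers[[it$family]], it$n_copies,
                    sp$substitution_rate, sp$indel_rate)
      })
      seglen <- vapply(segs, function(s) nchar(s$seq), numeric(1))
      if (sum(seglen) >= clen * 0.95)
        stop("infeasible packing on ", chrom,
             ": planted arrays exceed 95% of chromosome length")
      bg <- random_dna(clen, background_gc)
      if (length(segs) > 0) {
        # random-gap placement: segments in random order, separated by
        # exponential gaps rescaled to the free background (min gap 500 bp
        # so neighbouring arrays stay distinct)
        ns <- length(segs)
        min_gap <- 500L
        free <- clen - sum(seglen) - min_gap * (ns + 1L)
        if (free < 0) stop("infeasible packing on ", chrom)
        ord <- sample.int(ns)
        gw <- rexp(ns + 1L)
        gaps <- min_gap + floor(gw / sum(gw) * free)
        seq_parts <- character(0)
        pos <- 1L
        for (j in seq_len(ns)) {
          it <- items[[ord[j]]]; sg <- segs[[ord[j]]]
          st <- pos + gaps[j]
          seq_parts <- c(seq_parts, substr(bg, pos, st - 1L), sg$seq)
          pos <- st + nchar(sg$seq)
          intervals[[length(intervals) + 1]] <- data.frame(
            chromosome = chrom, start = st, end = pos - 1L,
            family_id = specs[[it$family]]$family_id,
            n_copies = sg$n_copies,
            is_contaminant = specs[[it$family]]$is_contaminant,
            stringsAsFactors = FALSE)
        }
        seq_parts <- c(seq_parts, substr(bg, pos, clen))
        genome[[chrom]] <- paste(seq_parts, collapse = "")
      } else {
        genome[[chrom]] <- bg
      }
    }

    # unplaced scaffolds, one per family that requests them
    sc_i <- 0L
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      if (sp$unplaced_copies <= 0) next
      sc_i <- sc_i + 1L
      arr <- build_array(monomers[[si]], sp$unplaced_copies,
                         sp$substitution_rate, sp$indel_rate)
      pad1 <- random_dna(unplaced_margin, background_gc)
      pad2 <- random_dna(unplaced_margin, background_gc)
      nm <- sprintf("scaffold_%d", sc_i)
      genome[[nm]] <- paste0(pad1, arr$seq, pad2)
      intervals[[length(intervals) + 1]] <- data.frame(
        chromosome = nm, start = unplaced_margin + 1L,
        end = unplaced_margin + nchar(arr$seq),
        family_id = sp$family_id, n_copies = arr$n_copies,
        is_contaminant = sp$is_contaminant, stringsAsFactors = FALSE)
    }

    ints <- if (length(intervals)) do.call(rbind, intervals) else
      data.frame(chromosome = character(), start = integer(),
                 end = integer(), family_id = character(),
                 n_copies = integer(), is_contaminant = logical())
    truth <- list(
      chromosome_lengths = vapply(genome, nchar, numeric(1)),
      array_intervals = ints[!ints$is_contaminant, , drop = FALSE],
      contaminant_intervals = ints[ints$is_contaminant, , drop = FALSE],
      true_monomers = monomers)
    list(genome = genome, truth = truth)
  })
}

apply_substitutions <- function(reads, n_err) {
  if (n_err <= 0) return(reads)
  lens <- nchar(reads)
  # uniform over all bases via cumulative offsets (length-weighted draws
  # through weighted sample() would be quadratic here)
  cum <- c(0, cumsum(as.numeric(lens)))
  off <- floor(runif(n_err) * cum[length(cum)])
  ridx <- findInterval(off, cum, rightmost.closed = FALSE, left.open = FALSE)
  pos <- as.integer(off - cum[ridx] + 1)
  alt <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
  by_read <- split(seq_len(n_err), ridx)
  for (r in names(by_read)) {
    i <- as.integer(r)
    x <- strsplit(reads[[i]], "", fixed = TRUE)[[1]]
    for (e in by_read[[r]]) {
      p <- pos[e]
      if (x[p] == alt[e]) x[p] <- c(A = "C", C = "A", G = "T", T = "G",
                                    N = "A")[[x[p]]]
      else x[p] <- alt[e]
    }
    reads[[i]] <- paste(x, collapse = "")
  }
  reads
}

#' Simulate uniform-coverage short reads
#'
#' Reads are sampled uniformly over all scaffolds (probability proportional
#' to scaffold length), half on each strand, with i.i.d. substitution
#' errors. The read count is `round(coverage * genome_size / read_length)`.
#' Read names encode the true origin as `"r<i> <scaffold>:<start>-<end>:<strand>"`.
#'
#' @param genome named character vector of scaffold sequences.
#' @param params a [read_sim_params()] object.
#' @return named character vector of reads (possibly empty).
#' @export
simulate_short_reads <- function(genome, params = read_sim_params()) {
  rl <- params$short_read_length
  glen <- vapply(genome, nchar, numeric(1))
  usable <- glen >= rl
  if (!any(usable)) stop("no scaffold is at least one read length long")
  n_reads <- round(params$short_coverage * sum(glen) / rl)
  if (n_reads == 0) return(setNames(character(0), character(0)))
  with_seed(params$seed, {
    w <- pmax(glen - rl + 1, 0)
    sc <- sample(names(genome), n_reads, replace = TRUE, prob = w)
    start <- floor(runif(n_reads) * (glen[sc] - rl + 1)) + 1L
    seqs <- character(n_reads)
    for (nm in unique(sc)) {
      idx <- which(sc == nm)
      seqs[idx] <- substring(genome[[nm]], start[idx], start[idx] + rl - 1L)
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    n_err <- rbinom(1, n_reads * rl, params$short_error_rate)
    seqs <- apply_substitutions(seqs, n_err)
    names(seqs) <- sprintf("r%06d %s:%d-%d:%s", seq_len(n_reads), sc,
                           start, start + rl - 1L, strand)
    seqs
  })
}

mutate_long_read <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  nerr <- rbinom(1, n, error_rate)
  if (nerr == 0) return(seq)
  pos <- sample.int(n, nerr)
  type <- sample(c("sub", "ins", "del"), nerr, replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
  subs <- pos[type == "sub"]
  if (length(subs)) {
    alt <- sample(c("A", "C", "G", "T"), length(subs), replace = TRUE)
    same <- x[subs] == alt
    alt[same] <- c(A = "C", C = "A", G = "T", T = "G",
                   N = "A")[x[subs][same]]
    x[subs] <- alt
  }
  dels <- pos[type == "del"]
  inspos <- pos[type == "ins"]
  if (length(inspos)) {
    insbase <- sample(c("A", "C", "G", "T"), length(inspos), replace = TRUE)
    # build via splitting: mark insertions by pasting onto the base
    x[inspos] <- paste0(x[inspos], insbase)
  }
  if (length(dels)) x <- x[-dels]
  paste(x, collapse = "")
}

#' Simulate length-filtered long reads
#'
#' Read lengths are lognormal with `meanlog` chosen so the untruncated mean
#' equals `long_read_mean`, resampled until above the `long_read_min` floor
#' (no read below the floor is ever emitted, mirroring a >= 10 kb HiFi
#' length filter). Reads are drawn until the target fold coverage in bases
#' is reached; errors are 90% substitutions and 10% single-base indels.
#'
#' @param genome named character vector of scaffold sequences.
#' @param params a [read_sim_params()] object.
#' @return named character vector of reads; names encode the true origin.
#' @export
simulate_long_reads <- function(genome, params = read_sim_params()) {
  glen <- vapply(genome, nchar, numeric(1))
  target <- params$long_coverage * sum(glen)
  meanlog <- log(params$long_read_mean) - params$long_read_sdlog^2 / 2
  maxlen <- max(glen)
  if (maxlen < params$long_read_min)
    stop("no scaffold is at least long_read_min bp long")
  with_seed(params$seed, {
    reads <- character(0); origins <- character(0)
    total <- 0
    while (total < target) {
      len <- Inf
      while (len < params$long_read_min || len > maxlen)
        len <- round(rlnorm(1, meanlog, params$long_read_sdlog))
      w <- pmax(glen - len + 1, 0)
      if (all(w == 0)) next
      nm <- sample(names(genome), 1, prob = w)
      st <- floor(runif(1) * (glen[[nm]] - len + 1)) + 1L
      rd <- substr(genome[[nm]], st, st + len - 1L)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") rd <- revcomp(rd)
      rd <- mutate_long_read(rd, params$long_error_rate)
      reads <- c(reads, rd)
      origins <- c(origins, sprintf("%s:%d-%d:%s", nm, st, st + len - 1L,
                                    strand))
      total <- total + len
    }
    names(reads) <- sprintf("lr%05d %s", seq_along(reads), origins)
    reads
  })
}

#' Write a ground-truth manifest
#'
#' Array and contaminant intervals as TSV; monomers as FASTA; the full
#' manifest additionally as JSON when jsonlite is available.
#'
#' @param truth the `truth` element of [build_genome()].
#' @param dir output directory (created if needed).
#' @export
write_truth_manifest <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truth$array_intervals, file.path(dir, "array_intervals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$contaminant_intervals,
              file.path(dir, "contaminant_intervals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(unlist(truth$true_monomers),
              file.path(dir, "true_monomers.fasta"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(chromosome_lengths = as.list(truth$chromosome_lengths),
           array_intervals = truth$array_intervals,
           contaminant_intervals = truth$contaminant_intervals,
           true_monomers = as.list(unlist(truth$true_monomers))),
      file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
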