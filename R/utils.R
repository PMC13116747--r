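# Shared helpers: seeded RNG scoping, sequence utilities, interval algebra,
# FASTA/FASTQ I/O thin wrappers around Biostrings.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generators in the package route through
# this so that global reproducibility is never disturbed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A, C, G, T, N (case kept).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) .revcomp_cpp(x)

#' GC fraction of a sequence
#'
#' Computed over non-N bases; returns `NA` if no informative base exists.
#'
#' @param x a single DNA string.
#' @return numeric in \[0, 1\], or `NA`.
#' @export
gc_fraction <- function(x) {
  counts <- tabulate_bases(x)
  inf <- sum(counts[c("A", "C", "G", "T")])
  if (inf == 0) return(NA_real_)
  sum(counts[c("G", "C")]) / inf
}

tabulate_bases <- function(x) {
  bs <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  tb <- table(bs)
  keep <- intersect(names(tb), names(out))
  out[keep] <- tb[keep]
  out["N"] <- out["N"] + sum(tb[!names(tb) %in% names(out)])
  out
}

# Total length of the union of closed integer intervals [starts, ends].
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- starts[1]; cur_e <- ends[1]
  if (length(starts) > 1) for (i in 2:length(starts)) {
    if (starts[i] <= cur_e + 1L && starts[i] >= cur_s) {
      cur_e <- max(cur_e, ends[i])
    } else if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Read sequences from FASTA/FASTQ
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return named character vector of sequences.
#' @export
read_seqs <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- if (format == "fasta") Biostrings::readDNAStringSet(path)
        else Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), names(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads to FASTQ with uniform placeholder qualities
#'
#' Simulated reads carry no base-quality model, so every base gets quality
#' "I" (Phred 40).
#'
#' @param seqs named character vector of reads.
#' @param path output path.
#' @export
write_fastq <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
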