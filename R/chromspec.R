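# Chromosome specificity: per-chromosome hit counting, correspondence
# analysis of the log-transformed count matrix, Mahalanobis ranking from
# the CA origin, peak-copy-number chromosomes and anchoring status.

#' Count a family's hits per chromosome
#'
#' The consensus is scanned against every scaffold; hits on scaffolds
#' whose name starts with `chromosome_prefix` are tallied per chromosome,
#' all other hits are tallied as unplaced.
#'
#' @param family_seq consensus monomer.
#' @param assembly named character vector of scaffold sequences.
#' @param params an [alignment_params()] object.
#' @param thresholds a [hit_thresholds()] object (defaults E <= 1e-5,
#'   identity >= 70%, query coverage >= 70%).
#' @param chromosome_prefix scaffold-name prefix identifying chromosomes.
#' @param family family name recorded in the profile.
#' @return object of class `"chromosome_profile"`: `family`, `counts`
#'   (named integer over all chromosome scaffolds), `unplaced_count`,
#'   `fully_anchored`.
#' @export
count_hits_per_chromosome <- function(family_seq, assembly,
                                      params = alignment_params(),
                                      thresholds = hit_thresholds(),
                                      chromosome_prefix = "chr",
                                      family = "family") {
  is_chrom <- startsWith(names(assembly), chromosome_prefix)
  counts <- setNames(integer(sum(is_chrom)), names(assembly)[is_chrom])
  unplaced <- 0L
  for (nm in names(assembly)) {
    h <- scan_hits(family_seq, assembly[[nm]], params, thresholds,
                   subject_id = nm)
    if (startsWith(nm, chromosome_prefix)) counts[[nm]] <- nrow(h)
    else unplaced <- unplaced + nrow(h)
  }
  structure(list(family = family, counts = counts,
                 unplaced_count = unplaced,
                 fully_anchored = unplaced == 0L),
            class = "chromosome_profile")
}

#' Assemble profiles into a families x chromosomes count matrix
#'
#' @param profiles list of [count_hits_per_chromosome()] profiles.
#' @return integer matrix (rownames = families) with an `unplaced`
#'   attribute vector; the unplaced counts are never part of the matrix.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  M <- do.call(rbind, lapply(profiles, function(p) p$counts))
  rownames(M) <- vapply(profiles, function(p) p$family, character(1))
  attr(M, "unplaced") <- setNames(
    vapply(profiles, function(p) p$unplaced_count, numeric(1)),
    rownames(M))
  M
}

#' Correspondence analysis of a log-transformed count matrix
#'
#' Counts x are replaced by ln(1 + x) to damp multiplicative copy-number
#' differences between chromosomes, then standard CA is applied: with
#' P the matrix normalized to sum 1 and r, c its margins, the SVD of
#' `diag(r)^-1/2 (P - r c') diag(c)^-1/2` gives principal coordinates;
#' the first two dimensions are retained. Sign convention: the first
#' nonzero row coordinate of each dimension is positive, making the
#' solution reproducible across runs.
#'
#' @param count_matrix non-negative families x chromosomes matrix.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return object of class `"ca_result"`: `row_coordinates`,
#'   `column_coordinates`, `inertia_shares`, `singular_values`,
#'   `dropped_rows`.
#' @export
correspondence_analysis <- function(count_matrix,
                                    transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  X <- as.matrix(count_matrix)
  stopifnot(all(X >= 0), nrow(X) >= 2, ncol(X) >= 2)
  if (transform == "log1p") X <- log1p(X)
  zero_rows <- rowSums(X) == 0
  dropped <- rownames(X)[zero_rows]
  if (any(zero_rows)) {
    warning(sprintf("dropping %d all-zero row(s): %s", sum(zero_rows),
                    paste(dropped, collapse = ", ")))
    X <- X[!zero_rows, , drop = FALSE]
  }
  if (nrow(X) < 2 || sum(colSums(X) > 0) < 2)
    stop("need at least 2 rows and 2 columns with positive sums")
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  cc_pos <- pmax(cc, .Machine$double.xmin)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc_pos))
  sv <- svd(S)
  pos <- sv$d > max(sv$d) * 1e-10
  if (sum(pos) < 2)
    stop("degenerate count matrix: CA rank < 2")
  ndim <- 2L
  row_std <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(ndim), drop = FALSE]
  col_std <- diag(1 / sqrt(cc_pos)) %*% sv$v[, seq_len(ndim), drop = FALSE]
  row_coord <- sweep(row_std, 2, sv$d[seq_len(ndim)], "*")
  col_coord <- sweep(col_std, 2, sv$d[seq_len(ndim)], "*")
  for (k in seq_len(ndim)) { # deterministic sign
    nz <- which(abs(row_coord[, k]) > 1e-12)
    if (length(nz) > 0 && row_coord[nz[1], k] < 0) {
      row_coord[, k] <- -row_coord[, k]
      col_coord[, k] <- -col_coord[, k]
    }
  }
  rownames(row_coord) <- rownames(X)
  rownames(col_coord) <- colnames(X)
  structure(list(row_coordinates = row_coord,
                 column_coordinates = col_coord,
                 inertia_shares = (sv$d^2 / sum(sv$d^2))[seq_len(ndim)],
                 singular_values = sv$d,
                 dropped_rows = dropped),
            class = "ca_result")
}

#' Mahalanobis distance of each family from the CA origin
#'
#' Covariance-scaled distance of each family's 2-D CA coordinates from
#' (0, 0); larger distances mean a less uniform distribution across
#' chromosomes, i.e. stronger chromosome specificity. A singular
#' coordinate covariance falls back to the Moore-Penrose pseudo-inverse
#' with a warning.
#'
#' @param ca a [correspondence_analysis()] result.
#' @return named numeric vector of distances.
#' @export
mahalanobis_from_origin <- function(ca) {
  V <- ca$row_coordinates
  C <- cov(V)
  inv <- tryCatch(solve(C), error = function(e) {
    warning("singular coordinate covariance; using pseudo-inverse")
    MASS::ginv(C)
  })
  d2 <- rowSums((V %*% inv) * V)
  sqrt(pmax(d2, 0))
}

#' Peak-copy-number chromosomes and strict specificity
#'
#' PCN chromosomes are those whose hit count reaches at least `pcn_frac`
#' (default 50%) of the family's maximum per-chromosome count. Strict
#' specificity is called from positive counts alone: `"1-chromosome"` or
#' `"2-chromosome"` when positive counts occur on exactly one or two
#' chromosomes, else `"none"` (unplaced copies are reported separately via
#' `fully_anchored`, not here).
#'
#' @param profile a [count_hits_per_chromosome()] profile.
#' @param pcn_frac fraction of the maximum defining a peak.
#' @return list: `pcn_chromosomes` (character), `strict_level`.
#' @export
call_pcn_and_specificity <- function(profile, pcn_frac = 0.5) {
  counts <- profile$counts
  mx <- max(counts)
  if (mx == 0)
    return(list(pcn_chromosomes = character(0), strict_level = "none"))
  pcn <- names(counts)[counts >= pcn_frac * mx]
  npos <- sum(counts > 0)
  strict <- if (npos == 1) "1-chromosome"
    else if (npos == 2) "2-chromosome"
    else "none"
  list(pcn_chromosomes = pcn, strict_level = strict)
}

#' Fraction of families fully anchored in chromosome scaffolds
#'
#' @param profiles non-empty list of chromosome profiles.
#' @return fraction of families with zero unplaced hits.
#' @export
anchored_fraction <- function(profiles) {
  if (length(profiles) == 0) stop("empty satellitome")
  mean(vapply(profiles, function(p) p$unplaced_count == 0, logical(1)))
}
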