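# Independent oracles used across the suite. These are deliberately
# written from the definitions, without reusing package internals.

# Full quadratic-time affine-gap local alignment, score only.
# Gap of length L costs gap_open + L * gap_extend.
oracle_sw_score <- function(a, b, match = 1, mismatch = 2, gap_open = 5,
                            gap_extend = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                   X[i - 1, j] - gap_extend)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                   Y[i, j - 1] - gap_extend)
    s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else -mismatch
    M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                              Y[i - 1, j - 1]))
    best <- max(best, M[i, j])
  }
  best
}

# Brute-force union length of closed integer intervals.
oracle_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

# Independent correspondence analysis (principal row coordinates, 2 dims).
oracle_ca_rows <- function(X) {
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  coords <- diag(1 / sqrt(r)) %*% sv$u[, 1:2] %*% diag(sv$d[1:2])
  rownames(coords) <- rownames(X)
  coords
}

# Hand-iterated MCL (expansion + inflation on the column-normalized
# matrix), returning a cluster id per node.
oracle_mcl <- function(W, inflation = 2, iters = 200) {
  diag(W) <- apply(W, 1, max)
  norm <- function(M) sweep(M, 2, colSums(M), "/")
  M <- norm(W)
  for (i in seq_len(iters)) M <- norm((M %*% M)^inflation)
  B <- (M > 1e-5) | t(M > 1e-5)
  diag(B) <- TRUE
  n <- nrow(B)
  comp <- rep(NA_integer_, n); cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      q <- c(q, which(B[v, ] & is.na(comp)))
    }
  }
  comp
}

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Point substitutions at a fixed rate (no indels), for controlled-identity
# constructions.
mutate_subs <- function(x, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(x, "")[[1]]
  k <- round(length(ch) * rate)
  if (k > 0) {
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

rotate_seq <- function(x, k) {
  n <- nchar(x)
  k <- k %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1, n), substr(x, 1, k))
}

# Minimal hit data frame for metric tests.
make_hits <- function(s_start, s_end, score = NULL, strand = "+",
                      read = "r1", read_length = 10000L) {
  n <- length(s_start)
  data.frame(query_id = "q", subject_id = read,
             q_start = 1L, q_end = s_end - s_start + 1L,
             s_start = s_start, s_end = s_end,
             strand = rep(strand, length.out = n),
             identity_pct = 100, query_coverage_pct = 100,
             score = if (is.null(score)) s_end - s_start + 1L else score,
             evalue = 1e-10, matches = s_end - s_start + 1L,
             mismatches = 0L, gap_opens = 0L,
             columns = s_end - s_start + 1L,
             read = read, read_length = read_length,
             stringsAsFactors = FALSE)
}
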