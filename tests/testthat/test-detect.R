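tandem_array <- function(monomer, n, sub_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(vapply(seq_len(n), function(i) mutate_subs(monomer, sub_rate),
               character(1)), collapse = "")
}

test_that("periodicity detection recovers planted periods", {
  set.seed(101)
  m150 <- rand_seq(150)
  w <- paste0(rand_seq(400), tandem_array(m150, 20, 0.02), rand_seq(400))
  p <- detect_periodicity(w, period_range = c(10, 200))
  expect_true(!is.null(p) && abs(p - 150) <= 2)

  m40 <- rand_seq(40)
  w40 <- paste0(rand_seq(300), tandem_array(m40, 40, 0.02), rand_seq(300))
  p40 <- detect_periodicity(w40, period_range = c(10, 200))
  expect_true(!is.null(p40) && abs(p40 - 40) <= 1)
})

test_that("random sequence has no significant periodicity", {
  expect_null(detect_periodicity(rand_seq(5000, seed = 102),
                                 period_range = c(10, 200)))
  expect_error(detect_periodicity(rand_seq(300), period_range = c(10, 200)),
               "shorter")
})

test_that("array segmentation separates distinct arrays and respects bounds", {
  set.seed(103)
  m <- rand_seq(120)
  g <- c(chr1 = paste0(rand_seq(2000), tandem_array(m, 25, 0.02),
                       rand_seq(5000), tandem_array(m, 25, 0.02),
                       rand_seq(2000)))
  calls <- segment_arrays(g, period_range = c(10, 200))
  expect_equal(nrow(calls), 2)
  expect_true(all(abs(calls$period - 120) <= 2))
  # array flush at the scaffold edge stays in bounds
  g2 <- c(chr1 = paste0(tandem_array(m, 25, 0.02), rand_seq(3000)))
  c2 <- segment_arrays(g2, period_range = c(10, 200))
  expect_equal(nrow(c2), 1)
  expect_gte(c2$start, 1)
  expect_lte(c2$end, nchar(g2[[1]]))
  # arrays only: no calls on plain background
  expect_equal(nrow(segment_arrays(c(chr1 = rand_seq(20000, seed = 104)),
                                   period_range = c(10, 200))), 0)
})

test_that("round masking prevents re-calling and finds long monomers last", {
  set.seed(105)
  m60 <- rand_seq(60)
  m2500 <- rand_seq(2500)
  g <- c(chr1 = paste0(rand_seq(3000), tandem_array(m60, 60, 0.02),
                       rand_seq(3000), tandem_array(m2500, 4, 0.01),
                       rand_seq(3000)))
  calls <- run_rounds(g)
  short <- calls[calls$period < 100, ]
  long <- calls[calls$period > 2000, ]
  expect_equal(nrow(short), 1)
  expect_equal(short$source_round, 1)
  expect_equal(nrow(long), 1)
  expect_equal(long$source_round, 3)
  expect_true(abs(long$period - 2500) <= 250)
  # masking monotonicity: nothing called twice across rounds
  key <- paste(calls$chromosome, calls$start)
  expect_equal(anyDuplicated(key), 0)
  # no arrays at all
  expect_equal(nrow(run_rounds(c(chr1 = rand_seq(15000, seed = 106)))), 0)
})

test_that("monomer extraction partitions and phase-standardizes the array", {
  set.seed(107)
  m <- rand_seq(100)
  g <- c(chr1 = paste0(rand_seq(1000), tandem_array(m, 12), rand_seq(1000)))
  call <- data.frame(chromosome = "chr1", start = 1001, end = 2200,
                     period = 100)
  mono <- extract_monomers(call, g)
  expect_equal(length(mono), 12)
  expect_true(all(mono == mono[1]))
  expect_true(abs(length(mono) -
                  (call$end - call$start + 1) %/% call$period) <= 1)
  # mutated copies keep high mutual identity
  g2 <- c(chr1 = paste0(rand_seq(500), tandem_array(m, 12, 0.03),
                        rand_seq(500)))
  call2 <- data.frame(chromosome = "chr1", start = 501, end = 1700,
                      period = 100)
  mono2 <- extract_monomers(call2, g2)
  ids <- outer(seq_along(mono2), seq_along(mono2), Vectorize(function(i, j)
    if (i >= j) NA else pairwise_identity_circular(mono2[i], mono2[j])))
  expect_gte(mean(ids, na.rm = TRUE), 100 * (1 - 2 * 0.03))
})

test_that("re-orientation makes monomer strands consistent", {
  set.seed(108)
  m <- rand_seq(150)
  copies <- vapply(1:10, function(i) mutate_subs(m, 0.02), character(1))
  flipped <- copies
  flipped[c(2, 5, 7, 9)] <- revcomp(flipped[c(2, 5, 7, 9)])
  fixed <- reorient_monomers(flipped)
  pool <- unique(satellitome:::kmer_multiset(paste(fixed, collapse = ""), 7))
  shared <- vapply(fixed, function(x)
    mean(satellitome:::kmer_multiset(x, 7) %in% pool), numeric(1))
  expect_true(all(shared > 0.9))
  # single monomer unchanged
  expect_identical(reorient_monomers(m), m)
  # palindrome tie-break: lexicographically smaller kept
  pal <- "ACGTACGTACGTACGTACGT" # revcomp equals itself
  expect_identical(reorient_monomers(pal),
                   min(pal, unname(revcomp(pal))))
})

test_that("consensus building matches a brute-force k-mer coverage oracle", {
  cons1 <- build_consensus("ACGTACGTACGTAA")
  expect_equal(cons1$sequence, "ACGTACGTACGTAA")
  expect_equal(cons1$kmer_coverage, 1.0)
  expect_error(build_consensus(character(0)), "empty")
  set.seed(109)
  for (rep in 1:5) {
    m <- rand_seq(sample(60:150, 1))
    mono <- vapply(1:15, function(i) mutate_subs(m, 0.03), character(1))
    cons <- build_consensus(mono)
    # oracle: count monomer 7-mer instances present in the consensus
    km <- function(x, k = 7) substring(x, 1:(nchar(x) - k + 1),
                                       k:nchar(x))
    pool <- unlist(lapply(mono, km))
    expect_equal(cons$kmer_coverage,
                 sum(pool %in% unique(km(cons$sequence))) / length(pool))
    expect_gte(pairwise_identity_circular(cons$sequence, m), 95)
  }
})

test_that("mixed unrelated families give a low-coverage consensus", {
  set.seed(110)
  a <- rand_seq(120); b <- rand_seq(120)
  mono <- c(vapply(1:8, function(i) mutate_subs(a, 0.02), character(1)),
            vapply(1:8, function(i) mutate_subs(b, 0.02), character(1)))
  cons <- build_consensus(mono)
  expect_lt(cons$kmer_coverage, 0.5)
})

test_that("detect_satellites recovers a planted family end to end", {
  set.seed(111)
  sp <- family_spec("F1", 220, 0.4, c(chr1 = 60L), substitution_rate = 0.03,
                    indel_rate = 0.002, n_arrays_per_chromosome = 2)
  g <- build_genome(list(sp), c(chr1 = 80000L), seed = 41)
  cand <- detect_satellites(g$genome)
  expect_gte(nrow(cand), 1)
  best <- which.max(vapply(cand$sequence, function(s)
    pairwise_identity_circular(s, g$truth$true_monomers$F1), numeric(1)))
  expect_gte(pairwise_identity_circular(cand$sequence[best],
                                        g$truth$true_monomers$F1), 90)
  expect_lt(abs(cand$length[best] - 220) / 220, 0.05)
  expect_true(all(cand$kmer_coverage >= 0.5))
})

test_that("array calls export as BED with 0-based half-open coordinates", {
  calls <- data.frame(chromosome = "chr1", start = 101L, end = 400L,
                      period = 50L, n_copies_est = 6L, support = 20L)
  f <- tempfile()
  write_calls_bed(calls, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 400)
})
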