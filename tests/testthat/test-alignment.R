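test_that("local alignment of identical sequences is perfect", {
  a <- rand_seq(20, seed = 1)
  h <- local_align(a, a)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_coverage_pct, 100)
  expect_equal(h$score, 20)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 20, 1, 20))
})

test_that("local alignment rejects empty or non-DNA input", {
  expect_error(local_align("", "ACGT"), "non-empty")
  expect_error(local_align("ACGT", "ACXT"), "outside")
})

test_that("engine scores match an exhaustive DP oracle on short pairs", {
  set.seed(42)
  p <- alignment_params()
  for (i in 1:120) {
    a <- rand_seq(sample(5:50, 1))
    b <- rand_seq(sample(5:50, 1))
    r <- satellitome:::.sw_align_cpp(a, b, p$match, p$mismatch, p$gap_open,
                                     p$gap_extend, FALSE)
    expect_equal(r$score, oracle_sw_score(a, b), label = paste(a, b))
  }
})

test_that("strand-aware scan finds a reverse-complement query", {
  a <- rand_seq(60, seed = 7)
  h <- scan_hits(a, revcomp(a), thresholds = hit_thresholds(max_evalue = 1))
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(h$identity_pct, 100)
})

test_that("scan finds exact planted copies at their positions", {
  set.seed(11)
  q <- rand_seq(200)
  bg <- rand_seq(50000)
  pos <- c(10001, 30201, 45401)
  sub <- paste0(substr(bg, 1, 10000), q, substr(bg, 10001, 30000), q,
                substr(bg, 30001, 45000), q, substr(bg, 45001, 50000))
  h <- scan_hits(q, sub)
  expect_equal(nrow(h), 3)
  expect_equal(h$s_start, pos)
  expect_equal(h$s_end, pos + 199)
  expect_true(all(h$strand == "+"))
})

test_that("query sharing no seed k-mer yields no hits", {
  q <- strrep("ACGT", 10)
  sub <- strrep("AATTAATTAATTAATTAATT", 100)
  expect_equal(nrow(scan_hits(q, sub)), 0)
})

test_that("a planted reverse-complement copy is reported on the minus strand", {
  set.seed(12)
  q <- rand_seq(200)
  sub <- paste0(rand_seq(5000), revcomp(q), rand_seq(5000))
  h <- scan_hits(q, sub)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(h$s_start, 5001)
})

test_that("scanning the reverse-complement subject mirrors coordinates", {
  set.seed(13)
  q <- rand_seq(150)
  sub <- paste0(rand_seq(3000), q, rand_seq(2000),
                mutate_subs(q, 0.05), rand_seq(1000))
  n <- nchar(sub)
  h1 <- scan_hits(q, sub)
  h2 <- scan_hits(q, revcomp(sub))
  expect_equal(nrow(h1), nrow(h2))
  m1 <- h1[order(h1$s_start), ]
  m2 <- data.frame(s_start = n - h2$s_end + 1, s_end = n - h2$s_start + 1,
                   strand = h2$strand)
  m2 <- m2[order(m2$s_start), ]
  expect_equal(m1$s_start, m2$s_start)
  expect_equal(m1$s_end, m2$s_end)
  expect_true(all(m1$strand != m2$strand))
})

test_that("every returned hit satisfies the thresholds it was scanned with", {
  set.seed(14)
  thr <- hit_thresholds(max_evalue = 1e-5, min_identity_pct = 80,
                        min_query_coverage_pct = 80, max_hits = 100)
  q <- rand_seq(180)
  copies <- vapply(c(0, 0.05, 0.1, 0.25, 0.4), function(r)
    mutate_subs(q, r), character(1))
  sub <- paste(c(rand_seq(2000), copies[1], rand_seq(800), copies[2],
                 rand_seq(800), copies[3], rand_seq(800), copies[4],
                 rand_seq(800), copies[5], rand_seq(2000)), collapse = "")
  h <- scan_hits(q, sub, thresholds = thr)
  expect_gt(nrow(h), 0)
  expect_true(all(h$evalue <= thr$max_evalue))
  expect_true(all(h$identity_pct >= thr$min_identity_pct))
  expect_true(all(h$query_coverage_pct >= thr$min_query_coverage_pct))
  expect_true(all(h$q_start <= h$q_end & h$s_start <= h$s_end))
  expect_true(all(h$s_start >= 1 & h$s_end <= nchar(sub)))
})

test_that("E-value follows the Karlin-Altschul form", {
  p <- alignment_params(karlin_lambda = 0.267, karlin_k = 0.041)
  e1 <- estimate_evalue(40, 100, 1e6, p)
  e2 <- estimate_evalue(50, 100, 1e6, p)
  expect_lt(e2, e1)
  expect_equal(e2, 0.041 * 100 * 1e6 * exp(-0.267 * 50), tolerance = 1e-6)
  expect_equal(estimate_evalue(0, 100, 1e6, p), 0.041 * 100 * 1e6)
})

test_that("circular identity is rotation invariant and symmetric", {
  set.seed(15)
  a <- rand_seq(200)
  expect_equal(pairwise_identity_circular(rotate_seq(a, 37), a), 100)
  b <- mutate_subs(a, 0.10)
  id_ab <- pairwise_identity_circular(a, b)
  expect_gte(id_ab, 85); expect_lte(id_ab, 95)
  expect_lt(abs(id_ab - pairwise_identity_circular(b, a)), 1)
})

test_that("unrelated monomers align only over short low-coverage stretches", {
  a <- rand_seq(200, seed = 16)
  b <- rand_seq(200, seed = 17)
  ca <- satellitome:::circular_align(a, b)
  expect_lt(ca$coverage_shorter_pct, 50)
})

test_that("hits export as 12-column tabular text", {
  set.seed(18)
  q <- rand_seq(100)
  sub <- paste0(rand_seq(1000), q, rand_seq(1000))
  h <- scan_hits(q, sub)
  f <- tempfile()
  write_hits_tabular(h, f)
  tab <- read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12)
  expect_equal(nrow(tab), nrow(h))
  expect_equal(tab$V9, h$s_start)
})
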