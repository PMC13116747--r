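test_that("per-chromosome counting separates placed and unplaced hits", {
  set.seed(601)
  m <- rand_seq(200)
  mk <- function(n_copies, len = 20000)
    paste0(rand_seq(2000), strrep(m, n_copies), rand_seq(len))
  asm <- c(chr1 = rand_seq(15000), chr2 = rand_seq(15000),
           chr3 = mk(12), scaffold_1 = mk(4))
  pr <- count_hits_per_chromosome(m, asm, family = "fam")
  expect_equal(sort(names(pr$counts)), c("chr1", "chr2", "chr3"))
  expect_equal(pr$counts[["chr1"]], 0)
  expect_equal(pr$counts[["chr3"]], 12)
  expect_gt(pr$unplaced_count, 0)
  expect_false(pr$fully_anchored)
  # absent family
  pr0 <- count_hits_per_chromosome(rand_seq(200), asm)
  expect_true(all(pr0$counts == 0))
  expect_true(pr0$fully_anchored)
  # planted ratios recovered at 0% mutation
  asm2 <- c(chr1 = mk(30), chr2 = mk(10))
  pr2 <- count_hits_per_chromosome(m, asm2)
  expect_lt(abs(pr2$counts[["chr1"]] / pr2$counts[["chr2"]] - 3), 0.3)
})

test_that("CA centers average-profile rows at the origin, duplicates coincide", {
  # f3 and f4 share a profile proportional to the column totals; three
  # other rows deviate in independent directions so the CA has rank 2
  M <- rbind(f1 = c(10, 20, 40), f2 = c(30, 5, 10), f5 = c(5, 30, 10),
             f3 = c(9, 11, 12), f4 = c(9, 11, 12))
  colnames(M) <- paste0("chr", 1:3)
  stopifnot(all(abs(M["f3", ] / sum(M["f3", ]) -
                    colSums(M) / sum(M)) < 1e-12))
  ca <- correspondence_analysis(M, transform = "none")
  expect_lt(max(abs(ca$row_coordinates["f3", ])), 1e-9)
  expect_equal(ca$row_coordinates["f3", ], ca$row_coordinates["f4", ])
})

test_that("CA coordinates match an independent implementation on toy matrices", {
  set.seed(602)
  for (rep in 1:5) {
    M <- matrix(rpois(12, 30) + 1, nrow = 3,
                dimnames = list(paste0("f", 1:3), paste0("c", 1:4)))
    ca <- correspondence_analysis(M, transform = "none")
    oc <- oracle_ca_rows(M)
    for (k in 1:2) {
      a <- ca$row_coordinates[, k]; b <- oc[, k]
      expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
    }
  }
  # log transform is applied: same matrix, different coordinates
  M <- matrix(c(1, 10, 100, 100, 10, 1, 50, 50, 50), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("c", 1:3)))
  ca_log <- correspondence_analysis(M)
  oc_log <- oracle_ca_rows(log1p(M))
  for (k in 1:2) {
    a <- ca_log$row_coordinates[, k]; b <- oc_log[, k]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
})

test_that("CA drops all-zero rows with a warning and rejects degenerate input", {
  M <- rbind(f1 = c(5, 1, 3), f2 = c(0, 0, 0), f3 = c(2, 8, 1),
             f4 = c(1, 1, 9))
  expect_warning(ca <- correspondence_analysis(M), "all-zero")
  expect_equal(ca$dropped_rows, "f2")
  expect_equal(nrow(ca$row_coordinates), 3)
  expect_error(suppressWarnings(correspondence_analysis(
    rbind(a = c(1, 1), b = c(1, 1)), transform = "none")), "rank|degenerate")
})

test_that("CA row coordinates are reproducible with a fixed sign convention", {
  set.seed(603)
  M <- matrix(rpois(40, 20), nrow = 8,
              dimnames = list(paste0("f", 1:8), paste0("c", 1:5)))
  ca1 <- correspondence_analysis(M)
  ca2 <- correspondence_analysis(M)
  expect_equal(ca1$row_coordinates, ca2$row_coordinates, tolerance = 1e-9)
  expect_gt(ca1$row_coordinates[which(abs(ca1$row_coordinates[, 1]) >
                                      1e-12)[1], 1], 0)
})

test_that("Mahalanobis distances match brute force and ignore sign flips", {
  set.seed(604)
  M <- matrix(rpois(25, 15) + 1, nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("c", 1:5)))
  ca <- correspondence_analysis(M)
  d <- mahalanobis_from_origin(ca)
  V <- ca$row_coordinates
  Ci <- solve(cov(V))
  brute <- sqrt(diag(V %*% Ci %*% t(V)))
  expect_equal(unname(d), unname(brute), tolerance = 1e-10)
  # sign flips of a CA dimension leave distances unchanged
  ca2 <- ca
  ca2$row_coordinates[, 1] <- -ca2$row_coordinates[, 1]
  expect_equal(mahalanobis_from_origin(ca2), d, tolerance = 1e-10)
  # a family exactly at the origin has distance 0
  ca3 <- ca
  ca3$row_coordinates[1, ] <- 0
  expect_equal(unname(mahalanobis_from_origin(ca3)[1]), 0)
})

test_that("PCN calling and strict specificity follow the 50%-of-max rule", {
  prof <- function(counts) structure(
    list(family = "f", counts = counts, unplaced_count = 0L,
         fully_anchored = TRUE), class = "chromosome_profile")
  p1 <- call_pcn_and_specificity(prof(c(chr1 = 0, chr2 = 0, chr3 = 100,
                                        chr4 = 0)))
  expect_equal(p1$pcn_chromosomes, "chr3")
  expect_equal(p1$strict_level, "1-chromosome")
  p2 <- call_pcn_and_specificity(prof(c(chr1 = 80, chr2 = 100, chr3 = 0)))
  expect_equal(sort(p2$pcn_chromosomes), c("chr1", "chr2"))
  expect_equal(p2$strict_level, "2-chromosome")
  p3 <- call_pcn_and_specificity(prof(c(chr1 = 50, chr2 = 50, chr3 = 50)))
  expect_equal(length(p3$pcn_chromosomes), 3)
  expect_equal(p3$strict_level, "none")
  p0 <- call_pcn_and_specificity(prof(c(chr1 = 0, chr2 = 0)))
  expect_equal(p0$strict_level, "none")
  expect_length(p0$pcn_chromosomes, 0)
})

test_that("anchored fraction counts families with no unplaced hits", {
  prof <- function(u) structure(
    list(family = "f", counts = c(chr1 = 1), unplaced_count = u,
         fully_anchored = u == 0), class = "chromosome_profile")
  expect_equal(anchored_fraction(lapply(c(0, 0, 0), prof)), 1.0)
  expect_equal(anchored_fraction(lapply(c(0, 5, 0, 2, 0), prof)), 0.6)
  expect_error(anchored_fraction(list()), "empty")
})

test_that("the CA input matrix never contains an unplaced column", {
  prof <- structure(list(family = "f1", counts = c(chr1 = 3, chr2 = 9),
                         unplaced_count = 7L, fully_anchored = FALSE),
                    class = "chromosome_profile")
  M <- profile_matrix(list(prof))
  expect_false("unplaced" %in% colnames(M))
  expect_equal(attr(M, "unplaced")[["f1"]], 7)
})
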