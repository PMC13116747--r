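test_that("monomer generation matches the requested GC and is reproducible", {
  m <- make_monomer(1000, 0.39, seed = 3)
  expect_equal(nchar(m), 1000)
  expect_lt(abs(gc_fraction(m) - 0.39), 0.05)
  expect_identical(m, make_monomer(1000, 0.39, seed = 3))
  at_only <- make_monomer(500, 0, seed = 4)
  expect_false(grepl("[GC]", at_only))
  expect_error(make_monomer(5, 0.4, seed = 1), ">= 10")
})

test_that("planted arrays appear in the truth manifest with consistent size", {
  sp <- family_spec("F1", 300, 0.4, c(chr1 = 100L), substitution_rate = 0.02,
                    indel_rate = 0.002, n_arrays_per_chromosome = 1)
  g <- build_genome(list(sp), c(chr1 = 100000L), seed = 9)
  ti <- g$truth$array_intervals
  expect_equal(nrow(ti), 1)
  len <- ti$end - ti$start + 1
  expect_gte(len, 30000 * (1 - 3 * 0.002))
  expect_lte(len, 30000 * (1 + 3 * 0.002))
  # the planted interval really contains the array: copies match the monomer
  arr <- substr(g$genome[["chr1"]], ti$start, ti$end)
  copy <- substr(arr, 1, 300)
  expect_gte(pairwise_identity_circular(copy, g$truth$true_monomers$F1),
             100 * (1 - 2 * 0.02) - 3)
})

test_that("zero families gives plain background; placement is confined", {
  g0 <- build_genome(list(), c(chr1 = 20000L), seed = 2)
  expect_equal(nchar(g0$genome[["chr1"]]), 20000)
  expect_equal(nrow(g0$truth$array_intervals), 0)
  sp <- family_spec("F1", 100, 0.4, c(chr2 = 30L),
                    n_arrays_per_chromosome = 3)
  g <- build_genome(list(sp), c(chr1 = 30000L, chr2 = 30000L), seed = 2)
  expect_true(all(g$truth$array_intervals$chromosome == "chr2"))
  expect_true(all(g$truth$array_intervals$end <= 30000))
})

test_that("infeasible packing is an input error", {
  sp <- family_spec("F1", 1000, 0.4, c(chr1 = 50L))
  expect_error(build_genome(list(sp), c(chr1 = 20000L), seed = 1),
               "infeasible")
})

test_that("short-read count follows coverage arithmetic and is reproducible", {
  g <- build_genome(list(), c(chr1 = 1000000L), seed = 21)
  rp <- read_sim_params(short_coverage = 10, seed = 5)
  reads <- simulate_short_reads(g$genome, rp)
  expect_true(length(reads) %in% c(66666, 66667))
  expect_true(all(nchar(reads) == 150))
  expect_identical(reads[1:50], simulate_short_reads(g$genome, rp)[1:50])
  none <- simulate_short_reads(g$genome,
                               read_sim_params(short_coverage = 0, seed = 5))
  expect_length(none, 0)
})

test_that("reads hit a planted array at its genomic proportion", {
  sp <- family_spec("F1", 250, 0.4, c(chr1 = 120L), substitution_rate = 0)
  g <- build_genome(list(sp), c(chr1 = 300000L), seed = 31)
  ti <- g$truth$array_intervals
  rp <- read_sim_params(short_coverage = 8, seed = 6)
  reads <- simulate_short_reads(g$genome, rp)
  origin <- do.call(rbind, strsplit(sub("^\\S+ ", "", names(reads)), "[:-]"))
  st <- as.integer(origin[, 2]); en <- as.integer(origin[, 3])
  n_overlap <- sum(st <= ti$end & en >= ti$start)
  p <- (ti$end - ti$start + 1 + 150) / 300000 # interval inflated by read len
  expect_lt(abs(n_overlap - length(reads) * p),
            3 * sqrt(length(reads) * p * (1 - p)) + 3)
})

test_that("long reads respect the length floor and coverage target", {
  g <- build_genome(list(), c(chr1 = 150000L), seed = 22)
  rp <- read_sim_params(long_coverage = 5, seed = 7)
  lr <- simulate_long_reads(g$genome, rp)
  expect_true(all(nchar(lr) >= 10000))
  expect_gte(sum(nchar(lr)), 5 * 150000)
  expect_identical(lr, simulate_long_reads(g$genome, rp))
})

test_that("error-free long reads are exact substrings of the genome", {
  g <- build_genome(list(), c(chr1 = 120000L), seed = 23)
  rp <- read_sim_params(long_coverage = 1, long_error_rate = 0, seed = 8)
  lr <- simulate_long_reads(g$genome, rp)
  origin <- sub("^\\S+ ", "", names(lr))
  for (i in seq_along(lr)) {
    f <- regmatches(origin[i],
                    regexec("^(.+):(\\d+)-(\\d+):([+-])$", origin[i]))[[1]][-1]
    truth <- substr(g$genome[[f[1]]], as.integer(f[2]), as.integer(f[3]))
    if (f[4] == "-") truth <- unname(revcomp(truth))
    expect_identical(lr[[i]], truth)
  }
})

test_that("a 40 kb array region is fully spanned by some read at deep coverage", {
  sp <- family_spec("F1", 400, 0.4, c(chr1 = 100L), substitution_rate = 0.01)
  g <- build_genome(list(sp), c(chr1 = 150000L), seed = 24)
  ti <- g$truth$array_intervals
  rp <- read_sim_params(long_coverage = 20, seed = 9)
  lr <- simulate_long_reads(g$genome, rp)
  origin <- do.call(rbind, strsplit(sub("^\\S+ ", "", names(lr)), "[:-]"))
  st <- as.integer(origin[, 2]); en <- as.integer(origin[, 3])
  expect_true(any(st <= ti$start & en >= ti$end))
})

test_that("truth manifest round-trips to files", {
  sp <- family_spec("F1", 120, 0.4, c(chr1 = 20L))
  g <- build_genome(list(sp), c(chr1 = 20000L), seed = 25)
  d <- tempfile()
  write_truth_manifest(g$truth, d)
  ti <- read.delim(file.path(d, "array_intervals.tsv"))
  expect_equal(ti$start, g$truth$array_intervals$start)
  mono <- read_seqs(file.path(d, "true_monomers.fasta"))
  expect_identical(unname(mono["F1"]), g$truth$true_monomers$F1)
})
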