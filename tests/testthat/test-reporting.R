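fam_df <- function(n = 3, abund = NULL, lens = NULL, seed = 700) {
  set.seed(seed)
  lens <- lens %||% sample(c(150, 377, 750), n, replace = TRUE)
  data.frame(family_id = paste0("f", seq_len(n)),
             sequence = vapply(lens, rand_seq, character(1)),
             length = lens,
             final_abundance_pct = abund %||% sort(runif(n), decreasing = TRUE),
             suffix = "none", provenance = "", stringsAsFactors = FALSE)
}

test_that("nomenclature renders rank, length and suffix", {
  fams <- fam_df(3, abund = c(5, 1, 0.2), lens = c(377, 200, 31))
  fams$suffix[1] <- "subtel"
  named <- assign_names(fams, "Ac")
  expect_equal(named$name[1], "AcSat1-377-subtel")
  expect_equal(named$name[2], "AcSat2-200")
  expect_equal(named$name[3], "AcSat3-31")
  # ranks are a dense bijection and re-rank densely after removal
  named2 <- assign_names(named[-2, names(fams)], "Ac")
  expect_equal(named2$rank, 1:2)
  expect_equal(named2$name[2], "AcSat2-31")
})

test_that("naming ties break deterministically and provenance is mapped", {
  fams <- fam_df(2, abund = c(1, 1), lens = c(300, 500))
  fams$provenance[2] <- "OldName1;OldName2"
  n1 <- assign_names(fams, "Af")
  n2 <- assign_names(fams[2:1, ], "Af")
  expect_equal(n1$name, n2$name) # order-independent
  expect_equal(n1$length[1], 500) # longer first on equal abundance
  mp <- attr(n1, "name_mapping")
  expect_equal(sort(mp$original_name), c("OldName1", "OldName2"))
  expect_equal(unique(mp$new_name), "AfSat1-500")
})

test_that("cross-species homology is symmetric and threshold-driven", {
  set.seed(701)
  a1 <- rand_seq(377); a2 <- rand_seq(250)
  b1 <- mutate_subs(a1, 0.1) # ~90% ortholog
  sat_a <- c(A1 = a1, A2 = a2)
  sat_b <- c(B1 = b1, B2 = rand_seq(400))
  hom <- cross_species_homology(sat_a, sat_b)
  expect_equal(hom$a$status[hom$a$family == "A1"], "shared")
  expect_equal(hom$a$partner[hom$a$family == "A1"], "B1")
  expect_equal(hom$b$status[hom$b$family == "B1"], "shared")
  expect_equal(hom$b$partner[hom$b$family == "B1"], "A1")
  expect_equal(hom$a$status[hom$a$family == "A2"], "specific")
  # identical satellitomes: everything shared at 100%
  hom2 <- cross_species_homology(sat_a, setNames(sat_a, c("X1", "X2")))
  expect_true(all(hom2$a$status == "shared"))
  expect_true(all(hom2$a$identity_pct == 100))
})

test_that("an ortholog with a large internal deletion is still shared", {
  set.seed(702)
  long <- rand_seq(1682)
  short <- mutate_subs(paste0(substr(long, 1, 600),
                              substr(long, 1034, 1682)), 0.05)
  hom <- cross_species_homology(c(cepa = long), c(fist = short))
  expect_equal(hom$a$status, "shared")
  expect_gte(hom$a$identity_pct, 80)
})

test_that("in-silico PCR computes product length from primer 5' ends", {
  set.seed(703)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  # forward site starts at 100; reverse-primer site ends at 1535
  tpl <- paste0(rand_seq(99), fwd, rand_seq(1436 - 40),
                revcomp(rev), rand_seq(2000 - 1535))
  expect_equal(nchar(tpl), 2000)
  expect_equal(in_silico_pcr(tpl, fwd, rev), 1436)
  # no binding sites
  expect_length(in_silico_pcr(rand_seq(2000), fwd, rev), 0)
  # reverse-complement template yields the same product multiset
  expect_equal(in_silico_pcr(revcomp(tpl), fwd, rev), 1436)
  expect_error(in_silico_pcr(tpl, substr(fwd, 1, 10), rev), "15 bp")
})

test_that("circular templates amplify across the monomer junction", {
  set.seed(704)
  m <- rand_seq(500)
  fwd <- substr(m, 401, 420)
  rev_site <- substr(m, 101, 120) # upstream of fwd on the linear monomer
  rev <- unname(revcomp(rev_site))
  lin <- in_silico_pcr(m, fwd, rev)
  circ <- in_silico_pcr(m, fwd, rev, circular = TRUE)
  expect_length(lin, 0)
  expect_equal(circ, 220) # 100 to the end + 120 into the next copy
})

test_that("mismatch tolerance widens primer matching", {
  set.seed(705)
  fwd <- rand_seq(20); rev <- rand_seq(20)
  fwd_mut <- mutate_subs(fwd, 0.1, seed = 1) # 2 mismatches
  tpl <- paste0(rand_seq(50), fwd_mut, rand_seq(300), revcomp(rev),
                rand_seq(50))
  expect_length(in_silico_pcr(tpl, fwd, rev), 0)
  expect_length(in_silico_pcr(tpl, fwd, rev, max_mismatches = 2), 1)
})

test_that("assembly statistics follow the standard N50/L50 definitions", {
  asm <- setNames(vapply(c(10, 20, 30, 40), rand_seq, character(1)),
                  paste0("s", 1:4))
  st <- assembly_stats(asm)
  expect_equal(st$n50_bp, 30)
  expect_equal(st$l50_count, 2)
  expect_equal(st$n_scaffolds, 4)
  one <- assembly_stats(c(chr1 = rand_seq(5000, seed = 706)))
  expect_equal(one$n50_bp, 5000)
  expect_equal(one$l50_count, 1)
  expect_warning(allN <- assembly_stats(c(x = strrep("N", 100))), "non-N")
  expect_equal(allN$gc_pct, 0)
})

test_that("assembly preprocessing unmasks and normalizes ambiguity codes", {
  expect_equal(unname(preprocess_assembly(c(x = "acgtRYacgt"))),
               "ACGTNNACGT")
  clean <- c(chr1 = "ACGTACGT")
  expect_equal(preprocess_assembly(clean), clean)
  messy <- c(s = "acGTnryswkmbdhvACGT-")
  expect_equal(nchar(preprocess_assembly(messy)), nchar(messy))
})

test_that("reports round-trip through files", {
  set.seed(707)
  fams <- fam_df(3, abund = c(2, 1, 0.5))
  fams <- assign_names(fams, "Sy")
  run <- structure(list(families = fams, per_read_stats = NULL,
                        count_matrix = NULL,
                        settings = list(min_score = 30)),
                   class = "satellitome_run")
  d <- tempfile()
  write_reports(run, d)
  back <- read_seqs(file.path(d, "satellitome.fasta"))
  expect_equal(unname(back), fams$sequence)
  tab <- read.delim(file.path(d, "families.tsv"))
  expect_equal(nrow(tab), nrow(fams))
  expect_true(all(c("name", "length", "final_abundance_pct") %in%
                  names(tab)))
})
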