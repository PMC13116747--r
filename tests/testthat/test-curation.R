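cand_df <- function(seqs, ids = NULL, assembly = "asm1",
                    detector = "det1") {
  data.frame(candidate_id = ids %||% sprintf("c%02d", seq_along(seqs)),
             sequence = seqs, length = nchar(seqs),
             kmer_coverage = 1, source_round = 1L,
             assembly = rep(assembly, length.out = length(seqs)),
             detector = rep(detector, length.out = length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("identical candidates from two assemblies collapse to one", {
  set.seed(201)
  m <- rand_seq(300)
  cd <- cand_df(c(m, m), assembly = c("asm1", "asm2"))
  out <- dedup_identity(cd)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_merged, 2L)
})

test_that("merging follows the 80% circular-identity threshold", {
  set.seed(202)
  m <- rand_seq(300)
  near <- rotate_seq(mutate_subs(m, 0.15), 50)   # ~85% identity
  far <- mutate_subs(m, 0.42)                    # local islands only
  expect_gte(pairwise_identity_circular(m, near), 80)
  # the heavily mutated copy aligns only over short local islands, so its
  # coverage of the monomer stays below the merge threshold
  expect_lt(satellitome:::circular_align(m, far)$coverage_shorter_pct, 80)
  out <- dedup_identity(cand_df(c(m, near, far)))
  expect_equal(nrow(out), 2)
})

test_that("dedup is idempotent and order-insensitive in cluster count", {
  set.seed(203)
  base <- replicate(4, rand_seq(250))
  seqs <- c(base, vapply(base[1:2], function(b) mutate_subs(b, 0.1),
                         character(1)))
  cd <- cand_df(seqs)
  out1 <- dedup_identity(cd)
  expect_identical(nrow(dedup_identity(out1)), nrow(out1))
  for (perm in 1:3) {
    cd2 <- cd[sample(nrow(cd)), ]
    expect_equal(nrow(dedup_identity(cd2)), nrow(out1))
  }
})

test_that("similarity graph admits edges only under all three thresholds", {
  set.seed(204)
  a <- rand_seq(400)
  g0 <- build_similarity_graph(cand_df(c(a, rand_seq(400), rand_seq(400))))
  expect_equal(nrow(g0$edges), 0)
  b <- mutate_subs(a, 0.1) # ~90% identity full length
  g1 <- build_similarity_graph(cand_df(c(a, b)))
  expect_equal(nrow(g1$edges), 1)
  ca <- satellitome:::circular_align(a, b)
  expect_equal(g1$edges$weight,
               satellitome:::bit_score(ca$score, alignment_params()))
  # strong 100 bp match between 1000-mers fails the 80% coverage rule
  core <- rand_seq(100)
  x <- paste0(rand_seq(450), core, rand_seq(450))
  y <- paste0(rand_seq(450), core, rand_seq(450))
  g2 <- build_similarity_graph(cand_df(c(x, y)))
  expect_equal(nrow(g2$edges), 0)
})

test_that("MCL separates weakly joined cliques and keeps singletons", {
  tri <- function(ids, w) do.call(rbind, lapply(list(c(1, 2), c(1, 3),
                                                     c(2, 3)), function(p)
    data.frame(i = ids[p[1]], j = ids[p[2]], weight = w,
               stringsAsFactors = FALSE)))
  nodes <- paste0("n", 1:6)
  edges <- rbind(tri(nodes[1:3], 100), tri(nodes[4:6], 100))
  g_dis <- structure(list(nodes = nodes, edges = edges, thresholds = list()),
                     class = "similarity_graph")
  cl <- mcl_cluster(g_dis)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  # barbell: weak bridge between the triangles
  edges_bb <- rbind(edges, data.frame(i = "n3", j = "n4", weight = 1))
  g_bb <- structure(list(nodes = nodes, edges = edges_bb,
                         thresholds = list()), class = "similarity_graph")
  cl_bb <- mcl_cluster(g_bb, inflation = 2.0)
  expect_equal(length(unique(cl_bb)), 2)
  # agreement with the hand-iterated expansion/inflation oracle
  W <- matrix(0, 6, 6)
  for (r in seq_len(nrow(edges_bb))) {
    i <- match(edges_bb$i[r], nodes); j <- match(edges_bb$j[r], nodes)
    W[i, j] <- W[j, i] <- edges_bb$weight[r]
  }
  oc <- oracle_mcl(W)
  expect_equal(as.integer(factor(cl_bb, levels = unique(cl_bb))),
               as.integer(factor(oc, levels = unique(oc))))
  # singleton
  g1 <- structure(list(nodes = "solo",
                       edges = data.frame(i = character(),
                                          j = character(),
                                          weight = numeric()),
                       thresholds = list()), class = "similarity_graph")
  expect_equal(unname(mcl_cluster(g1)), 1L)
})

test_that("MCL partitions refine the graph's connected components", {
  set.seed(205)
  for (rep in 1:5) {
    n <- 8
    nodes <- paste0("v", 1:n)
    ne <- sample(4:10, 1)
    edges <- unique(data.frame(
      i = nodes[sample(n, ne, replace = TRUE)],
      j = nodes[sample(n, ne, replace = TRUE)],
      weight = sample(1:50, ne, replace = TRUE),
      stringsAsFactors = FALSE))
    edges <- edges[edges$i != edges$j, ]
    g <- structure(list(nodes = nodes, edges = edges, thresholds = list()),
                   class = "similarity_graph")
    cl <- mcl_cluster(g)
    # components by union-find over the edge list
    comp <- seq_len(n); names(comp) <- nodes
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (r in seq_len(nrow(edges)))
      comp[find(edges$i[r])] <- find(edges$j[r])
    roots <- vapply(nodes, find, numeric(1))
    # two nodes in the same MCL cluster must share a component
    for (cc in unique(cl)) {
      members <- names(cl)[cl == cc]
      expect_equal(length(unique(roots[members])), 1)
    }
  }
})

test_that("known-library entries merge with provenance and survive alone", {
  set.seed(206)
  m <- rand_seq(377)
  cd <- cand_df(m, ids = "novel377")
  known <- setNames(c(mutate_subs(m, 0.05), rand_seq(200)),
                    c("AceSat01-377", "Orphan200"))
  merged <- merge_with_known(cd, known)
  expect_equal(nrow(merged), 3)
  fam <- cluster_families(merged)
  expect_equal(nrow(fam), 2)
  matched <- fam[grepl("AceSat01-377", fam$provenance), ]
  expect_equal(nrow(matched), 1)
  expect_equal(matched$n_cluster_members, 2L)
  orphan <- fam[fam$family_id == "known_Orphan200", ]
  expect_equal(nrow(orphan), 1)
  # empty library leaves candidates unchanged (modulo bookkeeping columns)
  expect_equal(merge_with_known(cd, NULL)$sequence, cd$sequence)
})

test_that("coverage profiles are flat for clean consensuses and expose chimeras", {
  set.seed(207)
  m <- rand_seq(150)
  g <- c(chr1 = strrep(m, 50))
  reads <- simulate_short_reads(g, read_sim_params(short_coverage = 50,
                                                   seed = 77))
  prof <- coverage_profile(m, reads)
  expect_length(prof, 150)
  expect_lt(max(prof) / max(min(prof), 1), 3)
  expect_false(flag_chimeric(prof))
  # unmapped reads give an all-zero profile
  noise <- vapply(1:50, function(i) rand_seq(150), character(1))
  expect_true(all(coverage_profile(m, noise) == 0))
  # chimeric consensus: real half + random half
  chim <- paste0(substr(m, 1, 150), rand_seq(150))
  prof_c <- coverage_profile(chim, reads)
  expect_lt(mean(prof_c[160:300]), 0.2 * mean(prof_c[1:150]))
  expect_true(flag_chimeric(prof_c))
})

test_that("no two retained families stay mutually redundant after curation", {
  set.seed(208)
  base <- replicate(3, rand_seq(300))
  seqs <- c(base,
            vapply(base, function(b) rotate_seq(mutate_subs(b, 0.08), 31),
                   character(1)))
  out <- dedup_identity(cand_df(seqs))
  if (nrow(out) >= 2) {
    for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
      ca <- satellitome:::circular_align(out$sequence[i], out$sequence[j])
      expect_false(ca$identity_pct >= 80 && ca$coverage_shorter_pct >= 80)
    }
  }
})
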