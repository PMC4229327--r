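# Pairwise identity, greedy clustering (with all-pairs oracle), chimera
# detection against planted truth, and the two-tier universal merge.

test_that("pairwise identity matches its definition and the DP oracle", {
  set.seed(201)
  a <- random_dna(100)
  expect_equal(pairwise_identity(a, a), 1.0)

  b <- mutate_k(a, 3)
  expect_equal(pairwise_identity(a, b), 0.97)
  expect_equal(pairwise_identity(b, a), 0.97)  # symmetric

  # prefix against full sequence: shorter-sequence denominator gives 1.0,
  # checked against an independent affine-gap aligner
  pre <- substr(a, 1, 50)
  expect_equal(pairwise_identity(a, pre), 1.0)
  expect_equal(oracle_align_matches(a, pre), 50L)

  # alignment-length denominator counts the end gap
  p2 <- identity_params(denominator_rule = "alignment_length")
  expect_equal(pairwise_identity(a, pre, p2), 0.5)

  # oracle agreement on structured mutated pairs
  for (k in c(1, 5, 10)) {
    bb <- mutate_k(a, k)
    expect_equal(pairwise_identity(a, bb) * 100, oracle_align_matches(a, bb))
  }
})

test_that("greedy clustering: identity groups, separation and determinism", {
  set.seed(202)
  base <- random_dna(100)
  reads <- records_from(rep(base, 5))
  cl <- greedy_cluster(reads)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$size, 5L)

  # two groups at ~90% cross-identity, 100% within
  g2 <- mutate_k(base, 10)
  cl2 <- greedy_cluster(records_from(c(rep(base, 3), rep(g2, 4))))
  expect_equal(nrow(cl2$clusters), 2L)
  expect_equal(sort(cl2$clusters$size), c(3L, 4L))
})

test_that("planted groups are recovered exactly (all-pairs oracle)", {
  set.seed(203)
  k_groups <- 6
  centers <- vapply(seq_len(k_groups), function(i) random_dna(150),
                    character(1))
  seqs <- unlist(lapply(centers, function(cc) {
    c(cc, vapply(1:4, function(i) mutate_k(cc, 1), character(1)))
  }))
  reads <- records_from(sample(seqs))
  cl <- greedy_cluster(reads)
  expect_equal(nrow(cl$clusters), k_groups)

  # oracle: all-pairs identity matrix + connected components at 0.97
  uniq <- unique(reads$residues)
  n <- length(uniq)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- pairwise_identity(uniq[i], uniq[j]) >= 0.97
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  oracle_groups <- split(uniq, comp)
  got_groups <- split(reads$residues[match(cl$members$read_id, reads$id)],
                      cl$members$cluster_id)
  got_sets <- lapply(got_groups, function(x) sort(unique(x)))
  oracle_sets <- lapply(oracle_groups, sort)
  expect_setequal(
    unname(vapply(got_sets, paste, character(1), collapse = "|")),
    unname(vapply(oracle_sets, paste, character(1), collapse = "|")))

  # partition property: every read in exactly one cluster
  expect_setequal(cl$members$read_id, reads$id)
  expect_equal(anyDuplicated(cl$members$read_id), 0L)
  # representative separation below the threshold
  reps <- cl$rep_records$residues
  for (i in seq_along(reps)) {
    for (j in seq_along(reps)) {
      if (i < j) expect_lt(pairwise_identity(reps[i], reps[j]), 0.97)
    }
  }
})

test_that("clustering is invariant to input order", {
  set.seed(204)
  base <- random_dna(120)
  seqs <- c(rep(base, 3), rep(mutate_k(base, 8), 2),
            vapply(1:3, function(i) random_dna(120), character(1)))
  ids <- sprintf("r%02d", seq_along(seqs))
  mk <- function(ord) {
    seq_records(ids[ord], "ds", seqs[ord])
  }
  cl1 <- greedy_cluster(mk(seq_along(seqs)))
  cl2 <- greedy_cluster(mk(rev(seq_along(seqs))))
  key <- function(cl) {
    m <- cl$members[order(cl$members$read_id), ]
    paste(m$read_id, m$cluster_id, collapse = ";")
  }
  expect_equal(key(cl1), key(cl2))
  expect_equal(sort(cl1$clusters$rep_id), sort(cl2$clusters$rep_id))
})

test_that("constructed chimeras are flagged, genuine reads are not", {
  set.seed(205)
  pa <- random_dna(200)
  pb <- mutate_k(pa, 30)               # parents at 85% identity
  chim <- paste0(substr(pa, 1, 100), substr(pb, 101, 200))
  reads <- seq_records(c("A", "B", "Q", "C"), "ds",
                       c(pa, pb, chim, pa))
  ab <- c(A = 10, B = 10, Q = 1, C = 1)
  res <- detect_chimeras(reads[1:3, ], ab)
  expect_equal(res$chimeric$id, "Q")
  expect_setequal(res$clean$id, c("A", "B"))

  # an exact copy of a parent is clean even when rare: full identity to
  # that parent (1.0) exceeds the dissimilarity requirement p_lo
  res2 <- detect_chimeras(reads[c(1, 2, 4), ], ab)
  expect_equal(nrow(res2$chimeric), 0L)
})

test_that("planted chimera mixtures: >=90% sensitivity, no false positives", {
  set.seed(206)
  n_parents <- 6
  centers <- vapply(seq_len(n_parents), function(i) random_dna(300),
                    character(1))
  n_chim <- 15
  pairs <- t(replicate(n_chim, sample(n_parents, 2)))
  splits <- sample(75:225, n_chim, replace = TRUE)
  chims <- vapply(seq_len(n_chim), function(i) {
    paste0(substr(centers[pairs[i, 1]], 1, splits[i]),
           substr(centers[pairs[i, 2]], splits[i] + 1, 300))
  }, character(1))
  ids <- c(sprintf("P%02d", seq_len(n_parents)),
           sprintf("X%02d", seq_len(n_chim)))
  reads <- seq_records(ids, "ds", c(centers, chims))
  ab <- stats::setNames(c(rep(50, n_parents), rep(1, n_chim)), ids)
  res <- detect_chimeras(reads, ab)
  planted <- grepl("^X", res$chimeric$id)
  expect_gte(sum(planted) / n_chim, 0.9)
  expect_false(any(grepl("^P", res$chimeric$id)))  # zero false positives
})

test_that("universal merge aggregates per-dataset tallies and flags", {
  set.seed(207)
  base <- random_dna(200)
  far <- vapply(1:2, function(i) random_dna(200), character(1))

  ds1 <- greedy_cluster(seq_records(c("a1", "a2"), "ds1",
                                    c(base, far[1])), dataset_id = "ds1")
  ds2 <- greedy_cluster(seq_records(c("b1", "b2", "b3"), "ds2",
                                    c(mutate_k(base, 2), far[2], far[2])),
                        dataset_id = "ds2")
  cult <- greedy_cluster(seq_records("iso1", "cultured", base,
                                     is_cultured = TRUE),
                         dataset_id = "cultured")
  uni <- build_universal_otus(list(ds1 = ds1, ds2 = ds2), cult)

  # base-derived representatives merge with the cultured rep
  expect_equal(nrow(uni$otus), 3L)
  shared <- uni$otus[uni$otus$contains_cultured, ]
  expect_equal(nrow(shared), 1L)
  expect_true(shared$contains_rumen_survey)
  expect_equal(unname(uni$counts[shared$otu_id, c("ds1", "ds2")]), c(1L, 1L))

  # totals: sum of per-dataset tallies equals sum of tier-1 sizes
  expect_equal(sum(uni$counts), sum(ds1$clusters$size) +
                 sum(ds2$clusters$size))

  # disjoint representatives stay separate
  only <- uni$otus[!uni$otus$contains_cultured, ]
  expect_equal(nrow(only), 2L)
  expect_false(any(only$contains_cultured))
})
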