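# Neighbour joining, path distances, nearest-cultured dynamic programme
# (against brute force), length-preserving pruning, and clade partitioning.

test_that("NJ solves the three-taxon case exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # three-point formulas: A:1, B:1, C:3
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("NJ inverts additive matrices (path sums equal inputs)", {
  set.seed(301)
  for (rep in 1:5) {
    tr0 <- random_tree(8 + rep)
    d <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(d)
    d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(d - d2)), 1e-9)
  }
})

test_that("NJ on an all-equal matrix reproduces the common distance", {
  n <- 5
  d <- matrix(2, n, n) - diag(2, n)
  dimnames(d) <- list(letters[1:n], letters[1:n])
  tr <- nj_tree(d)
  d2 <- ape::cophenetic.phylo(tr)[letters[1:n], letters[1:n]]
  expect_lt(max(abs(d - d2)), 1e-9)
})

test_that("NJ input validation rejects malformed matrices", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 1, 0, NA, 2, NA, 0), 3, 3)
  expect_error(nj_tree(d3), "non-finite")
  d4 <- matrix(c(0, -1, 2, -1, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(d4), "negative")
})

test_that("tip-to-tip distances are path sums of branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  expect_equal(tip_to_tip_distance(tr, "A", "B"), 3.0)
  expect_equal(tip_to_tip_distance(tr, "A", "C"), 4.5)
  expect_equal(tip_to_tip_distance(tr, "C", "C"), 0.0)
  expect_equal(tip_to_tip_distance(tr, "B", "A"), 3.0)  # symmetric
  expect_error(tip_to_tip_distance(tr, "A", "Z"), "unknown tip")
})

test_that("nearest-cultured distances: zero rule and small-tree example", {
  tr <- ape::read.tree(text = "((Q:1,K:2):0.5,C:3);")
  res <- nearest_cultured_distances(tr, "C")
  expect_equal(res$distance[res$otu_id == "Q"], 4.5)
  expect_equal(res$nearest_cultured_otu_id[res$otu_id == "Q"], "C")
  # the cultured tip itself: zero and self
  expect_equal(res$distance[res$otu_id == "C"], 0)
  expect_equal(res$nearest_cultured_otu_id[res$otu_id == "C"], "C")

  expect_error(nearest_cultured_distances(tr, character(0)), "empty")
  expect_error(nearest_cultured_distances(tr, "nope"), "not in tree")
})

test_that("two-pass nearest-cultured equals brute force on random trees", {
  set.seed(302)
  for (rep in 1:12) {
    n <- sample(10:200, 1)
    tr <- random_tree(n)
    cult <- sample(tr$tip.label, max(1, round(n * 0.1)))
    got <- nearest_cultured_distances(tr, cult)
    want <- oracle_nearest_cultured(tr, cult)
    expect_equal(got$distance, unname(want[, "distance"]), tolerance = 1e-9)
    expect_equal(got$nearest_cultured_otu_id,
                 tr$tip.label[want[, "nearest"]])
  }
})

test_that("nearest-cultured distance is monotone in the cultured set", {
  set.seed(303)
  tr <- random_tree(60)
  cult <- sample(tr$tip.label, 5)
  extra <- sample(setdiff(tr$tip.label, cult), 1)
  d1 <- nearest_cultured_distances(tr, cult)
  d2 <- nearest_cultured_distances(tr, c(cult, extra))
  expect_true(all(d2$distance <= d1$distance + 1e-12))
})

test_that("pruning preserves kept-pair distances and is idempotent", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  pr <- prune_tree(tr, c("A", "B"))
  expect_equal(tip_to_tip_distance(pr, "A", "B"), 3.0)

  # keeping all tips is a no-op
  expect_equal(prune_tree(tr, c("A", "B", "C")), tr)
  expect_error(prune_tree(tr, c("A", "Z")), "Z")

  set.seed(304)
  big <- random_tree(100)
  keep <- sample(big$tip.label, 40)
  pr2 <- prune_tree(big, keep)
  d0 <- ape::cophenetic.phylo(big)[keep, keep]
  d1 <- ape::cophenetic.phylo(pr2)[keep, keep]
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # idempotent
  pr3 <- prune_tree(pr2, keep)
  d2 <- ape::cophenetic.phylo(pr3)[keep, keep]
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("path sums are invariant to rerooting", {
  set.seed(305)
  tr <- random_tree(30)
  d0 <- ape::cophenetic.phylo(tr)
  re <- ape::root(tr, outgroup = tr$tip.label[7], resolve.root = TRUE)
  d1 <- ape::cophenetic.phylo(re)[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # and so are nearest-cultured results
  cult <- tr$tip.label[1:3]
  r0 <- nearest_cultured_distances(tr, cult)
  r1 <- nearest_cultured_distances(re, cult)
  expect_equal(r0$distance[match(r1$otu_id, r0$otu_id)], r1$distance,
               tolerance = 1e-9)
})

test_that("clade partition: limits and planted lineages", {
  set.seed(306)
  tr <- random_tree(40)
  diam <- max(ape::cophenetic.phylo(tr))
  one <- partition_clades(tr, diam + 1)
  expect_equal(length(unique(one$clade_id)), 1L)

  cher <- min(ape::cophenetic.phylo(tr)[upper.tri(diag(40))])
  all_single <- partition_clades(tr, cher / 2)
  expect_equal(length(unique(all_single$clade_id)), 40L)

  # three planted lineages: tight within, far between
  mk_clade <- function(tag) {
    t <- ape::rtree(5, br = function(k) stats::runif(k, 0.005, 0.02))
    t$tip.label <- paste0(tag, 1:5)
    t
  }
  a <- mk_clade("a")
  b <- mk_clade("b")
  c3 <- mk_clade("c")
  join <- ape::read.tree(text = "(A:1,(B:1,C:1):1);")
  big <- ape::bind.tree(join, a, where = which(join$tip.label == "A"))
  big <- ape::bind.tree(big, b, where = which(big$tip.label == "B"))
  big <- ape::bind.tree(big, c3, where = which(big$tip.label == "C"))
  part <- partition_clades(big, 0.3)
  grp <- split(part$otu_id, part$clade_id)
  expect_equal(length(grp), 3L)
  expect_setequal(vapply(grp, function(g) {
    paste(sort(substr(g, 1, 1)) |> unique(), collapse = "")
  }, character(1)), c("a", "b", "c"))

  expect_error(partition_clades(tr, 0), "must be > 0")
})
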