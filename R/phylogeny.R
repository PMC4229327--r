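# Tree handling for the universal OTUs: p-distance matrix and neighbour
# joining as the self-contained tree builder (an externally estimated newick
# can be ingested instead via read_newick), tip-to-tip path distances,
# nearest-cultured-tip distances with the zero rule, length-preserving
# pruning, and a thresholded partition of the tree into monophyletic clades.

#' P-distance matrix from pairwise global alignments
#'
#' Proportion of mismatched positions among compared (non-gap) aligned
#' positions, for every pair of sequences.  Used as input to [nj_tree].
#'
#' @param records A [seq_records] data frame.
#' @return Symmetric numeric matrix with zero diagonal, labelled by record
#'   id.
#' @export
p_distance_matrix <- function(records) {
  records <- .as_records(records)
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    aln <- .align(records$residues[(i + 1L):n], records$residues[i])
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    p <- nmm / (nm + nmm)
    d[i, (i + 1L):n] <- p
    d[(i + 1L):n, i] <- p
  }
  d
}

#' Neighbour-joining tree
#'
#' Standard neighbour joining on a symmetric distance matrix; negative
#' estimated branch lengths are clamped to zero.  On additive matrices the
#' path sums of the result reproduce the input distances exactly.
#'
#' @param distance_matrix Symmetric numeric matrix, zero diagonal, at least
#'   3 taxa, no negative or non-finite off-diagonal entries.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 3L) stop("need at least 3 taxa for neighbour joining")
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  if (any(d < 0)) stop("negative entries in distance matrix")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Tip-to-tip path distance
#'
#' Sum of branch lengths along the unique path between two tips.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param a,b Tip labels.
#' @return Non-negative path length; 0 when `a == b`.
#' @export
tip_to_tip_distance <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip label: ", a)
  if (is.na(ib)) stop("unknown tip label: ", b)
  if (ia == ib) return(0)
  path <- ape::nodepath(tree, ia, ib)
  edges <- cbind(path[-length(path)], path[-1])
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  # edges along a node path can run either way relative to tree$edge
  idx <- match(paste(edges[, 1], edges[, 2]), key)
  rev_idx <- match(paste(edges[, 2], edges[, 1]), key)
  idx[is.na(idx)] <- rev_idx[is.na(idx)]
  sum(tree$edge.length[idx])
}

#' Nearest cultured tip for every tip of the tree
#'
#' For each tip, the minimum path distance to any tip in the cultured set,
#' computed by a two-pass dynamic programme over the tree (a post-order pass
#' recording the best cultured tip within each subtree, then a pre-order
#' pass propagating the best route via the parent), linear in tree size.
#' Tips flagged as containing a cultured isolate get distance 0 with
#' themselves as nearest tip (the zero rule: an OTU whose cluster contains a
#' cultured sequence is by definition cultured).  Ties among equidistant
#' cultured tips are broken by the lexicographically smallest tip id.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param cultured_tips Character vector of tip labels whose OTUs contain a
#'   cultured isolate.
#' @return Data frame: `otu_id`, `distance`, `nearest_cultured_otu_id`.
#' @export
nearest_cultured_distances <- function(tree, cultured_tips) {
  if (length(cultured_tips) == 0L) stop("cultured tip set is empty")
  missing <- setdiff(cultured_tips, tree$tip.label)
  if (length(missing)) {
    stop("cultured tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  tot <- n + nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  parent <- tr$edge[, 1]
  child <- tr$edge[, 2]
  elen <- tr$edge.length

  down_d <- rep(Inf, tot)
  down_t <- rep(NA_character_, tot)
  cult <- match(cultured_tips, tree$tip.label)
  down_d[cult] <- 0
  down_t[cult] <- tree$tip.label[cult]

  better <- function(d1, t1, d2, t2) {
    # is (d1, t1) strictly better than (d2, t2)?
    d1 < d2 || (d1 == d2 && !is.na(t1) && (is.na(t2) || t1 < t2))
  }
  for (e in seq_along(parent)) {          # postorder: children first
    cand_d <- down_d[child[e]] + elen[e]
    if (better(cand_d, down_t[child[e]], down_d[parent[e]],
               down_t[parent[e]])) {
      down_d[parent[e]] <- cand_d
      down_t[parent[e]] <- down_t[child[e]]
    }
  }

  up_d <- rep(Inf, tot)
  up_t <- rep(NA_character_, tot)
  kids <- split(seq_along(parent), parent)
  for (e in rev(seq_along(parent))) {     # preorder: parents first
    p <- parent[e]
    c_ <- child[e]
    best_d <- up_d[p]
    best_t <- up_t[p]
    for (e2 in kids[[as.character(p)]]) {
      if (e2 == e) next
      sib_d <- down_d[child[e2]] + elen[e2]
      if (better(sib_d, down_t[child[e2]], best_d, best_t)) {
        best_d <- sib_d
        best_t <- down_t[child[e2]]
      }
    }
    up_d[c_] <- best_d + elen[e]
    up_t[c_] <- best_t
  }

  res_d <- numeric(n)
  res_t <- character(n)
  is_cult <- seq_len(n) %in% cult
  for (i in seq_len(n)) {
    if (is_cult[i]) {
      res_d[i] <- 0
      res_t[i] <- tree$tip.label[i]
    } else if (better(down_d[i], down_t[i], up_d[i], up_t[i])) {
      res_d[i] <- down_d[i]
      res_t[i] <- down_t[i]
    } else {
      res_d[i] <- up_d[i]
      res_t[i] <- up_t[i]
    }
  }
  data.frame(otu_id = tree$tip.label, distance = res_d,
             nearest_cultured_otu_id = res_t, stringsAsFactors = FALSE)
}

#' Prune a tree to a tip subset, preserving branch lengths
#'
#' Removed tips and the resulting degree-2 internal nodes are deleted with
#' the lengths of merged edges summed, so all pairwise path distances among
#' kept tips are unchanged.
#'
#' @param tree A `phylo` tree.
#' @param keep_tips Tip labels to retain (at least 2, all present).
#' @return The pruned `phylo` tree.
#' @export
prune_tree <- function(tree, keep_tips) {
  missing <- setdiff(keep_tips, tree$tip.label)
  if (length(missing)) {
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep_tips) < 2L) stop("need at least 2 tips to keep")
  if (length(keep_tips) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep_tips)
}

#' Partition tree tips into monophyletic clades by a diameter threshold
#'
#' Post-order greedy merge: a subtree becomes a single clade exactly when
#' its maximal within-subtree tip-to-tip path distance is at most
#' `max_within_distance` while its parent's subtree would exceed it.  Every
#' tip is assigned to exactly one clade; each multi-tip clade induces a
#' connected (monophyletic) subtree.  An automated, reproducible stand-in
#' for subdividing a large OTU tree into clades by eye.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param max_within_distance Positive clade diameter threshold
#'   (substitutions/site units of the branch lengths).
#' @return Data frame `otu_id`, `clade_id`; clade sizes as attribute
#'   `clade_sizes`.
#' @export
partition_clades <- function(tree, max_within_distance) {
  if (max_within_distance <= 0) stop("max_within_distance must be > 0")
  n <- length(tree$tip.label)
  tot <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  parent <- tr$edge[, 1]
  child <- tr$edge[, 2]
  elen <- tr$edge.length

  depth <- numeric(tot)      # max distance to a tip within the subtree
  within <- numeric(tot)     # max tip-to-tip distance within the subtree
  top2 <- matrix(0, tot, 2)  # two largest child depth contributions
  has_kid <- logical(tot)
  for (e in seq_along(parent)) {
    p <- parent[e]
    contrib <- depth[child[e]] + elen[e]
    if (!has_kid[p]) {
      has_kid[p] <- TRUE
      top2[p, 1] <- contrib
    } else if (contrib > top2[p, 1]) {
      top2[p, 2] <- top2[p, 1]
      top2[p, 1] <- contrib
    } else if (contrib > top2[p, 2]) {
      top2[p, 2] <- contrib
    }
    depth[p] <- max(depth[p], contrib)
    within[p] <- max(within[p], within[child[e]])
  }
  internal <- unique(parent)
  for (p in internal) {
    within[p] <- max(within[p], top2[p, 1] + top2[p, 2])
  }

  # clade roots: subtree fits, parent subtree does not (or node is root)
  par_of <- rep(NA_integer_, tot)
  par_of[child] <- parent
  fits <- within <= max_within_distance
  clade_root <- fits & (is.na(par_of) | !fits[par_of])

  # assign each tip to its unique clade-root ancestor
  clade_of <- rep(NA_integer_, tot)
  roots_in_order <- which(clade_root)
  clade_of[roots_in_order] <- seq_along(roots_in_order)
  for (e in rev(seq_along(parent))) {     # preorder
    if (is.na(clade_of[child[e]])) clade_of[child[e]] <- clade_of[parent[e]]
  }
  ids <- sprintf("clade_%03d", clade_of[seq_len(n)])
  out <- data.frame(otu_id = tree$tip.label, clade_id = ids,
                    stringsAsFactors = FALSE)
  attr(out, "clade_sizes") <- table(ids)
  out
}
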