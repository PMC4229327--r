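# Independent oracles used to freeze expected values: a from-scratch
# affine-gap global aligner, brute-force tree distance minimisation via
# ape's full distance matrices, and a direct transcription of the
# trimmed-mean-of-M formula.  None of these share code with the package
# implementations they check.

# Needleman-Wunsch with affine gaps (match +1, mismatch -1, open 5,
# extend 1), returning the number of identically aligned positions on an
# optimal-score path.  Dynamic programming over three layers with
# traceback; quadratic, for small inputs only.
oracle_align_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(5 + (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(5 + (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - 6, Ix[i - 1, j] - 1)
      Iy[i, j] <- max(M[i, j - 1] - 6, Iy[i, j - 1] - 1)
    }
  }
  # traceback counting matches along one optimal path
  layer <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n + 1
  j <- m + 1
  matches <- 0L
  while (i > 1 || j > 1) {
    if (layer == 1) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      s <- if (A[i - 1] == B[j - 1]) 1 else -1
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      layer <- which.max(prev)
      i <- i - 1
      j <- j - 1
    } else if (layer == 2) {
      from_M <- M[i - 1, j] - 6
      from_Ix <- Ix[i - 1, j] - 1
      layer <- if (from_M >= from_Ix) 1 else 2
      i <- i - 1
    } else {
      from_M <- M[i, j - 1] - 6
      from_Iy <- Iy[i, j - 1] - 1
      layer <- if (from_M >= from_Iy) 1 else 3
      j <- j - 1
    }
    if (i == 1 && j > 1) layer <- 3
    if (j == 1 && i > 1) layer <- 2
  }
  matches
}

# Brute-force nearest cultured tip: full cophenetic matrix, row minima.
oracle_nearest_cultured <- function(tree, cultured) {
  D <- ape::cophenetic.phylo(tree)
  t(vapply(tree$tip.label, function(tip) {
    if (tip %in% cultured) {
      return(c(distance = 0, nearest = match(tip, tree$tip.label)))
    }
    d <- D[tip, cultured]
    # ties: lexicographically smallest cultured tip
    best <- cultured[d == min(d)]
    best <- sort(best)[1]
    c(distance = min(d), nearest = match(best, tree$tip.label))
  }, c(distance = 0, nearest = 0)))
}

# Direct transcription of the doubly trimmed, precision-weighted mean of
# log fold-changes: factor for column j against reference column r.
oracle_tmm_factor <- function(counts, j, r, trim_M = 0.30, trim_A = 0.05) {
  Nj <- sum(counts[, j])
  Nr <- sum(counts[, r])
  keep <- counts[, j] > 0 & counts[, r] > 0
  x <- counts[keep, j]
  xr <- counts[keep, r]
  M <- log2((x / Nj) / (xr / Nr))
  A <- 0.5 * log2((x / Nj) * (xr / Nr))
  w <- (Nj - x) / (Nj * x) + (Nr - xr) / (Nr * xr)
  n <- length(M)
  loL <- floor(n * trim_M) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * trim_A) + 1
  hiS <- n + 1 - loS
  keep2 <- rank(M) >= loL & rank(M) <= hiL &
    rank(A) >= loS & rank(A) <= hiS
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# ---- small fixture builders ----------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions (guaranteed-different bases)
mutate_k <- function(seq, k, positions = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(chars), k)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

records_from <- function(seqs, dataset_id = "test", prefix = "s",
                         cultured = FALSE) {
  seq_records(id = sprintf("%s%03d", prefix, seq_along(seqs)),
              dataset_id = dataset_id, residues = seqs,
              is_cultured = cultured)
}

# random bifurcating tree with uniform branch lengths
random_tree <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}

# Map recovered universal OTUs back to planted taxa by majority vote over
# member-read provenance, and compare recovered flag sets with the truth.
recovery_summary <- function(sim, res) {
  ra <- res$read_assignments
  tx <- sim$truth$reads$taxon[match(ra$read_id, sim$truth$reads$read_id)]
  ok <- !is.na(tx) & !is.na(ra$otu_id)
  votes <- table(ra$otu_id[ok], tx[ok])
  map <- data.frame(otu_id = rownames(votes),
                    taxon = colnames(votes)[apply(votes, 1, which.max)],
                    stringsAsFactors = FALSE)
  m <- merge(res$metrics, map, by = "otu_id", all.x = TRUE)
  m <- merge(m, sim$truth$taxa, by.x = "taxon", by.y = "taxon_id",
             all.x = TRUE, suffixes = c("", ".truth"))
  mapped <- m[!is.na(m$taxon), ]
  list(
    mapped = mapped,
    core_recovered = sort(mapped$taxon[mapped$is_core]),
    core_truth = sort(sim$truth$taxa$taxon_id[sim$truth$taxa$is_core]),
    novel_recovered = sort(mapped$taxon[mapped$is_novel]),
    novel_truth = sort(sim$truth$taxa$taxon_id[sim$truth$taxa$is_novel]),
    abundance_spearman = stats::cor(mapped$scaled_abundance,
                                    mapped$true_mean_percent,
                                    method = "spearman")
  )
}
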