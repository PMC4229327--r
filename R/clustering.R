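# Greedy incremental identity clustering at 97%, abundance-aware chimera
# detection, and the two-tier merge of per-survey OTU representatives with
# the cultured-isolate representatives into universal OTUs.

#' Identity-computation parameters
#'
#' @param threshold Clustering identity threshold, in (0.5, 1] (default 0.97,
#'   the species-level OTU convention).
#' @param word_size K-mer size used by the pre-alignment screen.
#' @param denominator_rule Either `"shorter_sequence"` (identical aligned
#'   positions divided by the shorter input length, the convention of greedy
#'   clustering tools for mixed-length reads; default) or
#'   `"alignment_length"`.
#' @return A list of class `identity_params`.
#' @export
identity_params <- function(threshold = 0.97, word_size = 8,
                            denominator_rule = c("shorter_sequence",
                                                 "alignment_length")) {
  stopifnot(threshold > 0.5, threshold <= 1)
  denominator_rule <- match.arg(denominator_rule)
  structure(list(threshold = threshold, word_size = as.integer(word_size),
                 denominator_rule = denominator_rule),
            class = "identity_params")
}

# Global alignment scoring shared by all identity computations: match +1,
# mismatch -1, gap open -5, gap extend -1.
.sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

.align <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = .sub_matrix(),
    gapOpening = 5, gapExtension = 1)
}

# Identity of one subject against many patterns under `params`.
.identity_many <- function(patterns, subject, params) {
  aln <- .align(patterns, subject)
  nm <- Biostrings::nmatch(aln)
  denom <- switch(
    params$denominator_rule,
    shorter_sequence = pmin(nchar(patterns), nchar(subject)),
    alignment_length =
      nchar(as.character(Biostrings::alignedPattern(aln))))
  nm / denom
}

#' Pairwise sequence identity
#'
#' Global alignment with affine gap penalties (match +1, mismatch -1, gap
#' open -5, extend -1); identity is the number of identically aligned
#' positions divided by the denominator chosen in `params`.  Symmetric.
#'
#' @param a,b DNA strings; `a` may be a vector, giving one identity per
#'   element against the single subject `b`.
#' @param params An [identity_params] object.
#' @return Identity fraction(s) in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, params = identity_params()) {
  stopifnot(nzchar(a), nzchar(b))
  .identity_many(toupper(a), toupper(b), params)
}

#' Greedy incremental clustering at an identity threshold
#'
#' Reads are processed longest-first (ties broken by lexicographic id); each
#' read joins the first existing cluster whose representative it matches at
#' `params$threshold` identity or better, otherwise it founds a new cluster
#' with itself as representative.  The canonical processing order makes the
#' result deterministic and invariant to input file order.
#'
#' @param reads A [seq_records] data frame.
#' @param params An [identity_params] object.
#' @param dataset_id Label for the clustering run; defaults to the single
#'   dataset id of `reads`, or `"universal"` for mixed input.
#' @return A list of class `otu_clusters`: `clusters` (cluster_id, rep_id,
#'   size, dataset_id), `members` (read_id, cluster_id, is_representative),
#'   `rep_records` (the representatives as [seq_records]) and `params`.
#' @export
greedy_cluster <- function(reads, params = identity_params(),
                           dataset_id = NULL) {
  reads <- .as_records(reads)
  if (nrow(reads) == 0L) stop("no reads to cluster")
  if (is.null(dataset_id)) {
    ds <- unique(reads$dataset_id)
    dataset_id <- if (length(ds) == 1L) ds else "universal"
  }
  ord <- order(-nchar(reads$residues), reads$id, method = "radix")
  reads <- reads[ord, , drop = FALSE]

  # identical residue strings always land in the same cluster as their first
  # occurrence in canonical order, so clustering is done on unique sequences
  uniq_idx <- which(!duplicated(reads$residues))
  uniq_seq <- reads$residues[uniq_idx]

  rep_seq <- character(0)
  rep_kmers <- list()
  assign_uniq <- integer(length(uniq_seq))
  for (u in seq_along(uniq_seq)) {
    hit <- 0L
    if (length(rep_seq)) {
      q_kmers <- .kmer_set(uniq_seq[u], params$word_size)
      cand <- which(vapply(rep_kmers, function(rk) any(q_kmers %in% rk),
                           logical(1)))
      if (length(cand)) {
        ids <- .identity_many(rep_seq[cand], uniq_seq[u], params)
        ok <- cand[ids >= params$threshold]
        if (length(ok)) hit <- min(ok)     # first cluster in founding order
      }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, uniq_seq[u])
      rep_kmers[[length(rep_seq)]] <- .kmer_set(uniq_seq[u], params$word_size)
      hit <- length(rep_seq)
    }
    assign_uniq[u] <- hit
  }
  cluster_of <- assign_uniq[match(reads$residues, uniq_seq)]

  cluster_id <- sprintf("%s_C%04d", dataset_id, seq_along(rep_seq))
  # representative = founding read (first in canonical order for its seq)
  rep_row <- vapply(seq_along(rep_seq), function(ci) {
    which(cluster_of == ci & reads$residues == rep_seq[ci])[1]
  }, integer(1))
  clusters <- data.frame(
    cluster_id = cluster_id,
    rep_id = reads$id[rep_row],
    size = as.integer(tabulate(cluster_of, length(rep_seq))),
    dataset_id = dataset_id,
    stringsAsFactors = FALSE
  )
  members <- data.frame(
    read_id = reads$id,
    cluster_id = cluster_id[cluster_of],
    is_representative = seq_len(nrow(reads)) %in% rep_row,
    stringsAsFactors = FALSE
  )
  rep_records <- reads[rep_row, , drop = FALSE]
  structure(list(clusters = clusters, members = members,
                 rep_records = rep_records, params = params),
            class = "otu_clusters")
}

#' Chimera-detection parameters
#'
#' @param p_hi Minimum prefix/suffix identity to each putative parent
#'   (default 0.99).
#' @param p_lo Maximum full-length identity to either parent (default 0.97):
#'   parents must be sufficiently dissimilar to the chimera over its full
#'   length.
#' @param min_fold Minimum abundance fold of a candidate parent's cluster
#'   over the query's cluster (default 2).
#' @return A list of class `chimera_params`.
#' @export
chimera_params <- function(p_hi = 0.99, p_lo = 0.97, min_fold = 2) {
  structure(list(p_hi = p_hi, p_lo = p_lo, min_fold = min_fold),
            class = "chimera_params")
}

#' Detect chimeric sequences from more-abundant parents
#'
#' A sequence is flagged chimeric when some split position and ordered pair
#' of candidate parents (A, B) exist such that its prefix matches A and its
#' suffix matches B at `p_hi` identity or better, while its full-length
#' identity to both A and B stays at or below `p_lo`.  Candidate parents are
#' sequences whose cluster abundance is at least `min_fold` times the
#' query's.  Comparison is positional (ungapped) over the shared length, the
#' regime of window-trimmed amplicons.
#'
#' @param reads [seq_records] to screen (typically cluster representatives).
#' @param cluster_abundances Named numeric vector of cluster abundances,
#'   indexed by read id.
#' @param params A [chimera_params] object.
#' @return List with `clean` and `chimeric` record subsets; `chimeric`
#'   carries a `parents` data frame attribute (read_id, parent_a, parent_b,
#'   split).
#' @export
detect_chimeras <- function(reads, cluster_abundances,
                            params = chimera_params()) {
  reads <- .as_records(reads)
  ab <- cluster_abundances[reads$id]
  if (anyNA(ab)) stop("cluster_abundances missing for some read ids")
  n <- nrow(reads)
  is_chim <- logical(n)
  parents <- vector("list", n)

  for (q in seq_len(n)) {
    cand <- which(ab >= params$min_fold * ab[q] & seq_len(n) != q)
    if (length(cand) < 2L) next
    qs <- charToRaw(reads$residues[q])
    Lq <- length(qs)
    # per-candidate cumulative match counts over the shared prefix
    cum <- lapply(cand, function(j) {
      cs <- charToRaw(reads$residues[j])
      L <- min(Lq, length(cs))
      cumsum(qs[seq_len(L)] == cs[seq_len(L)])
    })
    L <- min(lengths(cum))
    full_id <- vapply(cum, function(v) v[L] / L, numeric(1))
    splits <- seq_len(L - 1L)
    pref_ok <- lapply(cum, function(v) v[splits] >= params$p_hi * splits)
    suf_ok <- lapply(cum, function(v) {
      (v[L] - v[splits]) >= params$p_hi * (L - splits)
    })
    for (ia in seq_along(cand)) {
      if (full_id[ia] > params$p_lo) next
      for (ib in seq_along(cand)) {
        if (ib == ia || full_id[ib] > params$p_lo) next
        s <- which(pref_ok[[ia]] & suf_ok[[ib]])
        if (length(s)) {
          is_chim[q] <- TRUE
          parents[[q]] <- data.frame(read_id = reads$id[q],
                                     parent_a = reads$id[cand[ia]],
                                     parent_b = reads$id[cand[ib]],
                                     split = s[1],
                                     stringsAsFactors = FALSE)
          break
        }
      }
      if (is_chim[q]) break
    }
  }
  chimeric <- reads[is_chim, , drop = FALSE]
  attr(chimeric, "parents") <- do.call(rbind, parents[is_chim])
  list(clean = reads[!is_chim, , drop = FALSE], chimeric = chimeric)
}

#' Merge per-dataset and cultured clusters into universal OTUs
#'
#' Representatives of all first-tier clusters (each survey's OTUs plus the
#' cultured-isolate pool's) are themselves greedily clustered at the same
#' identity threshold.  Member tallies are aggregated per source dataset; an
#' OTU contains a cultured isolate when any cultured representative merged
#' into it.  The two-tier design lets each survey be clustered on its full
#' available region while the merge operates on the shared window.
#'
#' @param dataset_clusters List of `otu_clusters`, one per survey.
#' @param cultured_clusters `otu_clusters` for the cultured pool (or `NULL`).
#' @param params An [identity_params] object.
#' @param min_overlap Representatives shorter than this are excluded from
#'   the merge with a warning (default 50 nt).
#' @return A list of class `universal_otus`: `otus` (otu_id, representative,
#'   contains_cultured, contains_rumen_survey, n_cultured_members), `counts`
#'   (integer matrix OTU x survey of member read counts), `rep_records`, and
#'   `rep_assignments` mapping every tier-1 cluster to its universal OTU.
#' @export
build_universal_otus <- function(dataset_clusters, cultured_clusters = NULL,
                                 params = identity_params(),
                                 min_overlap = 50) {
  all_cl <- dataset_clusters
  if (!is.null(cultured_clusters)) all_cl <- c(all_cl, list(cultured_clusters))
  reps <- do.call(rbind, lapply(all_cl, function(x) {
    r <- x$rep_records
    r$tier1_cluster <- x$clusters$cluster_id[match(r$id, x$clusters$rep_id)]
    r$tier1_size <- x$clusters$size[match(r$id, x$clusters$rep_id)]
    r
  }))
  short <- nchar(reps$residues) < min_overlap
  if (any(short)) {
    warning(sum(short), " representative(s) shorter than ", min_overlap,
            " nt excluded from the universal merge")
    reps <- reps[!short, , drop = FALSE]
  }
  if (anyDuplicated(reps$id)) {
    reps$orig_id <- reps$id
    reps$id <- paste(reps$dataset_id, reps$id, sep = ":")
  } else {
    reps$orig_id <- reps$id
  }
  tier2 <- greedy_cluster(reps, params, dataset_id = "universal")

  survey_ids <- unique(reps$dataset_id[!reps$is_cultured])
  m <- match(tier2$members$read_id, reps$id)
  otu_of_rep <- tier2$members$cluster_id
  n_otu <- nrow(tier2$clusters)
  otu_index <- match(otu_of_rep, tier2$clusters$cluster_id)

  counts <- matrix(0L, nrow = n_otu, ncol = length(survey_ids),
                   dimnames = list(tier2$clusters$cluster_id, survey_ids))
  is_cult_rep <- reps$is_cultured[m]
  for (r in seq_along(m)) {
    if (!is_cult_rep[r]) {
      j <- match(reps$dataset_id[m[r]], survey_ids)
      counts[otu_index[r], j] <- counts[otu_index[r], j] +
        reps$tier1_size[m[r]]
    }
  }
  n_cult <- tapply(ifelse(is_cult_rep, reps$tier1_size[m], 0L),
                   otu_index, sum)
  n_cult_vec <- integer(n_otu)
  n_cult_vec[as.integer(names(n_cult))] <- as.integer(n_cult)

  otu_id <- sprintf("UOTU%04d", seq_len(n_otu))
  rownames(counts) <- otu_id
  otus <- data.frame(
    otu_id = otu_id,
    representative = reps$orig_id[match(tier2$clusters$rep_id, reps$id)],
    contains_cultured = n_cult_vec > 0L,
    contains_rumen_survey = rowSums(counts) > 0L,
    n_cultured_members = n_cult_vec,
    stringsAsFactors = FALSE
  )
  rep_assignments <- data.frame(
    rep_id = reps$orig_id[m],
    dataset_id = reps$dataset_id[m],
    tier1_cluster = reps$tier1_cluster[m],
    tier1_size = reps$tier1_size[m],
    otu_id = otu_id[otu_index],
    stringsAsFactors = FALSE
  )
  rep_records <- tier2$rep_records
  rep_records$id <- otu_id
  structure(list(otus = otus, counts = counts, rep_records = rep_records,
                 rep_assignments = rep_assignments, params = params),
            class = "universal_otus")
}
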