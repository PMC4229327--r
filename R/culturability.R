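# The culturability scoring plane: scale nearest-cultured distance and
# abundance to [0, 1] by their dataset-wide maxima, rank OTUs by Euclidean
# distance from the origin of that plane, and flag core / abundant / novel
# OTUs and cultivation or sequencing candidates.

#' Classification thresholds
#'
#' @param n_datasets Number of surveys D.
#' @param novel_cutoff An OTU is novel when its scaled phylogenetic distance
#'   to the nearest cultured isolate strictly exceeds this (default 0.25).
#' @param abundant_cutoff An OTU is abundant when its scaled abundance
#'   strictly exceeds this (default 0.25).
#' @param core_min_datasets Minimum surveys of occurrence for core
#'   membership; default `ceiling(5/7 * D)`, generalising the five-of-seven
#'   rule while staying integral.
#' @param candidate_similarity Percent-identity cutoff to a cultured rumen
#'   isolate above which a flagged OTU selects that isolate as a
#'   genome-sequencing candidate (default 93).
#' @return A list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(n_datasets,
                                      novel_cutoff = 0.25,
                                      abundant_cutoff = 0.25,
                                      core_min_datasets =
                                        ceiling(5 / 7 * n_datasets),
                                      candidate_similarity = 93) {
  stopifnot(n_datasets >= 1,
            novel_cutoff > 0, novel_cutoff < 1,
            abundant_cutoff > 0, abundant_cutoff < 1,
            core_min_datasets >= 1, core_min_datasets <= n_datasets)
  structure(list(n_datasets = as.integer(n_datasets),
                 novel_cutoff = novel_cutoff,
                 abundant_cutoff = abundant_cutoff,
                 core_min_datasets = as.integer(core_min_datasets),
                 candidate_similarity = candidate_similarity),
            class = "classification_thresholds")
}

#' Scale distances and abundances to the unit plane
#'
#' Each OTU's nearest-cultured distance and mean percentage abundance are
#' reported as the ratio to the largest value observed across the whole OTU
#' set, mapping both axes to \[0, 1\]; the Euclidean distance from the
#' (0, 0) point of that plane gives a combined rank.  If all distances are
#' zero, all scaled distances are zero.
#'
#' @param nearest_distances Data frame from [nearest_cultured_distances]
#'   (columns `otu_id`, `distance`).
#' @param abundance_summary Data frame from [summarize_abundance] (columns
#'   `otu_id`, `mean_percent_abundance`, `prevalence`), covering the same
#'   OTU set.
#' @return Data frame of class `otu_metrics`: `otu_id`, `scaled_distance`,
#'   `scaled_abundance`, `prevalence`, `euclidean` (flags unset until
#'   [classify_otus]).
#' @export
scale_metrics <- function(nearest_distances, abundance_summary) {
  d_ids <- nearest_distances$otu_id
  a_ids <- abundance_summary$otu_id
  if (!setequal(d_ids, a_ids)) {
    only_d <- setdiff(d_ids, a_ids)
    only_a <- setdiff(a_ids, d_ids)
    stop("OTU sets differ; only in distances: ",
         paste(only_d, collapse = ", "), "; only in abundances: ",
         paste(only_a, collapse = ", "))
  }
  m <- match(d_ids, a_ids)
  dist <- nearest_distances$distance
  ab <- abundance_summary$mean_percent_abundance[m]
  if (all(ab <= 0)) stop("need at least one positive abundance")
  max_d <- max(dist)
  scaled_d <- if (max_d > 0) dist / max_d else rep(0, length(dist))
  scaled_a <- ab / max(ab)
  out <- data.frame(
    otu_id = d_ids,
    scaled_distance = scaled_d,
    scaled_abundance = scaled_a,
    prevalence = abundance_summary$prevalence[m],
    euclidean = sqrt(scaled_d^2 + scaled_a^2),
    is_core = NA, is_abundant = NA, is_novel = NA,
    stringsAsFactors = FALSE
  )
  class(out) <- c("otu_metrics", "data.frame")
  out
}

#' Flag core, abundant and novel OTUs
#'
#' Core: present in at least `core_min_datasets` of the D surveys.
#' Abundant: scaled abundance strictly greater than `abundant_cutoff`.
#' Novel: scaled phylogenetic distance strictly greater than `novel_cutoff`.
#' The flags are independent and may overlap.
#'
#' @param metrics Data frame from [scale_metrics].
#' @param thresholds A [classification_thresholds] object.
#' @return `metrics` with `is_core`, `is_abundant`, `is_novel` set.
#' @export
classify_otus <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  D <- thresholds$n_datasets
  n_present <- round(metrics$prevalence * D)
  metrics$is_core <- n_present >= thresholds$core_min_datasets
  metrics$is_abundant <- metrics$scaled_abundance > thresholds$abundant_cutoff
  metrics$is_novel <- metrics$scaled_distance > thresholds$novel_cutoff
  metrics
}

#' Select cultivation and genome-sequencing candidates
#'
#' Among OTUs flagged core, abundant or novel: those whose 16S similarity to
#' a cultured rumen isolate exceeds `candidate_similarity` percent nominate
#' that isolate as a sequencing candidate, de-duplicated when several OTUs
#' share the same nearest isolate (the highest-similarity OTU is kept); the
#' remainder are emitted as taxa requiring further cultivation effort.
#'
#' @param metrics Classified [otu_metrics] (flags set).
#' @param taxonomy Data frame with columns `otu_id`,
#'   `similarity_to_nearest_cultured` (percent in \[0, 100\], `NA` when
#'   unknown), `nearest_cultured_isolate` (isolate id) and optionally
#'   `nearest_isolate_rumen` (logical; assumed `TRUE` when absent).
#' @param thresholds A [classification_thresholds] object.
#' @return List with `candidates` (one row per distinct isolate) and
#'   `needs_cultivation` (flagged OTUs without a close cultured rumen
#'   relative).
#' @export
select_candidates <- function(metrics, taxonomy, thresholds) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (anyNA(metrics$is_core)) stop("run classify_otus() first")
  flagged <- metrics[metrics$is_core | metrics$is_abundant |
                       metrics$is_novel, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    empty <- flagged[, "otu_id", drop = FALSE]
    return(list(candidates = cbind(empty, nearest_cultured_isolate =
                                     character(0),
                                   similarity = numeric(0)),
                needs_cultivation = empty))
  }
  tx <- taxonomy[match(flagged$otu_id, taxonomy$otu_id), , drop = FALSE]
  sim <- tx$similarity_to_nearest_cultured
  rumen <- if ("nearest_isolate_rumen" %in% names(tx)) {
    isTRUE_v <- tx$nearest_isolate_rumen
    !is.na(isTRUE_v) & isTRUE_v
  } else rep(TRUE, nrow(tx))
  is_cand <- !is.na(sim) & sim > thresholds$candidate_similarity & rumen

  cand <- data.frame(otu_id = flagged$otu_id[is_cand],
                     nearest_cultured_isolate =
                       tx$nearest_cultured_isolate[is_cand],
                     similarity = sim[is_cand],
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$similarity, cand$otu_id), , drop = FALSE]
  cand <- cand[!duplicated(cand$nearest_cultured_isolate), , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand,
       needs_cultivation = flagged[!is_cand, , drop = FALSE])
}
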