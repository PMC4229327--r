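# Orchestration: an in-memory end-to-end runner over the stage functions,
# and a file-based stage interface (simulate / preprocess / cluster / merge
# / tree / distances / abundance / classify / report / all) whose artifacts
# are plain files with a checksum manifest, enabling partial reruns with no
# hidden state.

#' Run the whole culturability analysis in memory
#'
#' Chains the pipeline stages in analysis order: orientation screening,
#' anchor derivation and trimming per survey, per-survey greedy clustering
#' at 97%, chimera removal among cluster representatives, the two-tier
#' universal-OTU merge with the cultured pool, tree building (neighbour
#' joining on p-distances, or an ingested tree), nearest-cultured-tip
#' distances, TMM abundance and prevalence, scaling and core/abundant/novel
#' classification, clade partitioning, and (when a per-OTU taxonomy is
#' supplied) the phylum roll-ups and candidate selection.
#'
#' @param datasets Named list of [seq_records], one per survey.
#' @param cultured [seq_records] of the cultured-isolate pool.
#' @param reference Reference 16S string for orientation; defaults to the
#'   first cultured sequence.
#' @param trim A [trim_spec] to use for every survey, or `NULL` to derive
#'   anchors per survey from the conserved columns of its reads.
#' @param otu_taxonomy Optional per-OTU taxonomy (columns `otu_id`,
#'   `phylum`, `nearest_cultured_isolate`,
#'   `similarity_to_nearest_cultured`, `nearest_isolate_rumen`).
#' @param identity An [identity_params].
#' @param chimera A [chimera_params].
#' @param thresholds A [classification_thresholds]; defaults to the
#'   five-of-seven core rule generalised to the number of surveys with 0.25
#'   cutoffs.
#' @param conservation_threshold Column conservation for anchor derivation
#'   (default 0.97: anchor motifs are the near-invariant flanks of the
#'   homologous window, so a stringent cutoff keeps hypervariable columns
#'   from ever qualifying).
#' @param clade_threshold Maximum within-clade tip-to-tip distance for the
#'   clade partition (default 0.5 substitutions/site).
#' @param orient_k K-mer size for orientation voting (default 12).
#' @param tree Optional externally built `phylo` tree over universal OTU
#'   ids (ingest path); when `NULL`, neighbour joining on alignment
#'   p-distances of the OTU representatives is used.
#' @return A list of class `rumencult_result` with elements
#'   `trim_reports`, `dataset_clusters`, `chimeras`, `universal`, `counts`,
#'   `tree`, `survey_tree`, `distances`, `factors`, `abundance`, `metrics`,
#'   `clades`, `read_assignments`, and (with taxonomy) `flag_summary`,
#'   `phylum_table`, `candidates`.
#' @export
run_pipeline <- function(datasets, cultured, reference = NULL, trim = NULL,
                         otu_taxonomy = NULL,
                         identity = identity_params(),
                         chimera = chimera_params(),
                         thresholds = NULL,
                         conservation_threshold = 0.97,
                         clade_threshold = 0.5,
                         orient_k = 12,
                         tree = NULL) {
  stopifnot(length(datasets) >= 2, !is.null(names(datasets)))
  if (is.null(reference)) reference <- cultured$residues[1]

  trim_reports <- list()
  dataset_clusters <- list()
  chimeras <- list()
  for (ds in names(datasets)) {
    oriented <- orient_reads(datasets[[ds]], reference, k = orient_k)
    spec <- if (is.null(trim)) {
      .derive_dataset_anchors(oriented, conservation_threshold)
    } else {
      trim
    }
    trimmed <- .trim_with_default_minlen(oriented, spec)
    trim_reports[[ds]] <- trimmed$report
    cl <- greedy_cluster(trimmed$kept, identity, dataset_id = ds)
    scr <- detect_chimeras(
      cl$rep_records,
      stats::setNames(cl$clusters$size, cl$clusters$rep_id),
      chimera)
    chimeras[[ds]] <- scr$chimeric
    dataset_clusters[[ds]] <- .drop_clusters(cl, scr$chimeric$id)
  }

  cult_spec <- if (is.null(trim)) {
    .derive_dataset_anchors(cultured, conservation_threshold)
  } else {
    trim
  }
  cult_trim <- .trim_with_default_minlen(cultured, cult_spec)
  cultured_clusters <- greedy_cluster(cult_trim$kept, identity,
                                      dataset_id = "cultured")

  universal <- build_universal_otus(dataset_clusters, cultured_clusters,
                                    identity)
  survey_otus <- universal$otus$otu_id[universal$otus$contains_rumen_survey]
  counts <- universal$counts[survey_otus, , drop = FALSE]

  if (is.null(tree)) {
    tree <- nj_tree(p_distance_matrix(universal$rep_records))
  } else {
    missing <- setdiff(universal$otus$otu_id, tree$tip.label)
    if (length(missing)) {
      stop("ingested tree lacks tip(s): ", paste(missing, collapse = ", "))
    }
  }
  cultured_tips <- universal$otus$otu_id[universal$otus$contains_cultured]
  distances <- nearest_cultured_distances(tree, cultured_tips)

  factors <- tmm_factors(counts)
  abundance <- summarize_abundance(counts, factors)
  metrics <- scale_metrics(
    distances[distances$otu_id %in% survey_otus, , drop = FALSE],
    abundance)
  if (is.null(thresholds)) {
    thresholds <- classification_thresholds(n_datasets = ncol(counts))
  }
  metrics <- classify_otus(metrics, thresholds)

  clades <- partition_clades(tree, clade_threshold)
  survey_tree <- if (length(survey_otus) >= 2) {
    prune_tree(tree, survey_otus)
  }

  read_assignments <- .read_assignments(dataset_clusters, universal)

  out <- list(trim_reports = do.call(rbind, trim_reports),
              dataset_clusters = dataset_clusters,
              chimeras = chimeras,
              cultured_clusters = cultured_clusters,
              universal = universal, counts = counts,
              tree = tree, survey_tree = survey_tree,
              distances = distances, factors = factors,
              abundance = abundance, metrics = metrics,
              thresholds = thresholds, clades = clades,
              read_assignments = read_assignments)
  if (!is.null(otu_taxonomy)) {
    out$flag_summary <- summarize_flags(metrics, otu_taxonomy,
                                        n_datasets = ncol(counts))
    out$phylum_table <- summarize_by_phylum(metrics$otu_id, otu_taxonomy)
    out$candidates <- select_candidates(metrics, otu_taxonomy, thresholds)
  }
  class(out) <- "rumencult_result"
  out
}

# Anchor derivation for one survey: conserved-column scan over the unique
# modal-length sequences (the survey's reads share one amplicon window, so
# those are already positionally homologous).
.derive_dataset_anchors <- function(records, conservation_threshold,
                                    max_seqs = 200) {
  lens <- nchar(records$residues)
  modal_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  seqs <- unique(records$residues[lens == modal_len])
  if (length(seqs) > max_seqs) seqs <- seqs[seq_len(max_seqs)]
  derive_anchors(seqs, conservation_threshold)
}

# Trim, then apply the default dataset-specific minimum length (half the
# median trimmed length) when the spec does not fix one.
.trim_with_default_minlen <- function(reads, spec) {
  res <- trim_to_anchors(reads, spec)
  if (spec$min_length <= 1L && nrow(res$kept) > 0) {
    min_len <- floor(0.5 * stats::median(nchar(res$kept$residues)))
    short <- nchar(res$kept$residues) < min_len
    if (any(short)) {
      res$kept <- res$kept[!short, , drop = FALSE]
      res$report$n_too_short <- res$report$n_too_short + sum(short)
      res$report$n_kept <- nrow(res$kept)
      res$report$fraction_discarded <-
        1 - res$report$n_kept / res$report$n_input
      res$report$mean_length_after <- mean(nchar(res$kept$residues))
    }
  }
  res
}

# Remove clusters (by representative id) flagged as chimeric.
.drop_clusters <- function(cl, chimeric_rep_ids) {
  if (length(chimeric_rep_ids) == 0L) return(cl)
  drop <- cl$clusters$rep_id %in% chimeric_rep_ids
  gone <- cl$clusters$cluster_id[drop]
  cl$clusters <- cl$clusters[!drop, , drop = FALSE]
  cl$members <- cl$members[!cl$members$cluster_id %in% gone, , drop = FALSE]
  cl$rep_records <- cl$rep_records[!cl$rep_records$id %in% chimeric_rep_ids,
                                   , drop = FALSE]
  cl
}

# read -> tier-1 cluster -> universal OTU mapping
.read_assignments <- function(dataset_clusters, universal) {
  per_ds <- lapply(dataset_clusters, function(cl) {
    data.frame(read_id = cl$members$read_id,
               dataset_id = cl$clusters$dataset_id[1],
               tier1_cluster = cl$members$cluster_id,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, c(per_ds, make.row.names = FALSE))
  ra <- universal$rep_assignments
  m$otu_id <- ra$otu_id[match(m$tier1_cluster, ra$tier1_cluster)]
  m
}

#' Majority-vote OTU taxonomy from read-level annotations
#'
#' Converts a per-taxon taxonomy table plus read-level truth (as produced
#' by [simulate_surveys]) into the per-OTU taxonomy input the report stage
#' expects, by majority vote over each OTU's member reads.
#'
#' @param read_assignments Data frame from a pipeline run (`read_id`,
#'   `otu_id`).
#' @param read_taxa Data frame `read_id`, `taxon` (NA for chimeras).
#' @param taxonomy Per-taxon table with `taxon_id`, `phylum`,
#'   `nearest_cultured_isolate`, `similarity_to_nearest_cultured`,
#'   `nearest_isolate_rumen`.
#' @return Per-OTU taxonomy data frame keyed by `otu_id`.
#' @export
otu_taxonomy_from_reads <- function(read_assignments, read_taxa, taxonomy) {
  taxon <- read_taxa$taxon[match(read_assignments$read_id,
                                 read_taxa$read_id)]
  ok <- !is.na(taxon) & !is.na(read_assignments$otu_id)
  votes <- table(read_assignments$otu_id[ok], taxon[ok])
  major <- colnames(votes)[apply(votes, 1, which.max)]
  tx <- taxonomy[match(major, taxonomy$taxon_id), , drop = FALSE]
  data.frame(otu_id = rownames(votes),
             taxon_id = major,
             phylum = tx$phylum,
             nearest_cultured_isolate = tx$nearest_cultured_isolate,
             similarity_to_nearest_cultured =
               tx$similarity_to_nearest_cultured,
             nearest_isolate_rumen = tx$nearest_isolate_rumen,
             stringsAsFactors = FALSE)
}
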