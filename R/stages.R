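# File-based stage runner: each stage reads its inputs from, and writes its
# outputs to, a working directory of plain files, with an md5 manifest for
# provenance.  Stages fail with the name of the stage to run first when an
# upstream artifact is missing.

#' Pipeline configuration for the stage runner
#'
#' @param outdir Working directory for stage artifacts.
#' @param seed Seed forwarded to the simulation stage (the only source of
#'   randomness in the pipeline).
#' @param sim A [simulation_config]; defaults to `simulation_config(seed)`.
#' @param identity An [identity_params].
#' @param chimera A [chimera_params].
#' @param thresholds Optional [classification_thresholds] (derived from the
#'   data when `NULL`).
#' @param conservation_threshold,clade_threshold,orient_k See
#'   [run_pipeline].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            sim = simulation_config(seed),
                            identity = identity_params(),
                            chimera = chimera_params(),
                            thresholds = NULL,
                            conservation_threshold = 0.97,
                            clade_threshold = 0.5,
                            orient_k = 12) {
  structure(list(outdir = outdir, seed = seed, sim = sim,
                 identity = identity, chimera = chimera,
                 thresholds = thresholds,
                 conservation_threshold = conservation_threshold,
                 clade_threshold = clade_threshold, orient_k = orient_k),
            class = "pipeline_config")
}

.stage_order <- c("simulate", "preprocess", "cluster", "merge", "tree",
                  "distances", "abundance", "classify", "report")

.need <- function(path, stage) {
  if (!all(file.exists(path))) {
    stop("missing artifact(s) ", paste(basename(path), collapse = ", "),
         "; run the '", stage, "' stage first", call. = FALSE)
  }
}

.ds_from_files <- function(outdir, pattern) {
  f <- list.files(outdir, pattern = pattern)
  sub(pattern, "\\1", f)
}

#' Run one pipeline stage (or all of them) against a working directory
#'
#' Stage names: `simulate`, `preprocess`, `cluster`, `merge`, `tree`,
#' `distances`, `abundance`, `classify`, `report`, `all`.  Artifacts are
#' tab-separated tables, FASTA and newick files under `config$outdir`; an
#' md5 checksum manifest (`manifest.tsv`) is rewritten after every stage,
#' so a rerun on unchanged inputs is verifiably identical.
#'
#' @param name Stage name.
#' @param config A [pipeline_config].
#' @return Invisibly, the paths written by the stage.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  name <- match.arg(name, c(.stage_order, "all"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") {
    for (s in .stage_order) run_stage(s, config)
    return(invisible(file.path(config$outdir, "manifest.tsv")))
  }
  paths <- switch(name,
                  simulate = .stage_simulate(config),
                  preprocess = .stage_preprocess(config),
                  cluster = .stage_cluster(config),
                  merge = .stage_merge(config),
                  tree = .stage_tree(config),
                  distances = .stage_distances(config),
                  abundance = .stage_abundance(config),
                  classify = .stage_classify(config),
                  report = .stage_report(config))
  .write_manifest(config$outdir)
  invisible(paths)
}

.write_manifest <- function(outdir) {
  files <- setdiff(list.files(outdir), "manifest.tsv")
  df <- data.frame(file = files,
                   md5 = unname(tools::md5sum(file.path(outdir, files))),
                   stringsAsFactors = FALSE)
  .write_tsv(df, file.path(outdir, "manifest.tsv"))
}

.stage_simulate <- function(config) {
  out <- config$outdir
  sim <- simulate_surveys(config$sim)
  paths <- character(0)
  for (ds in names(sim$datasets)) {
    p <- file.path(out, sprintf("reads_%s.fasta", ds))
    write_fasta(sim$datasets[[ds]], p)
    paths <- c(paths, p)
  }
  write_fasta(sim$cultured, file.path(out, "cultured.fasta"))
  .write_tsv(sim$taxonomy, file.path(out, "taxonomy.tsv"))
  .write_tsv(sim$truth$reads, file.path(out, "truth_reads.tsv"))
  .write_tsv(sim$truth$taxa, file.path(out, "truth_taxa.tsv"))
  writeLines(c(">reference", sim$reference),
             file.path(out, "reference.fasta"))
  c(paths, file.path(out, c("cultured.fasta", "taxonomy.tsv",
                            "truth_reads.tsv", "truth_taxa.tsv",
                            "reference.fasta")))
}

.stage_preprocess <- function(config) {
  out <- config$outdir
  .need(file.path(out, "cultured.fasta"), "simulate")
  ds_ids <- .ds_from_files(out, "^reads_(.+)\\.fasta$")
  if (length(ds_ids) == 0L) .need(file.path(out, "reads_x.fasta"), "simulate")
  cultured <- read_fasta(file.path(out, "cultured.fasta"), "cultured",
                         cultured_flag = TRUE)
  reference <- cultured$residues[1]
  reports <- list()
  paths <- character(0)
  for (ds in ds_ids) {
    reads <- read_fasta(file.path(out, sprintf("reads_%s.fasta", ds)), ds)
    oriented <- orient_reads(reads, reference, k = config$orient_k)
    spec <- .derive_dataset_anchors(oriented, config$conservation_threshold)
    res <- .trim_with_default_minlen(oriented, spec)
    p <- file.path(out, sprintf("trimmed_%s.fasta", ds))
    write_fasta(res$kept, p)
    reports[[ds]] <- res$report
    paths <- c(paths, p)
  }
  cult_spec <- .derive_dataset_anchors(cultured,
                                       config$conservation_threshold)
  cult_res <- .trim_with_default_minlen(cultured, cult_spec)
  write_fasta(cult_res$kept, file.path(out, "trimmed_cultured.fasta"))
  .write_tsv(do.call(rbind, c(reports, make.row.names = FALSE)),
             file.path(out, "trim_report.tsv"))
  c(paths, file.path(out, c("trimmed_cultured.fasta", "trim_report.tsv")))
}

.stage_cluster <- function(config) {
  out <- config$outdir
  .need(file.path(out, "trimmed_cultured.fasta"), "preprocess")
  ds_ids <- .ds_from_files(out, "^trimmed_(.+)\\.fasta$")
  ds_ids <- setdiff(ds_ids, "cultured")
  paths <- character(0)
  for (ds in ds_ids) {
    reads <- read_fasta(file.path(out, sprintf("trimmed_%s.fasta", ds)), ds)
    cl <- greedy_cluster(reads, config$identity, dataset_id = ds)
    scr <- detect_chimeras(
      cl$rep_records,
      stats::setNames(cl$clusters$size, cl$clusters$rep_id),
      config$chimera)
    cl <- .drop_clusters(cl, scr$chimeric$id)
    .write_tsv(cl$members, file.path(out, sprintf("clusters_%s.tsv", ds)))
    write_fasta(cl$rep_records, file.path(out, sprintf("reps_%s.fasta", ds)))
    .write_tsv(data.frame(read_id = scr$chimeric$id),
               file.path(out, sprintf("chimeras_%s.tsv", ds)))
    paths <- c(paths, file.path(out, sprintf(c("clusters_%s.tsv",
                                               "reps_%s.fasta"), ds)))
  }
  cultured <- read_fasta(file.path(out, "trimmed_cultured.fasta"),
                         "cultured", cultured_flag = TRUE)
  ccl <- greedy_cluster(cultured, config$identity, dataset_id = "cultured")
  .write_tsv(ccl$members, file.path(out, "clusters_cultured.tsv"))
  write_fasta(ccl$rep_records, file.path(out, "reps_cultured.fasta"))
  c(paths, file.path(out, c("clusters_cultured.tsv", "reps_cultured.fasta")))
}

# rebuild a minimal otu_clusters object from stage files
.load_clusters <- function(outdir, ds, cultured = FALSE) {
  members <- read_metrics_table(file.path(outdir,
                                          sprintf("clusters_%s.tsv", ds)))
  reps <- read_fasta(file.path(outdir, sprintf("reps_%s.fasta", ds)), ds,
                     cultured_flag = cultured)
  sizes <- table(members$cluster_id)
  rep_cluster <- members$cluster_id[members$is_representative]
  rep_id <- members$read_id[members$is_representative]
  ord <- order(rep_cluster)
  clusters <- data.frame(cluster_id = rep_cluster[ord],
                         rep_id = rep_id[ord],
                         size = as.integer(sizes[rep_cluster[ord]]),
                         dataset_id = ds, stringsAsFactors = FALSE)
  reps <- reps[match(clusters$rep_id, reps$id), , drop = FALSE]
  structure(list(clusters = clusters, members = members,
                 rep_records = reps, params = NULL),
            class = "otu_clusters")
}

.stage_merge <- function(config) {
  out <- config$outdir
  .need(file.path(out, "reps_cultured.fasta"), "cluster")
  ds_ids <- setdiff(.ds_from_files(out, "^reps_(.+)\\.fasta$"),
                    c("cultured", "universal"))
  dataset_clusters <- lapply(stats::setNames(ds_ids, ds_ids),
                             function(ds) .load_clusters(out, ds))
  cultured_clusters <- .load_clusters(out, "cultured", cultured = TRUE)
  universal <- build_universal_otus(dataset_clusters, cultured_clusters,
                                    config$identity)
  .write_tsv(universal$otus, file.path(out, "universal_otus.tsv"))
  write_counts_table(universal$counts, file.path(out, "counts.tsv"))
  write_fasta(universal$rep_records, file.path(out, "reps_universal.fasta"))
  ra <- .read_assignments(dataset_clusters, universal)
  .write_tsv(ra, file.path(out, "read_assignments.tsv"))
  tr_path <- file.path(out, "truth_reads.tsv")
  tx_path <- file.path(out, "taxonomy.tsv")
  if (file.exists(tr_path) && file.exists(tx_path)) {
    otax <- otu_taxonomy_from_reads(ra, read_metrics_table(tr_path),
                                    read_metrics_table(tx_path))
    .write_tsv(otax, file.path(out, "otu_taxonomy.tsv"))
  }
  file.path(out, c("universal_otus.tsv", "counts.tsv",
                   "reps_universal.fasta", "read_assignments.tsv"))
}

.stage_tree <- function(config) {
  out <- config$outdir
  .need(file.path(out, "reps_universal.fasta"), "merge")
  reps <- read_fasta(file.path(out, "reps_universal.fasta"), "universal")
  tree <- nj_tree(p_distance_matrix(reps))
  write_newick(tree, file.path(out, "tree.nwk"))
  file.path(out, "tree.nwk")
}

.stage_distances <- function(config) {
  out <- config$outdir
  .need(file.path(out, "tree.nwk"), "tree")
  .need(file.path(out, "universal_otus.tsv"), "merge")
  tree <- read_newick(file.path(out, "tree.nwk"))
  otus <- read_metrics_table(file.path(out, "universal_otus.tsv"))
  d <- nearest_cultured_distances(tree,
                                  otus$otu_id[otus$contains_cultured])
  .write_tsv(d, file.path(out, "distances.tsv"))
  clades <- partition_clades(tree, config$clade_threshold)
  .write_tsv(clades, file.path(out, "clades.tsv"))
  file.path(out, c("distances.tsv", "clades.tsv"))
}

.stage_abundance <- function(config) {
  out <- config$outdir
  .need(file.path(out, "counts.tsv"), "merge")
  counts <- read_counts_table(file.path(out, "counts.tsv"))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  factors <- tmm_factors(counts)
  .write_tsv(data.frame(dataset_id = names(factors$factors),
                        factor = factors$factors,
                        effective_library_size =
                          factors$effective_library_size,
                        reference = names(factors$factors) ==
                          factors$reference_dataset),
             file.path(out, "tmm_factors.tsv"))
  .write_tsv(summarize_abundance(counts, factors),
             file.path(out, "abundance.tsv"))
  file.path(out, c("tmm_factors.tsv", "abundance.tsv"))
}

.stage_classify <- function(config) {
  out <- config$outdir
  .need(file.path(out, "distances.tsv"), "distances")
  .need(file.path(out, "abundance.tsv"), "abundance")
  d <- read_metrics_table(file.path(out, "distances.tsv"))
  ab <- read_metrics_table(file.path(out, "abundance.tsv"))
  counts <- read_counts_table(file.path(out, "counts.tsv"))
  metrics <- scale_metrics(d[d$otu_id %in% ab$otu_id, , drop = FALSE], ab)
  thr <- config$thresholds
  if (is.null(thr)) thr <- classification_thresholds(ncol(counts))
  metrics <- classify_otus(metrics, thr)
  write_metrics_table(metrics, file.path(out, "metrics.tsv"))
  file.path(out, "metrics.tsv")
}

.stage_report <- function(config) {
  out <- config$outdir
  .need(file.path(out, "metrics.tsv"), "classify")
  metrics <- read_metrics_table(file.path(out, "metrics.tsv"))
  counts <- read_counts_table(file.path(out, "counts.tsv"))
  tx_path <- file.path(out, "otu_taxonomy.tsv")
  paths <- character(0)
  if (file.exists(tx_path)) {
    otax <- read_metrics_table(tx_path)
    fs <- summarize_flags(metrics, otax, n_datasets = ncol(counts))
    for (fn in names(fs$by_flag)) {
      p <- file.path(out, sprintf("report_%s_phyla.tsv", fn))
      .write_tsv(fs$by_flag[[fn]], p)
      paths <- c(paths, p)
    }
    .write_tsv(fs$prevalence_strata,
               file.path(out, "report_prevalence_strata.tsv"))
    .write_tsv(summarize_by_phylum(metrics$otu_id, otax),
               file.path(out, "report_otus_by_phylum.tsv"))
    thr <- config$thresholds
    if (is.null(thr)) thr <- classification_thresholds(ncol(counts))
    cand <- select_candidates(metrics, otax, thr)
    .write_tsv(cand$candidates, file.path(out, "candidates.tsv"))
    .write_tsv(cand$needs_cultivation,
               file.path(out, "needs_cultivation.tsv"))
    paths <- c(paths, file.path(out, c("report_prevalence_strata.tsv",
                                       "report_otus_by_phylum.tsv",
                                       "candidates.tsv",
                                       "needs_cultivation.tsv")))
  }
  paths
}
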