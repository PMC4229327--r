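# Synthetic multi-survey 16S community generator with full ground truth.
# Emulates the statistical structure the analysis assumes: several surveys
# covering overlapping but non-identical windows of a master 16S-like
# reference, log-normally distributed taxon abundances with a shared core
# taxon set, community lineages at controlled divergence from a cultured
# reference pool, plus planted chimeras and reverse-complemented reads.

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a seven-survey rumen
#' meta-analysis: 7 surveys of 2000 reads, a 40-sequence cultured pool, 40
#' community taxa of which half are core (planted in every survey) and 6
#' are novel lineages far from any cultured reference.
#'
#' @param seed Integer seed; every random choice of the generator derives
#'   from it.
#' @param n_datasets Number of surveys (default 7).
#' @param reads_per_dataset Reads per survey (default 2000).
#' @param n_cultured_refs Size of the cultured-isolate pool (default 40).
#' @param n_taxa Number of community taxa (default 40).
#' @param n_novel_lineages Taxa evolved directly from the master reference
#'   at `novel_divergence`, far from every cultured reference (default 6).
#' @param core_fraction Fraction of taxa planted in all surveys (default
#'   0.5); remaining taxa occur in fewer surveys than the core rule
#'   requires.
#' @param novel_divergence Expected substitutions/site of novel lineages
#'   from the master reference (default 0.30: deep uncultured clades, six
#'   times the cultured pool radius, so their scaled distances sit near 1).
#' @param near_divergence Divergence of cultured-matching taxa from their
#'   (distinct) parent isolates (default 0.02, inside the 97% OTU radius).
#' @param mid_divergence Divergence of uncultured-but-not-novel taxa from
#'   their parent isolates (default 0.035: outside the OTU radius but well
#'   inside the novelty cutoff on the scaled axis).
#' @param mid_fraction Fraction of non-novel taxa at `mid_divergence`
#'   (default 0.35).
#' @param cultured_divergence Divergence of each cultured reference from
#'   the master (default 0.05), i.e. the pool radius.
#' @param rumen_fraction_cultured Fraction of cultured references annotated
#'   as rumen isolates (default 0.6).
#' @param abundance_sigma_between,abundance_sigma_within Log-normal
#'   standard deviations across taxa and across surveys within a taxon
#'   (defaults 1.0 and 0.3; core taxa share their across-survey mean).
#' @param per_base_error_rate Per-base substitution error rate on reads
#'   (default 0).
#' @param chimera_fraction Fraction of reads spliced from two parent reads
#'   (default 0.02).
#' @param revcomp_fraction Fraction of reads emitted reverse-complemented
#'   (default 0.10).
#' @param ref_length Master reference length in nt (default 800).
#' @param anchor_length Length of the conserved anchor motifs (default 12).
#' @param anchor5_start,anchor3_start 1-based positions of the anchors on
#'   the master (defaults 41 and 431; the inter-anchor homologous region is
#'   what every survey shares).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_datasets = 7,
                              reads_per_dataset = 2000,
                              n_cultured_refs = 40,
                              n_taxa = 40,
                              n_novel_lineages = 6,
                              core_fraction = 0.5,
                              novel_divergence = 0.30,
                              near_divergence = 0.02,
                              mid_divergence = 0.035,
                              mid_fraction = 0.35,
                              cultured_divergence = 0.05,
                              rumen_fraction_cultured = 0.6,
                              abundance_sigma_between = 1.0,
                              abundance_sigma_within = 0.3,
                              per_base_error_rate = 0,
                              chimera_fraction = 0.02,
                              revcomp_fraction = 0.10,
                              ref_length = 800,
                              anchor_length = 12,
                              anchor5_start = 41,
                              anchor3_start = 431) {
  cfg <- as.list(environment())
  fracs <- c(core_fraction, mid_fraction, rumen_fraction_cultured,
             per_base_error_rate, chimera_fraction, revcomp_fraction)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            n_datasets >= 2, reads_per_dataset >= 1,
            n_novel_lineages <= n_taxa,
            n_taxa - n_novel_lineages <= n_cultured_refs,
            anchor5_start + anchor_length <= anchor3_start,
            anchor3_start + anchor_length - 1 <= ref_length)
  structure(cfg, class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

# sample() safe for length-1 vectors
.resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

# i.i.d. substitutions at `rate` on `sites` of a character vector sequence
.mutate <- function(chars, rate, sites) {
  hit <- sites[stats::runif(length(sites)) < rate]
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(.BASES, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  chars
}

.hamming_frac <- function(a, b) {
  x <- charToRaw(a)
  y <- charToRaw(b)
  L <- min(length(x), length(y))
  sum(x[seq_len(L)] != y[seq_len(L)]) / L
}

#' Simulate surveys, a cultured pool, taxonomy and ground truth
#'
#' See [simulation_config] for the generative model.  Fully reproducible
#' from the seed: two runs with the same configuration produce identical
#' output.
#'
#' @param config A [simulation_config].
#' @return A list of class `rumen_simulation`:
#'   \describe{
#'     \item{datasets}{named list of [seq_records], one per survey;}
#'     \item{cultured}{[seq_records] of the isolate pool (dataset
#'       `"cultured"`);}
#'     \item{taxonomy}{per-taxon table: `taxon_id`, `phylum`,
#'       `nearest_cultured_isolate`, `similarity_to_nearest_cultured`,
#'       `nearest_isolate_rumen`;}
#'     \item{truth}{list with `reads` (read_id, dataset_id, taxon,
#'       is_chimera, parent_a, parent_b, was_revcomped) and `taxa`
#'       (taxon_id, is_core, is_novel, true_nearest_divergence,
#'       n_datasets_present, true_mean_percent), plus the true relative
#'       abundance matrix as attribute `rel_abundance`;}
#'     \item{reference}{the master 16S-like sequence;}
#'     \item{trim}{a [trim_spec] carrying the planted anchors;}
#'     \item{windows}{per-survey amplicon intervals on the master;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_surveys <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  master <- sample(.BASES, cfg$ref_length, replace = TRUE)
  a5 <- cfg$anchor5_start:(cfg$anchor5_start + cfg$anchor_length - 1L)
  a3 <- cfg$anchor3_start:(cfg$anchor3_start + cfg$anchor_length - 1L)
  mutable <- setdiff(seq_len(cfg$ref_length), c(a5, a3))

  # cultured pool: each reference at cultured_divergence from the master
  iso_id <- sprintf("ISO%03d", seq_len(cfg$n_cultured_refs))
  iso_seq <- vapply(iso_id, function(i) {
    paste(.mutate(master, cfg$cultured_divergence, mutable), collapse = "")
  }, character(1))
  iso_rumen <- stats::runif(cfg$n_cultured_refs) < cfg$rumen_fraction_cultured

  # community taxa: near / mid taxa from distinct cultured parents, novel
  # lineages straight from the master
  n_novel <- cfg$n_novel_lineages
  n_other <- cfg$n_taxa - n_novel
  n_mid <- round(cfg$mid_fraction * n_other)
  n_near <- n_other - n_mid
  kind <- c(rep("near", n_near), rep("mid", n_mid), rep("novel", n_novel))
  parents <- c(sample(cfg$n_cultured_refs, n_other), rep(NA_integer_, n_novel))
  taxon_id <- sprintf("TAX%03d", seq_len(cfg$n_taxa))
  taxon_seq <- character(cfg$n_taxa)
  for (t in seq_len(cfg$n_taxa)) {
    taxon_seq[t] <- switch(
      kind[t],
      near = paste(.mutate(strsplit(iso_seq[parents[t]], "")[[1]],
                           cfg$near_divergence, mutable), collapse = ""),
      mid = paste(.mutate(strsplit(iso_seq[parents[t]], "")[[1]],
                          cfg$mid_divergence, mutable), collapse = ""),
      novel = paste(.mutate(master, cfg$novel_divergence, mutable),
                    collapse = "")
    )
  }
  # realized nearest-cultured divergence, by direct comparison to the pool
  div_to_refs <- t(vapply(taxon_seq, function(s) {
    vapply(iso_seq, .hamming_frac, numeric(1), a = s)
  }, numeric(cfg$n_cultured_refs)))
  nearest_ref <- apply(div_to_refs, 1, which.min)
  true_div <- div_to_refs[cbind(seq_len(cfg$n_taxa), nearest_ref)]

  # phylum labels with rumen-like frequencies
  phyla <- sample(c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                    "Spirochaetes"),
                  cfg$n_taxa, replace = TRUE,
                  prob = c(0.5, 0.35, 0.1, 0.05))

  # presence design: core taxa in every survey, the rest in fewer surveys
  # than the core rule requires
  core_min <- ceiling(5 / 7 * cfg$n_datasets)
  n_core <- round(cfg$core_fraction * cfg$n_taxa)
  is_core <- seq_len(cfg$n_taxa) %in% sample(cfg$n_taxa, n_core)
  present <- matrix(FALSE, cfg$n_taxa, cfg$n_datasets)
  ds_id <- sprintf("survey%d", seq_len(cfg$n_datasets))
  colnames(present) <- ds_id
  for (t in seq_len(cfg$n_taxa)) {
    if (is_core[t]) {
      present[t, ] <- TRUE
    } else {
      k <- sample(seq_len(max(1L, core_min - 1L)), 1)
      present[t, sample(cfg$n_datasets, k)] <- TRUE
    }
  }

  # log-normal abundances, means shared across surveys
  base <- stats::rnorm(cfg$n_taxa, 0, cfg$abundance_sigma_between)
  rel <- matrix(0, cfg$n_taxa, cfg$n_datasets,
                dimnames = list(taxon_id, ds_id))
  for (d in seq_len(cfg$n_datasets)) {
    w <- exp(base + stats::rnorm(cfg$n_taxa, 0, cfg$abundance_sigma_within))
    w[!present[, d]] <- 0
    rel[, d] <- w / sum(w)
  }

  # per-survey amplicon windows, all containing the anchor span
  win_start <- sample(5:(cfg$anchor5_start - 5), cfg$n_datasets,
                      replace = TRUE)
  win_end <- sample((max(a3) + 10):min(cfg$ref_length, max(a3) + 60),
                    cfg$n_datasets, replace = TRUE)
  windows <- data.frame(dataset_id = ds_id, start = win_start, end = win_end)

  datasets <- vector("list", cfg$n_datasets)
  names(datasets) <- ds_id
  truth_reads <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    win_seq <- substr(taxon_seq, win_start[d], win_end[d])
    n_reads <- cfg$reads_per_dataset
    n_chim <- stats::rbinom(1, n_reads, cfg$chimera_fraction)
    n_norm <- n_reads - n_chim
    p <- rel[, d]
    src <- sample(cfg$n_taxa, n_norm, replace = TRUE, prob = p)
    seqs <- win_seq[src]
    taxon_of <- taxon_id[src]
    pa <- pb <- rep(NA_character_, n_norm)

    if (n_chim > 0) {
      ca <- sample(cfg$n_taxa, n_chim, replace = TRUE, prob = p)
      cb <- vapply(ca, function(a) {
        .resample(setdiff(which(p > 0), a), 1)
      }, integer(1))
      frac <- stats::runif(n_chim, 0.25, 0.75)
      wlen <- win_end[d] - win_start[d] + 1L
      split_at <- pmax(1L, pmin(wlen - 1L, round(frac * wlen)))
      chim_seq <- vapply(seq_len(n_chim), function(j) {
        paste0(substr(win_seq[ca[j]], 1, split_at[j]),
               substr(win_seq[cb[j]], split_at[j] + 1L, wlen))
      }, character(1))
      seqs <- c(seqs, chim_seq)
      taxon_of <- c(taxon_of, rep(NA_character_, n_chim))
      pa <- c(pa, taxon_id[ca])
      pb <- c(pb, taxon_id[cb])
    }
    is_chim <- c(rep(FALSE, n_norm), rep(TRUE, n_chim))

    if (cfg$per_base_error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        paste(.mutate(strsplit(s, "")[[1]], cfg$per_base_error_rate,
                      seq_len(nchar(s))), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    flip <- stats::runif(n_reads) < cfg$revcomp_fraction
    seqs[flip] <- revcomp(seqs[flip])

    ord <- sample(n_reads)
    rid <- sprintf("%s_r%05d", ds_id[d], seq_len(n_reads))
    datasets[[d]] <- seq_records(id = rid, dataset_id = ds_id[d],
                                 residues = seqs[ord])
    truth_reads[[d]] <- data.frame(
      read_id = rid, dataset_id = ds_id[d],
      taxon = taxon_of[ord], is_chimera = is_chim[ord],
      parent_a = pa[ord], parent_b = pb[ord],
      was_revcomped = flip[ord], stringsAsFactors = FALSE
    )
  }

  cultured <- seq_records(id = iso_id, dataset_id = "cultured",
                          residues = iso_seq, is_cultured = TRUE,
                          is_rumen_origin = iso_rumen)
  taxonomy <- data.frame(
    taxon_id = taxon_id,
    phylum = phyla,
    nearest_cultured_isolate = iso_id[nearest_ref],
    similarity_to_nearest_cultured = 100 * (1 - true_div),
    nearest_isolate_rumen = iso_rumen[nearest_ref],
    stringsAsFactors = FALSE
  )
  true_mean_percent <- rowMeans(100 * rel)
  truth_taxa <- data.frame(
    taxon_id = taxon_id,
    lineage = kind,
    is_core = is_core,
    # labels under the configured thresholds, recomputable from the
    # generator's own parameters: novel = realized divergence clearly
    # outside the cultured-pool radius; abundant = scaled true abundance
    # above the 0.25 cutoff
    is_novel = true_div > 2 * cfg$cultured_divergence,
    is_abundant = true_mean_percent / max(true_mean_percent) > 0.25,
    true_nearest_divergence = true_div,
    n_datasets_present = rowSums(present),
    true_mean_percent = true_mean_percent,
    stringsAsFactors = FALSE
  )
  truth <- list(reads = do.call(rbind, truth_reads), taxa = truth_taxa)
  attr(truth, "rel_abundance") <- rel

  inter_len <- cfg$anchor3_start - (cfg$anchor5_start + cfg$anchor_length)
  trim <- trim_spec(
    anchor5 = paste(master[a5], collapse = ""),
    anchor3 = paste(master[a3], collapse = ""),
    max_mismatches = 2,
    min_length = max(1L, floor(0.5 * inter_len))
  )
  structure(list(datasets = datasets, cultured = cultured,
                 taxonomy = taxonomy, truth = truth,
                 reference = paste(master, collapse = ""),
                 trim = trim, windows = windows, config = cfg),
            class = "rumen_simulation")
}
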