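# Taxonomic roll-ups: counts of cultured genera/isolates and survey OTUs
# per phylum with whole-percent shares and a totals row, and per-flag
# (core/abundant/novel) phylum breakdowns with prevalence strata.

#' Phylum summary table with percent columns and totals
#'
#' For every numeric column of `counts_df`, appends a column of whole
#' percents (`<name>_pct`, rounded half-up; the share of the column total)
#' and a final `Total` row equal to the column sums.
#'
#' @param counts_df Data frame with a `phylum` column and one or more
#'   numeric count columns.
#' @return Data frame with interleaved count and percent columns plus a
#'   totals row.
#' @export
phylum_summary <- function(counts_df) {
  stopifnot("phylum" %in% names(counts_df))
  num_cols <- names(counts_df)[vapply(counts_df, is.numeric, logical(1))]
  out <- data.frame(phylum = c(counts_df$phylum, "Total"),
                    stringsAsFactors = FALSE)
  for (cn in num_cols) {
    v <- counts_df[[cn]]
    tot <- sum(v)
    pct <- if (tot > 0) round_half_up(100 * v / tot) else rep(0, length(v))
    out[[cn]] <- c(v, tot)
    out[[paste0(cn, "_pct")]] <- c(pct, if (tot > 0) 100 else 0)
  }
  out
}

#' Summarise a set of OTUs by phylum
#'
#' @param otu_ids Character vector of OTU ids.
#' @param taxonomy Data frame with columns `otu_id` and `phylum`; OTUs
#'   missing from it are counted as `"unclassified"`.
#' @param column_name Name for the count column (default `"n_otus"`).
#' @return A [phylum_summary] table.
#' @export
summarize_by_phylum <- function(otu_ids, taxonomy, column_name = "n_otus") {
  phyla <- taxonomy$phylum[match(otu_ids, taxonomy$otu_id)]
  phyla[is.na(phyla) | !nzchar(phyla)] <- "unclassified"
  tab <- table(phyla)
  df <- data.frame(phylum = names(tab), n = as.integer(tab),
                   stringsAsFactors = FALSE)
  names(df)[2] <- column_name
  phylum_summary(df)
}

#' Per-flag phylum breakdown and prevalence strata
#'
#' For each of the core/abundant/novel flags, counts flagged OTUs per phylum
#' with half-up whole percents, and stratifies the flagged set by the exact
#' number of surveys of occurrence.
#'
#' @param metrics Classified [otu_metrics] (flags set by [classify_otus]).
#' @param taxonomy Data frame with `otu_id` and `phylum`.
#' @param n_datasets Number of surveys D (to convert prevalence fractions
#'   back to dataset counts).
#' @return List with `by_flag` (named list of phylum/count/percent data
#'   frames, possibly empty) and `prevalence_strata` (flag,
#'   n_datasets_present, n_otus).
#' @export
summarize_flags <- function(metrics, taxonomy, n_datasets) {
  if (anyNA(metrics$is_core)) stop("run classify_otus() first")
  flags <- c(core = "is_core", abundant = "is_abundant", novel = "is_novel")
  by_flag <- list()
  strata <- list()
  for (fn in names(flags)) {
    sel <- metrics[[flags[[fn]]]]
    ids <- metrics$otu_id[sel]
    if (length(ids) == 0L) {
      by_flag[[fn]] <- data.frame(phylum = character(0), n = integer(0),
                                  percent = numeric(0))
      next
    }
    phyla <- taxonomy$phylum[match(ids, taxonomy$otu_id)]
    phyla[is.na(phyla) | !nzchar(phyla)] <- "unclassified"
    tab <- sort(table(phyla), decreasing = TRUE)
    by_flag[[fn]] <- data.frame(
      phylum = names(tab),
      n = as.integer(tab),
      percent = round_half_up(100 * as.integer(tab) / length(ids)),
      stringsAsFactors = FALSE
    )
    k <- round(metrics$prevalence[sel] * n_datasets)
    ktab <- table(factor(k, levels = 0:n_datasets))
    strata[[fn]] <- data.frame(flag = fn,
                               n_datasets_present = as.integer(names(ktab)),
                               n_otus = as.integer(ktab),
                               stringsAsFactors = FALSE)
  }
  list(by_flag = by_flag,
       prevalence_strata = do.call(rbind, c(strata,
                                            make.row.names = FALSE)))
}

#' Load a phylum-counts fixture table
#'
#' Reads a tab-separated table of per-phylum counts (first column `phylum`,
#' remaining columns integer counts; `#` lines are comments), such as the
#' bundled summary of cultured rumen bacteria and survey OTUs per phylum in
#' `system.file("extdata", "rumen_phylum_counts.tsv", package = "rumencult")`.
#'
#' @param path Path to the TSV file.
#' @return Data frame suitable for [phylum_summary].
#' @export
read_phylum_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "phylum")
  for (j in 2:ncol(df)) df[[j]] <- as.integer(df[[j]])
  df
}

#' Format a phylum summary as aligned text lines
#'
#' @param x A [phylum_summary] table.
#' @return Character vector of fixed-width lines (deterministic: identical
#'   inputs give byte-identical output).
#' @export
format_phylum_summary <- function(x) {
  cols <- lapply(names(x), function(cn) {
    format(c(cn, as.character(x[[cn]])), justify = "right")
  })
  do.call(paste, cols)
}
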