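# Per-dataset cleaning: orientation screening by k-mer voting against a
# reference 16S, derivation of conserved 5'/3' anchor motifs from a profile
# alignment of OTU representatives, trimming of raw reads to the homologous
# region between the anchors, and a check that the trimmed window covers a
# required reference interval (the V1/V2 span shared by all retained
# surveys).

#' Trim specification
#'
#' Anchor motifs flanking the homologous region plus matching tolerances.
#'
#' @param anchor5,anchor3 Conserved DNA motifs at the 5' and 3' ends of the
#'   homologous region.
#' @param max_mismatches Maximum Hamming mismatches allowed when locating an
#'   anchor in a read (no indels; anchors are short conserved motifs).
#' @param min_length Dataset-specific minimum trimmed length; shorter reads
#'   are discarded.
#' @return A list of class `trim_spec`.
#' @export
trim_spec <- function(anchor5, anchor3, max_mismatches = 2, min_length = 1) {
  stopifnot(nzchar(anchor5), nzchar(anchor3),
            max_mismatches >= 0, min_length >= 1)
  structure(list(anchor5 = toupper(anchor5), anchor3 = toupper(anchor3),
                 max_mismatches = as.integer(max_mismatches),
                 min_length = as.integer(min_length)),
            class = "trim_spec")
}

#' Orient reads against a reference 16S sequence
#'
#' Re-implements the reverse-complementarity screen as k-mer orientation
#' voting: each read is kept in whichever orientation shares more distinct
#' k-mers with the reference.  Reads sharing no k-mer in either orientation
#' (or tying) are flagged unoriented and dropped.
#'
#' @param reads A [seq_records] data frame.
#' @param reference_16S A single reference DNA string.
#' @param k K-mer size for the vote (default 12; must be at least 5 and no
#'   longer than the reference).
#' @return The oriented records; attributes `n_flipped` and `n_dropped`
#'   count reverse-complemented and discarded reads.
#' @export
orient_reads <- function(reads, reference_16S, k = 12) {
  reads <- .as_records(reads)
  reference_16S <- toupper(reference_16S)
  if (k < 5) stop("k must be >= 5")
  if (k > nchar(reference_16S)) {
    stop("k (", k, ") is longer than the reference (",
         nchar(reference_16S), " nt)")
  }
  ref_kmers <- .kmer_set(reference_16S, k)

  uniq <- unique(reads$residues)
  fwd <- vapply(uniq, function(s) sum(.kmer_set(s, k) %in% ref_kmers),
                integer(1), USE.NAMES = FALSE)
  rc_seq <- revcomp(uniq)
  rev <- vapply(rc_seq, function(s) sum(.kmer_set(s, k) %in% ref_kmers),
                integer(1), USE.NAMES = FALSE)
  action <- ifelse(fwd == 0L & rev == 0L, "drop",
                   ifelse(rev > fwd, "flip",
                          ifelse(fwd > rev, "keep", "drop")))
  i <- match(reads$residues, uniq)
  act <- action[i]
  out <- reads[act != "drop", , drop = FALSE]
  flip <- act[act != "drop"] == "flip"
  out$residues[flip] <- rc_seq[i[act != "drop"][flip]]
  n_flipped <- sum(flip)
  n_dropped <- sum(act == "drop")
  message(sprintf("[orient] %s: %d reads, %d reverse-complemented, %d dropped",
                  reads$dataset_id[1] %||% "?", nrow(reads), n_flipped,
                  n_dropped))
  attr(out, "n_flipped") <- n_flipped
  attr(out, "n_dropped") <- n_dropped
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Derive conserved anchor motifs from a profile alignment
#'
#' Scans the columns of an alignment of OTU representatives for conserved
#' runs: the 5' anchor is the consensus of the first `anchor_length` columns
#' of the first run of at least `anchor_length` consecutive columns whose
#' modal residue frequency reaches `conservation_threshold`; the 3' anchor is
#' taken symmetrically from the last such run.
#'
#' @param alignment Character vector of equal-length aligned sequences (gaps
#'   as `-`).
#' @param conservation_threshold Minimum modal-residue column frequency, in
#'   (0.5, 1].
#' @param anchor_length Anchor length in columns (default 12).
#' @param max_mismatches,min_length Passed through to the returned
#'   [trim_spec].
#' @return A [trim_spec] whose anchors are column-consensus motifs.
#' @export
derive_anchors <- function(alignment, conservation_threshold,
                           anchor_length = 12, max_mismatches = 2,
                           min_length = 1) {
  stopifnot(conservation_threshold > 0.5, conservation_threshold <= 1)
  mat <- .char_matrix(alignment)
  modes <- .column_modes(mat)
  freq <- as.numeric(modes["freq", ])
  residue <- modes["residue", ]
  ok <- freq >= conservation_threshold & !residue %in% c("-", ".")
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  good <- which(runs$values & runs$lengths >= anchor_length)
  if (length(good) == 0L) {
    stop("no conserved run of >= ", anchor_length, " columns at threshold ",
         conservation_threshold, "; supply anchors manually")
  }
  r5 <- good[1]
  r3 <- good[length(good)]
  a5_cols <- starts[r5]:(starts[r5] + anchor_length - 1L)
  a3_cols <- (ends[r3] - anchor_length + 1L):ends[r3]
  trim_spec(anchor5 = paste(residue[a5_cols], collapse = ""),
            anchor3 = paste(residue[a3_cols], collapse = ""),
            max_mismatches = max_mismatches, min_length = min_length)
}

#' Trim reads to the region between the conserved anchors
#'
#' Each kept read is the substring strictly between (and excluding) the best
#' 5' and 3' anchor matches, located by a sliding Hamming scan allowing at
#' most `max_mismatches` mismatches.  Ties among equally good matches are
#' resolved leftmost for the 5' anchor and rightmost for the 3' anchor,
#' maximising the retained homologous span.  Reads lacking either anchor,
#' with the anchors out of order, or trimming shorter than `min_length` are
#' excluded.
#'
#' @param reads Oriented [seq_records].
#' @param spec A [trim_spec].
#' @return List with `kept` (trimmed records) and `report` (a one-row data
#'   frame: input/kept counts, exclusion reasons, discard fraction and mean
#'   lengths before/after).
#' @export
trim_to_anchors <- function(reads, spec) {
  reads <- .as_records(reads)
  stopifnot(inherits(spec, "trim_spec"))
  uniq <- unique(reads$residues)
  res <- lapply(uniq, .trim_one, spec = spec)
  i <- match(reads$residues, uniq)
  status <- vapply(res, `[[`, character(1), "status")[i]
  trimmed <- vapply(res, `[[`, character(1), "trimmed")[i]
  too_short <- status == "ok" & nchar(trimmed) < spec$min_length
  status[too_short] <- "too_short"

  keep <- status == "ok"
  kept <- reads[keep, , drop = FALSE]
  kept$residues <- trimmed[keep]
  report <- data.frame(
    dataset_id = reads$dataset_id[1] %||% NA_character_,
    n_input = nrow(reads),
    n_kept = sum(keep),
    n_missing_anchor = sum(status == "missing_anchor"),
    n_misordered = sum(status == "misordered"),
    n_too_short = sum(status == "too_short"),
    fraction_discarded = if (nrow(reads)) 1 - sum(keep) / nrow(reads) else 0,
    mean_length_before = mean(nchar(reads$residues)),
    mean_length_after = if (any(keep)) mean(nchar(kept$residues)) else NA_real_,
    stringsAsFactors = FALSE
  )
  list(kept = kept, report = report)
}

.trim_one <- function(seq, spec) {
  m5 <- .mismatch_scan(seq, spec$anchor5)
  m3 <- .mismatch_scan(seq, spec$anchor3)
  if (length(m5) == 0L || length(m3) == 0L ||
      min(m5) > spec$max_mismatches || min(m3) > spec$max_mismatches) {
    return(list(status = "missing_anchor", trimmed = ""))
  }
  a5_start <- which(m5 == min(m5))[1]                    # leftmost best
  best3 <- which(m3 == min(m3))
  a3_start <- best3[length(best3)]                       # rightmost best
  a5_end <- a5_start + nchar(spec$anchor5) - 1L
  if (a5_end >= a3_start) {
    return(list(status = "misordered", trimmed = ""))
  }
  list(status = "ok", trimmed = substr(seq, a5_end + 1L, a3_start - 1L))
}

#' Check that a dataset's trimmed window covers a required reference interval
#'
#' Maps the column consensus of the trimmed reads onto the reference by the
#' best ungapped offset and reports the covered interval (1-based, inclusive)
#' and whether it contains the required interval (the minimum shared V1/V2
#' span).  A consensus matching the reference at under half its positions is
#' considered unmappable.
#'
#' @param trimmed_reads [seq_records] after trimming (consensus is computed
#'   over reads of the modal length).
#' @param reference_16S Reference DNA string defining the coordinate system.
#' @param required_interval Integer vector `c(start, end)`, 1-based inclusive.
#' @return A one-row data frame: `dataset_id`, `covered_start`, `covered_end`,
#'   `overlaps_required_region`.
#' @export
check_region_overlap <- function(trimmed_reads, reference_16S,
                                 required_interval) {
  trimmed_reads <- .as_records(trimmed_reads)
  reference_16S <- toupper(reference_16S)
  stopifnot(length(required_interval) == 2L,
            required_interval[1] <= required_interval[2],
            required_interval[2] <= nchar(reference_16S))
  lens <- nchar(trimmed_reads$residues)
  modal_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  sub <- trimmed_reads$residues[lens == modal_len]
  cons <- paste(.column_modes(.char_matrix(sub))["residue", ], collapse = "")

  mism <- .mismatch_scan(reference_16S, cons)
  ds <- trimmed_reads$dataset_id[1] %||% NA_character_
  if (length(mism) == 0L) {
    warning("consensus longer than reference; cannot map dataset ", ds)
    return(data.frame(dataset_id = ds, covered_start = NA_integer_,
                      covered_end = NA_integer_,
                      overlaps_required_region = FALSE))
  }
  best <- which.min(mism)
  if (mism[best] > nchar(cons) / 2) {
    warning("consensus for dataset ", ds, " is unmappable to the reference")
    return(data.frame(dataset_id = ds, covered_start = NA_integer_,
                      covered_end = NA_integer_,
                      overlaps_required_region = FALSE))
  }
  covered <- c(best, best + nchar(cons) - 1L)
  data.frame(
    dataset_id = ds,
    covered_start = covered[1],
    covered_end = covered[2],
    overlaps_required_region = covered[1] <= required_interval[1] &&
      covered[2] >= required_interval[2],
    stringsAsFactors = FALSE
  )
}
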