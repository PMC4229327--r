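#' Construct a set of sequence records
#'
#' The basic container used throughout the pipeline: one row per oriented DNA
#' read or reference sequence, with its dataset provenance.  The dataset id
#' `"cultured"` is reserved for the cultured-isolate reference pool.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param dataset_id Single string naming the survey (or `"cultured"`).
#' @param residues Character vector of IUPAC DNA strings (upper-cased on
#'   construction).
#' @param description Optional free-text descriptions (FASTA header remainder).
#' @param is_cultured Logical; `TRUE` for isolate-pool sequences.
#' @param is_rumen_origin Logical; for cultured sequences, whether the isolate
#'   is annotated as of rumen origin.  `NA` for survey reads.
#' @return A `data.frame` with class `seq_records` and columns `id`,
#'   `dataset_id`, `residues`, `description`, `is_cultured`, `is_rumen_origin`.
#' @export
seq_records <- function(id, dataset_id, residues, description = "",
                        is_cultured = FALSE, is_rumen_origin = NA) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) {
    stop("`id` and `residues` must have the same length")
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s) within dataset '", dataset_id, "': ",
         paste(dup, collapse = ", "))
  }
  empty <- !nzchar(residues)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(id[empty], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", .iupac_chars), residues)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(id[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  out <- data.frame(
    id = id,
    dataset_id = rep_len(as.character(dataset_id), length(id)),
    residues = residues,
    description = rep_len(as.character(description), length(id)),
    is_cultured = rep_len(as.logical(is_cultured), length(id)),
    is_rumen_origin = rep_len(as.logical(is_rumen_origin), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_records", "data.frame")
  out
}

# IUPAC nucleotide codes accepted in `residues` (gap characters excluded;
# alignments are handled as plain character vectors, not records)
.iupac_chars <- "ACGTUNRYSWKMBDHV"

.as_records <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("id", "dataset_id", "residues") %in% names(x)))
  x
}
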