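# Readers and writers for the external representations the pipeline touches:
# FASTA (reads, references, cluster representatives), newick (trees) and
# tab-separated tables (counts, metrics, taxonomy).  All tables are written
# with a header line; "#" prefixes comments.

#' Read a FASTA file into sequence records
#'
#' The header token before the first whitespace becomes the record id; the
#' remainder is retained as a free-text description.  Residues are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param dataset_id Dataset label attached to every record (`"cultured"` is
#'   reserved for the isolate pool).
#' @param cultured_flag Logical; mark records as cultured-isolate sequences.
#' @param rumen_origin Logical; for cultured pools, whether isolates are of
#'   rumen origin (`NA` when unknown or not applicable).
#' @return A [seq_records] data frame, in file order.
#' @export
read_fasta <- function(path, dataset_id, cultured_flag = FALSE,
                       rumen_origin = NA) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("empty sequence in ", path, " for record(s): ",
         paste(ids[widths == 0L], collapse = ", "))
  }
  seq_records(id = ids, dataset_id = dataset_id,
              residues = as.character(set), description = desc,
              is_cultured = cultured_flag, is_rumen_origin = rumen_origin)
}

#' Write sequence records to FASTA
#'
#' @param records A [seq_records] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- .as_records(records)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a single newick tree
#'
#' Missing branch lengths are set to 1.0 with a warning: path-length based
#' distances are meaningless otherwise, and an explicit default beats a
#' silent zero.
#'
#' @param path Path to a newick file containing one tree.
#' @return An [ape::ape-package] `phylo` tree with unique tip labels and
#'   non-negative branch lengths.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .check_newick_syntax(txt, path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("unparseable newick in ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("newick tree in ", path,
            " has no branch lengths; all set to 1.0")
    tree$edge.length <- rep(1.0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("newick tree in ", path,
            " has missing branch lengths; those set to 1.0")
    tree$edge.length[is.na(tree$edge.length)] <- 1.0
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s) in ", path)
  }
  tree
}

# Cheap syntactic screen so that an unbalanced tree is reported with the
# character offset of the problem (ape's own message has none).
.check_newick_syntax <- function(txt, path) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unparseable newick in ", path,
             ": unmatched ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("unparseable newick in ", path, ": ", depth,
         " unclosed '(' by character offset ", length(chars))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("unparseable newick in ", path, ": missing ';' terminator ",
         "(character offset ", nchar(txt), ")")
  }
  invisible(TRUE)
}

#' Write a tree as newick
#'
#' Branch lengths are written with 10 significant digits so that
#' write-then-read round-trips preserve them to well below 1e-9.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read an OTU-by-dataset count table
#'
#' Tab-separated with a header line; first column holds OTU ids; `#` lines
#' are comments.  Counts must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with OTU ids as row names and dataset ids as
#'   column names.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("counts table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("counts table has no columns: ", path)
  otu_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop("invalid count '", vals[[j]][bad[1]], "' at row '",
           otu_ids[bad[1]], "', column '", names(vals)[j], "' in ", path)
    }
    vals[[j]] <- as.integer(v)
  }
  m <- as.matrix(vals)
  rownames(m) <- otu_ids
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU-by-dataset count table
#'
#' @param counts Integer matrix (OTU x dataset) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)[1, ]
    stop("invalid count at row '", rownames(counts)[bad[1]],
         "', column '", colnames(counts)[bad[2]], "'")
  }
  if (nrow(counts) == 0L) {
    writeLines(paste(c("otu_id", colnames(counts)), collapse = "\t"), path)
    return(invisible(path))
  }
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Write / read a metrics (or any rectangular) table as TSV
#'
#' Numeric columns are written with full precision (at least 6 significant
#' digits), so write-then-read round-trips are lossless for practical
#' purposes.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(x, path) {
  .write_tsv(as.data.frame(x), path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE,
                                          scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
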