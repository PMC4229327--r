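# Small shared helpers: reverse complement, k-mer sets, sliding Hamming
# scans, column consensus, half-up rounding.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Distinct k-mers of a single sequence.
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

# Mismatch count of `anchor` against every offset of `seq` (Hamming, no
# indels).  Returns integer(0) when seq is shorter than the anchor.
.mismatch_scan <- function(seq, anchor) {
  s <- charToRaw(seq)
  a <- charToRaw(anchor)
  L <- length(a)
  n <- length(s)
  if (n < L) return(integer(0))
  offs <- 0:(n - L)
  idx <- outer(seq_len(L), offs, "+")
  colSums(matrix(s[idx], nrow = L) != a)
}

# Character matrix (rows = sequences) from equal-length strings.
.char_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must all have the same length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# Per-column modal residue and its frequency; gaps ('-', '.') never win
# unless a column is all-gap.
.column_modes <- function(mat) {
  apply(mat, 2, function(col) {
    tab <- table(col)
    tab_res <- tab[!names(tab) %in% c("-", ".")]
    if (length(tab_res) == 0L) tab_res <- tab
    i <- which.max(tab_res)
    c(residue = names(tab_res)[i],
      freq = as.numeric(tab_res[i]) / length(col))
  })
}

#' Round half away from zero
#'
#' Plain "school" rounding (0.5 rounds up), as used for the whole-percent
#' columns of the summary tables; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
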