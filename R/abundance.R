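# Between-survey normalisation of OTU counts by the trimmed mean of
# M-values (TMM), average percentage abundance across surveys, and
# prevalence.

#' TMM normalisation factors for an OTU count matrix
#'
#' Computes trimmed-mean-of-M-values scaling factors across surveys, via
#' edgeR's implementation of the published method: the reference survey is
#' the one whose upper-quartile relative abundance is closest to the mean of
#' upper quartiles; per survey, log2 abundance ratios (M) against the
#' reference over shared nonzero OTUs are doubly trimmed (default 30% on M,
#' 5% on mean log abundance A) and combined by a precision-weighted mean;
#' factors are rescaled to geometric mean 1.  A survey sharing fewer than 5
#' nonzero OTUs with the reference gets factor 1 with a warning.
#'
#' @param counts Integer matrix, OTUs x surveys, each column sum positive,
#'   at least 2 surveys.
#' @param trim_M Two-sided trim fraction on M values (default 0.30).
#' @param trim_A Two-sided trim fraction on A values (default 0.05).
#' @return A list of class `tmm_factors`: `reference_dataset`, `factors`
#'   (named, geometric mean 1), `effective_library_size` (column sum times
#'   factor).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 surveys for TMM")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("all-zero survey column(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  # reference pick: upper-quartile relative abundance closest to the mean
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  fac <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                                logratioTrim = trim_M, sumTrim = trim_A,
                                doWeighting = TRUE)
  shared <- colSums(counts > 0 & counts[, ref] > 0)
  low <- shared < 5 & seq_len(ncol(counts)) != ref
  if (any(low)) {
    warning("survey(s) sharing < 5 OTUs with the reference get factor 1: ",
            paste(colnames(counts)[low], collapse = ", "))
    raw <- fac / fac[ref]        # undo the geometric-mean rescale
    raw[low] <- 1
    fac <- raw / exp(mean(log(raw)))
  }
  names(fac) <- colnames(counts)
  structure(list(reference_dataset = colnames(counts)[ref],
                 factors = fac,
                 effective_library_size = lib * fac),
            class = "tmm_factors")
}

#' Average percentage abundance and prevalence per OTU
#'
#' Per survey, an OTU's percentage abundance is 100 x count / effective
#' library size; the reported mean is taken over all surveys, counting
#' absence as zero.  Prevalence is the fraction of surveys in which the OTU
#' was observed at all (independent of normalisation).
#'
#' @param counts Integer matrix, OTUs x surveys.
#' @param factors A [tmm_factors] object covering all surveys.
#' @return Data frame of class `abundance_summary`: `otu_id`,
#'   `mean_percent_abundance`, `prevalence`; the full per-survey percentage
#'   matrix is attached as attribute `percent`.
#' @export
summarize_abundance <- function(counts, factors) {
  counts <- as.matrix(counts)
  stopifnot(inherits(factors, "tmm_factors"))
  eff <- factors$effective_library_size[colnames(counts)]
  if (anyNA(eff)) stop("factors missing for some surveys")
  percent <- 100 * sweep(counts, 2, eff, "/")
  out <- data.frame(
    otu_id = rownames(counts),
    mean_percent_abundance = rowMeans(percent),
    prevalence = rowMeans(counts > 0),
    stringsAsFactors = FALSE
  )
  attr(out, "percent") <- percent
  class(out) <- c("abundance_summary", "data.frame")
  out
}
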