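# Orientation voting, anchor derivation, anchor trimming and region
# coverage.

test_that("orientation voting keeps, flips and drops reads correctly", {
  set.seed(101)
  ref <- random_dna(500)
  fwd <- substr(ref, 101, 300)
  rc <- revcomp(fwd)
  junk <- random_dna(200)
  # oracle: exhaustive k-mer intersection in both orientations
  kmers <- function(s, k) unique(substring(s, 1:(nchar(s) - k + 1),
                                           k:nchar(s)))
  expect_equal(length(intersect(kmers(junk, 12), kmers(ref, 12))) +
                 length(intersect(kmers(revcomp(junk), 12),
                                  kmers(ref, 12))), 0L)

  reads <- records_from(c(fwd, rc, junk))
  out <- suppressMessages(orient_reads(reads, ref, k = 12))
  expect_equal(nrow(out), 2L)
  expect_equal(out$residues, c(fwd, fwd))
  expect_equal(attr(out, "n_flipped"), 1L)
  expect_equal(attr(out, "n_dropped"), 1L)

  # idempotence: orienting oriented reads changes nothing
  out2 <- suppressMessages(orient_reads(out, ref, k = 12))
  expect_equal(out2$residues, out$residues)
  expect_equal(attr(out2, "n_flipped"), 0L)

  expect_error(orient_reads(reads, substr(ref, 1, 8), k = 12), "longer")
})

test_that("anchor derivation finds conserved runs and their consensus", {
  set.seed(102)
  base <- random_dna(80)
  aln <- rep(base, 10)
  spec <- derive_anchors(aln, conservation_threshold = 0.9)
  expect_equal(spec$anchor5, substr(base, 1, 12))
  expect_equal(spec$anchor3, substr(base, 69, 80))

  # 95%-conserved first 12 columns, hypervariable middle, conserved tail
  n <- 20
  head_cols <- substr(base, 1, 12)
  tail_cols <- substr(base, 61, 72)
  aln2 <- vapply(seq_len(n), function(i) {
    paste0(head_cols, random_dna(48), tail_cols)
  }, character(1))
  # plant one mismatch per head column in distinct sequences (19/20 = 95%)
  for (col in 1:12) {
    s <- strsplit(aln2[col], "")[[1]]
    s[col] <- setdiff(c("A", "C", "G", "T"), s[col])[1]
    aln2[col] <- paste(s, collapse = "")
  }
  spec2 <- derive_anchors(aln2, conservation_threshold = 0.9)
  # oracle: column-frequency scan for the modal residue
  mat <- do.call(rbind, strsplit(substr(aln2, 1, 12), ""))
  consensus <- apply(mat, 2, function(cc) names(which.max(table(cc))))
  expect_equal(spec2$anchor5, paste(consensus, collapse = ""))

  # all-different random sequences: no conserved run
  set.seed(103)
  aln3 <- vapply(1:20, function(i) random_dna(60), character(1))
  expect_error(derive_anchors(aln3, conservation_threshold = 0.95),
               "manually")
})

test_that("trimming keeps the inter-anchor region and excludes the rest", {
  set.seed(104)
  a5 <- random_dna(12)
  a3 <- random_dna(12)
  spec <- trim_spec(a5, a3, max_mismatches = 2, min_length = 50)
  mid <- random_dna(100)
  reads <- records_from(c(
    paste0(a5, mid, a3),                       # kept, trimmed to mid
    paste0(a5, random_dna(100)),               # missing anchor3
    paste0(random_dna(30), a3),                # missing anchor5
    paste0(a5, random_dna(10), a3)             # too short after trimming
  ))
  res <- trim_to_anchors(reads, spec)
  expect_equal(res$kept$id, "s001")
  expect_equal(res$kept$residues, mid)
  expect_equal(res$report$n_missing_anchor, 2)
  expect_equal(res$report$n_too_short, 1)
  expect_equal(res$report$fraction_discarded, 0.75)
})

test_that("anchor-less reads drive the reported discard fraction", {
  set.seed(105)
  a5 <- random_dna(12)
  a3 <- random_dna(12)
  spec <- trim_spec(a5, a3, min_length = 20)
  n <- 100
  n_bad <- 17
  seqs <- c(
    vapply(seq_len(n - n_bad), function(i) {
      paste0(a5, random_dna(80), a3)
    }, character(1)),
    vapply(seq_len(n_bad), function(i) random_dna(104), character(1))
  )
  res <- trim_to_anchors(records_from(seqs), spec)
  expect_equal(res$report$fraction_discarded, n_bad / n)
  # error-free anchored reads all pass and equal the planted region
  expect_equal(nrow(res$kept), n - n_bad)
  expect_true(all(nchar(res$kept$residues) == 80))
})

test_that("trimming already-trimmed reads excludes everything", {
  set.seed(106)
  a5 <- random_dna(12)
  a3 <- random_dna(12)
  spec <- trim_spec(a5, a3, min_length = 10)
  reads <- records_from(vapply(1:10, function(i) {
    paste0(a5, random_dna(60), a3)
  }, character(1)))
  once <- trim_to_anchors(reads, spec)
  expect_equal(nrow(once$kept), 10L)
  twice <- trim_to_anchors(once$kept, spec)
  expect_equal(nrow(twice$kept), 0L)
})

test_that("region coverage requires containment of the required interval", {
  set.seed(107)
  ref <- random_dna(850)
  required <- c(28, 338)
  mk <- function(from, to) {
    records_from(rep(substr(ref, from, to), 5), dataset_id = "dsR")
  }
  r1 <- check_region_overlap(mk(28, 514), ref, required)
  expect_equal(c(r1$covered_start, r1$covered_end), c(28, 514))
  expect_true(r1$overlaps_required_region)

  r2 <- check_region_overlap(mk(515, 806), ref, required)
  expect_false(r2$overlaps_required_region)

  # partial overlap is not containment
  r3 <- check_region_overlap(mk(100, 400), ref, required)
  expect_false(r3$overlaps_required_region)

  # unmappable consensus
  expect_warning(
    r4 <- check_region_overlap(records_from(rep(random_dna(300), 3)),
                               ref, required),
    "unmappable")
  expect_false(r4$overlaps_required_region)
})
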