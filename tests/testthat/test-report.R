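# Phylum roll-ups: the bundled cultured-vs-survey counts table, per-flag
# breakdowns, rounding and purity.

fixture_path <- system.file("extdata", "rumen_phylum_counts.tsv",
                            package = "rumencult")

test_that("cultured genera and isolates columns roll up correctly", {
  counts <- read_phylum_counts(fixture_path)
  tab <- phylum_summary(counts)
  tot <- tab[tab$phylum == "Total", ]

  # 88 cultured genera across nine phyla
  expect_equal(tot$cultured_genera, 88)
  expect_equal(sum(counts$cultured_genera > 0), 9L)

  # 146 isolates of rumen origin in the collections; Firmicutes,
  # Proteobacteria and Actinobacteria dominate at 90% of cultures
  expect_equal(tot$cultured_isolates, 146)
  dom <- counts$cultured_isolates[counts$phylum %in%
                                    c("Firmicutes", "Proteobacteria",
                                      "Actinobacteria")]
  expect_equal(round_half_up(100 * sum(dom) / tot$cultured_isolates), 90)

  # survey OTU totals and the dominant-phyla share
  expect_equal(tot$this_study_otus, 2405)
  bf <- counts$this_study_otus[counts$phylum %in%
                                 c("Bacteroidetes", "Firmicutes")]
  expect_equal(round_half_up(100 * sum(bf) / tot$this_study_otus), 90)
  expect_equal(tab$this_study_otus_pct[tab$phylum == "Bacteroidetes"], 38)
})

test_that("percent columns are recomputable and totals are column sums", {
  counts <- read_phylum_counts(fixture_path)
  tab <- phylum_summary(counts)
  body <- tab[tab$phylum != "Total", ]
  for (cn in c("cultured_genera", "cultured_isolates", "this_study_otus")) {
    tot <- sum(counts[[cn]])
    expect_equal(tab[[cn]][tab$phylum == "Total"], tot)
    exact <- 100 * body[[cn]] / tot
    expect_true(all(abs(body[[paste0(cn, "_pct")]] - exact) <= 0.5))
  }
})

test_that("flag breakdowns reproduce the printed category shares", {
  # 98 core OTUs: 57 Firmicutes (58%), 41 Bacteroidetes (42%)
  ids <- sprintf("c%03d", 1:98)
  tax <- data.frame(otu_id = ids,
                    phylum = c(rep("Firmicutes", 57),
                               rep("Bacteroidetes", 41)))
  metrics <- data.frame(otu_id = ids, prevalence = 5 / 7,
                        is_core = TRUE, is_abundant = FALSE,
                        is_novel = FALSE)
  fs <- summarize_flags(metrics, tax, n_datasets = 7)
  core <- fs$by_flag$core
  expect_equal(core$percent[core$phylum == "Firmicutes"], 58)
  expect_equal(core$percent[core$phylum == "Bacteroidetes"], 42)

  # 27 abundant OTUs: 13 Bacteroidetes (48%), 11 Firmicutes (41%),
  # 3 Proteobacteria (11%)
  ids2 <- sprintf("a%03d", 1:27)
  tax2 <- data.frame(otu_id = ids2,
                     phylum = c(rep("Bacteroidetes", 13),
                                rep("Firmicutes", 11),
                                rep("Proteobacteria", 3)))
  metrics2 <- data.frame(otu_id = ids2, prevalence = 3 / 7,
                         is_core = FALSE, is_abundant = TRUE,
                         is_novel = FALSE)
  fs2 <- summarize_flags(metrics2, tax2, n_datasets = 7)
  ab <- fs2$by_flag$abundant
  expect_equal(ab$percent[ab$phylum == "Bacteroidetes"], 48)
  expect_equal(ab$percent[ab$phylum == "Firmicutes"], 41)
  expect_equal(ab$percent[ab$phylum == "Proteobacteria"], 11)
})

test_that("prevalence strata count OTUs by surveys of occurrence", {
  ids <- sprintf("c%03d", 1:98)
  tax <- data.frame(otu_id = ids, phylum = "Firmicutes")
  metrics <- data.frame(otu_id = ids,
                        prevalence = c(rep(7 / 7, 2), rep(6 / 7, 27),
                                       rep(5 / 7, 69)),
                        is_core = TRUE, is_abundant = FALSE,
                        is_novel = FALSE)
  fs <- summarize_flags(metrics, tax, n_datasets = 7)
  st <- fs$prevalence_strata
  expect_equal(st$n_otus[st$flag == "core" & st$n_datasets_present == 7], 2)
  expect_equal(st$n_otus[st$flag == "core" & st$n_datasets_present == 6], 27)
  expect_equal(st$n_otus[st$flag == "core" & st$n_datasets_present == 5], 69)
})

test_that("degenerate inputs: one phylum, zero flagged OTUs", {
  tax <- data.frame(otu_id = sprintf("o%d", 1:10), phylum = "Firmicutes")
  tab <- summarize_by_phylum(sprintf("o%d", 1:10), tax)
  expect_equal(tab$n_otus_pct[tab$phylum == "Firmicutes"], 100)

  metrics0 <- data.frame(otu_id = character(0), prevalence = numeric(0),
                         is_core = logical(0), is_abundant = logical(0),
                         is_novel = logical(0))
  fs0 <- summarize_flags(metrics0, tax, n_datasets = 7)
  expect_equal(nrow(fs0$by_flag$core), 0L)

  # unknown OTUs are counted as unclassified
  tab2 <- summarize_by_phylum(c("o1", "zzz"), tax)
  expect_true("unclassified" %in% tab2$phylum)
})

test_that("report formatting is pure and deterministic", {
  counts <- read_phylum_counts(fixture_path)
  l1 <- format_phylum_summary(phylum_summary(counts))
  l2 <- format_phylum_summary(phylum_summary(counts))
  expect_identical(l1, l2)
  expect_equal(length(l1), nrow(counts) + 2L)  # header + rows + total
})
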