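test_that("transcriptome generator plants the configured structure", {
  cfg <- generator_config(n_transcripts = 100, intron_fraction = 0.1, seed = 7)
  txome <- generate_transcriptome(cfg)
  tx <- txome$transcripts
  expect_equal(nrow(tx), 100)
  expect_equal(sum(tx$has_intron), 10) # exactly round(0.1 * 100)
  # intron-carrying transcripts have exactly two exons in the GFF3
  path <- withr::local_tempfile(fileext = ".gff3")
  write_transcriptome_gff3(txome, path)
  back <- read_transcriptome_gff3(path)
  expect_equal(sum(back$has_intron), 10)
  expect_setequal(back$transcript_id, tx$transcript_id)
  # genome-of-origin and half-life attributes round-trip
  m <- match(tx$transcript_id, back$transcript_id)
  expect_equal(back$genome[m], tx$genome)
  expect_equal(back$half_life_min[m], tx$half_life_min)
  # mature sequence length matches annotation
  expect_equal(unname(Biostrings::width(txome$sequences)), tx$length)
})

test_that("intron_fraction = 0 yields no intronic transcripts", {
  txome <- generate_transcriptome(
    generator_config(n_transcripts = 40, intron_fraction = 0, seed = 2))
  expect_false(any(txome$transcripts$has_intron))
})

test_that("degenerate length range is rejected", {
  expect_error(generator_config(length_distribution = c(4000, 200, 2)),
               "degenerate")
})

test_that("generators are deterministic: same config, byte-identical GFF3 and SAM", {
  cfg <- generator_config(n_transcripts = 25, n_read_pairs = 2000, seed = 9)
  t1 <- generate_transcriptome(cfg)
  t2 <- generate_transcriptome(cfg)
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_transcriptome_gff3(t1, p1)
  write_transcriptome_gff3(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  r1 <- simulate_reads(t1, cfg, "eluate")
  r2 <- simulate_reads(t2, cfg, "eluate")
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(r1, t1, s1, mode = "genome")
  write_sam(r2, t2, s2, mode = "genome")
  expect_identical(readBin(s1, "raw", file.size(s1)),
                   readBin(s2, "raw", file.size(s2)))
})

test_that("every alignment lies within its transcript and split gaps match introns", {
  fx <- small_txome(seed = 5, n = 40, intron_fraction = 0.5,
                    n_read_pairs = 4000, retention_rate = 0.3,
                    nascent_truncation_fraction = 0.4)
  reads <- simulate_reads(fx$txome, fx$cfg, "eluate")
  tx <- fx$txome$transcripts

  # transcript-coordinate bounds
  len <- setNames(tx$length, tx$transcript_id)
  expect_true(all(reads$transcript$start >= 1))
  expect_true(all(reads$transcript$end <= len[reads$transcript$rname]))

  # genome-coordinate bounds
  tstart <- setNames(tx$tx_start, tx$transcript_id)
  tend <- setNames(tx$tx_end, tx$transcript_id)
  expect_true(all(reads$genome$pos >= tstart[reads$genome$transcript_id]))
  expect_true(all(reads$genome$end <= tend[reads$genome$transcript_id]))

  # split gaps coincide exactly with annotated introns
  gal <- as_galignments(reads, fx$txome, "genome")
  gaps <- unlist(GenomicAlignments::junctions(gal), use.names = FALSE)
  key <- paste(GenomicRanges::start(gaps), GenomicRanges::end(gaps))
  intr <- tx[tx$has_intron, ]
  expect_true(all(key %in% paste(intr$intron_start, intr$intron_end)))
  expect_gt(length(gaps), 0)
})

test_that("retention rate boundaries control split reads", {
  fx <- small_txome(seed = 11, n = 20, intron_fraction = 1,
                    n_read_pairs = 2000, retention_rate = 1)
  r <- simulate_reads(fx$txome, fx$cfg, "lysate")
  expect_false(any(grepl("N", r$genome$cigar)))

  cfg0 <- generator_config(n_transcripts = 20, intron_fraction = 1,
                           n_read_pairs = 2000, retention_rate = 0, seed = 11)
  tx0 <- generate_transcriptome(cfg0)
  r0 <- simulate_reads(tx0, cfg0, "lysate")
  # with retention 0, every junction-spanning read is split: contiguous reads
  # never cross an intron boundary
  tx <- tx0$transcripts
  spans <- mapply(function(id, a, b) {
    j <- tx$junction[match(id, tx$transcript_id)]
    !is.na(j) && a <= j && b > j
  }, r0$transcript$rname, r0$transcript$start, r0$transcript$end)
  has_gap <- grepl("N", r0$genome$cigar)
  expect_equal(unname(has_gap), unname(spans))
})

test_that("mitochondrial transcripts are depleted in the eluate", {
  cfg <- generator_config(n_transcripts = 40, mito_fraction = 0.5,
                          intron_fraction = 0, mito_depletion_factor = 0.01,
                          n_read_pairs = 20000, seed = 3)
  txome <- generate_transcriptome(cfg)
  mito_ids <- txome$transcripts$transcript_id[txome$transcripts$genome == "mito"]
  share <- function(r) {
    cnt <- count_read_pairs(r)
    sum(cnt[mito_ids]) / sum(cnt)
  }
  s_ly <- share(simulate_reads(txome, cfg, "lysate"))
  s_el <- share(simulate_reads(txome, cfg, "eluate"))
  expect_gt(s_ly, 0.2)
  expect_lt(s_el, s_ly / 10)
})

test_that("abundance model recovers enrichment coefficient signs by regression", {
  cfg <- generator_config(n_transcripts = 400, intron_fraction = 0,
                          mito_fraction = 0,
                          enrichment_coefficients = c(-0.6, 0.5),
                          n_read_pairs = 50000, seed = 21)
  txome <- generate_transcriptome(cfg)
  ly <- count_read_pairs(simulate_reads(txome, cfg, "lysate"),
                         txome$transcripts$transcript_id)
  el <- count_read_pairs(simulate_reads(txome, cfg, "eluate"),
                         txome$transcripts$transcript_id)
  keep <- ly > 0 & el > 0
  y <- log((el + 0.5) / (ly + 0.5))[keep]
  tx <- txome$transcripts[keep, ]
  fit <- lm(y ~ scale(log(tx$half_life_min)) + scale(log(tx$length)))
  expect_lt(coef(fit)[2], 0)
  expect_gt(coef(fit)[3], 0)
})

test_that("peptide simulator honours weights and replicate structure", {
  prots <- c(P1 = strrep("ACDEFGHILK", 8), P2 = strrep("MNPQRSTVWK", 8))
  w <- cbind(eluate = c(2, 0), flowthrough = c(1, 1))
  rownames(w) <- names(prots)
  spec <- stoichiometry_spec(prots, w, n_replicates = 3)
  pep <- simulate_peptides(spec, seed = 4)
  # weight 0 in a condition -> no rows for it there
  expect_equal(nrow(pep[pep$protein == "P2" & pep$condition == "eluate", ]), 0)
  expect_gt(nrow(pep[pep$protein == "P2" & pep$condition == "flowthrough", ]), 0)
  # each present (protein, condition) has exactly 3 replicate labels
  reps <- dplyr::summarise(
    dplyr::group_by(pep, protein, condition),
    n_rep = dplyr::n_distinct(replicate), .groups = "drop")
  expect_true(all(reps$n_rep == 3))
  expect_error(simulate_peptides(
    stoichiometry_spec(character(0) |> setNames(character(0)),
                       matrix(numeric(0), 0, 1,
                              dimnames = list(NULL, "eluate"))), 1),
    "empty")
})

test_that("cross-link simulator emits each planted link once with clipped windows", {
  prots <- tibble::tibble(protein = c("P1", "P2"), length = c(100L, 80L),
                          lysines = list(c(5L, 10L, 50L, 98L), c(5L, 40L)))
  planted <- tibble::tibble(
    protein_a = c("P1", "P1", "P1"),
    residue_a = c(10L, 98L, 5L),
    protein_b = c("P1", "P2", NA),
    residue_b = c(50L, 40L, NA))
  spec <- crosslink_topology_spec(prots, planted, peptide_window = 7)
  xl <- simulate_crosslinks(spec, seed = 1)
  expect_equal(nrow(xl), 3)
  mono <- xl[is.na(xl$protein_b), ]
  expect_equal(nrow(mono), 1)
  expect_true(is.na(mono$residue_b) && is.na(mono$pep_b_start))
  # window clipped at the protein C terminus
  r98 <- xl[!is.na(xl$residue_a) & xl$residue_a == 98, ]
  expect_equal(c(r98$pep_a_start, r98$pep_a_end), c(91, 100))
  # planting on a non-lysine is rejected
  expect_error(
    crosslink_topology_spec(prots,
      tibble::tibble(protein_a = "P1", residue_a = 11L,
                     protein_b = NA, residue_b = NA)),
    "not a lysine")
})

test_that("planted link classes round-trip through classification", {
  prots <- tibble::tibble(
    protein = sprintf("Q%d", 1:4), length = rep(200L, 4),
    lysines = rep(list(c(20L, 60L, 100L, 140L, 180L)), 4))
  intra <- tibble::tibble(
    protein_a = c("Q1", "Q1", "Q2", "Q3", "Q4"),
    residue_a = c(20L, 60L, 20L, 100L, 140L),
    protein_b = c("Q1", "Q1", "Q2", "Q3", "Q4"),
    residue_b = c(100L, 180L, 140L, 180L, 180L))
  inter <- tibble::tibble(
    protein_a = c("Q1", "Q2", "Q3"), residue_a = c(20L, 60L, 20L),
    protein_b = c("Q2", "Q3", "Q4"), residue_b = c(20L, 60L, 20L))
  mono <- tibble::tibble(
    protein_a = c("Q1", "Q4"), residue_a = c(140L, 20L),
    protein_b = c(NA, NA), residue_b = c(NA, NA))
  spec <- crosslink_topology_spec(prots, dplyr::bind_rows(intra, inter, mono))
  cls <- classify_links(simulate_crosslinks(spec, seed = 8))
  expect_equal(unname(cls$counts[c("intra", "inter", "mono")]), c(5L, 3L, 2L))
})

test_that("annealing pair construction follows the printed assay geometry", {
  for (seed in c(1, 7, 123)) {
    pair <- make_annealing_pair(315, 60, 10, seed = seed)
    expect_equal(nchar(pair$substrate), 315)
    expect_equal(nchar(pair$probe), 80)
    # construction identity: probe core == revcomp of the substrate window
    core <- substr(pair$substrate, pair$core_start, pair$core_start + 59)
    expect_identical(
      substr(pair$probe, 11, 70),
      as.character(Biostrings::reverseComplement(Biostrings::RNAString(core))))
  }
  # zero flanks: fully complementary probe of core length
  p0 <- make_annealing_pair(315, 60, 0, seed = 4)
  expect_equal(nchar(p0$probe), 60)
  expect_error(make_annealing_pair(50, 60, 10, seed = 1), "exceeds")
})

test_that("probe flanks never pair with the substrate at the annealed register", {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (seed in 1:5) {
    pair <- make_annealing_pair(200, 40, 10, seed = seed)
    sub <- strsplit(pair$substrate, "")[[1]]
    probe <- strsplit(pair$probe, "")[[1]]
    # at the annealed register probe position i faces substrate position
    # core_start + core_len - 1 + (flank - i + 1) ... walk the full register
    reg_sub <- (pair$core_start + pair$core_len - 1 + 10):(pair$core_start - 10)
    for (i in seq_along(probe)) {
      sp <- reg_sub[i]
      if (sp < 1 || sp > length(sub)) next
      in_core <- i > 10 && i <= 50
      if (!in_core) expect_false(probe[i] == comp[[sub[sp]]])
    }
  }
})
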