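test_that("coverage depth counts M segments and skips N gaps", {
  sl <- c(TX1 = 400L)
  gal <- make_gal("TX1", 10, "75M", sl)
  depth <- coverage_profile(gal, "TX1")
  expect_equal(length(depth), 400)
  expect_true(all(depth[10:84] == 1))
  expect_true(all(depth[-(10:84)] == 0))

  gal2 <- make_gal("TX1", 1, "30M200N45M", sl)
  d2 <- coverage_profile(gal2, "TX1")
  expect_true(all(d2[1:30] == 1))
  expect_true(all(d2[31:230] == 0)) # the gap contributes nothing
  expect_true(all(d2[231:275] == 1))

  expect_error(coverage_profile(gal, "TXmissing"), "absent")
})

test_that("coverage agrees with the brute-force per-position oracle", {
  set.seed(31)
  for (case in 1:8) {
    len <- sample(150:400, 1)
    n <- sample(5:50, 1)
    pos <- sample(len - 100, n, replace = TRUE)
    cigar <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.4) {
        a <- sample(5:30, 1); gap <- sample(10:40, 1); b <- sample(5:30, 1)
        sprintf("%dM%dN%dM", a, gap, b)
      } else {
        sprintf("%dM", sample(20:75, 1))
      }
    }, character(1))
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
    keep <- pos + w - 1 <= len
    pos <- pos[keep]; cigar <- cigar[keep]
    gal <- make_gal(rep("T", length(pos)), pos, cigar, c(T = as.integer(len)))
    expect_equal(coverage_profile(gal, "T"),
                 brute_coverage(pos, cigar, len))
  }
})

test_that("truncated molecules produce 5'-biased coverage", {
  cfg <- generator_config(n_transcripts = 30, intron_fraction = 0,
                          nascent_truncation_fraction = 0.5,
                          n_read_pairs = 30000, seed = 13)
  txome <- generate_transcriptome(cfg)
  reads <- simulate_reads(txome, cfg, "eluate")
  profs <- coverage_profiles(as_galignments(reads, txome, "transcript"))
  decile_means <- vapply(profs, function(d) {
    L <- length(d)
    k <- max(1L, L %/% 10L)
    c(mean(d[1:k]), mean(d[(L - k + 1):L]))
  }, numeric(2))
  expect_gt(mean(decile_means[1, ]), mean(decile_means[2, ]))
})

test_that("metagene scaling follows the 100-bin 0-1 / 0-100% contract", {
  # constant profile -> all-zero row (degenerate min-max rule)
  flat <- list(A = rep(5L, 300))
  # strictly decreasing profile -> row from 1 down to 0
  dec <- list(B = as.integer(seq(300, 1)))
  mg <- metagene_matrix(c(flat, dec))
  expect_equal(ncol(mg$matrix), 100)
  expect_true(all(mg$matrix["A", ] == 0))
  expect_equal(unname(mg$matrix["B", 1]), 1)
  expect_equal(unname(mg$matrix["B", 100]), 0)
  expect_true(all(diff(mg$matrix["B", ]) < 0))
  expect_true(all(mg$matrix >= 0 & mg$matrix <= 1))
  expect_true(all(mg$summary >= 0 & mg$summary <= 100))
  expect_equal(max(mg$summary), 100)
  expect_error(metagene_matrix(list()), "empty")
})

test_that("metagene end bins separate truncated from untruncated samples", {
  base <- list(n_transcripts = 60, intron_fraction = 0, n_read_pairs = 40000)
  cfg0 <- do.call(generator_config,
                  c(base, nascent_truncation_fraction = 0, seed = 17))
  cfg5 <- do.call(generator_config,
                  c(base, nascent_truncation_fraction = 0.5, seed = 17))
  txome <- generate_transcriptome(cfg0)
  mg <- function(cfg) {
    r <- simulate_reads(txome, cfg, "eluate")
    metagene_matrix(coverage_profiles(as_galignments(r, txome, "transcript")))
  }
  m0 <- mg(cfg0); m5 <- mg(cfg5)
  expect_gt(m5$summary[1], m0$summary[1])
  expect_lte(m5$summary[100], m0$summary[100])
  expect_gt(metagene_end_contrast(m5), metagene_end_contrast(m0))
})

test_that("junction counting matches hand counts and applies the coverage filter", {
  # one intron: mature junction after base 100, intron [201, 300] in genome
  tx <- tibble::tibble(
    transcript_id = "TXJ", chrom = "chrN", tx_start = 101L, tx_end = 500L,
    genome = "nuclear", half_life_min = 10, has_intron = TRUE, length = 300L,
    exon1_end = 200L, intron_start = 201L, intron_end = 300L,
    exon2_start = 301L, junction = 100L, intron_length = 100L)
  sl <- c(chrN = 600L)
  # 15 split reads with the exact gap, 5 nonsplit over the 5' site
  gal <- make_gal(
    rname = rep("chrN", 22),
    pos = c(rep(171L, 15), rep(181L, 5), 150L, 173L),
    cigar = c(rep("30M100N45M", 15), rep("75M", 5),
              "20M", # gapless, far from the site: counted nowhere
              "28M90N47M"), # gap disagrees with annotation: discarded
    seqlengths = sl)
  js <- junction_stats(gal, tx, min_cov = 20, min_anchor = 3)
  five <- js[js$site == "five_prime", ]
  expect_equal(nrow(five), 1) # covered = 20 retained at the boundary
  expect_equal(five$split_count, 15)
  expect_equal(five$nonsplit_count, 5)
  expect_equal(five$unspliced_fraction, 5 / 15)
  # the 3' site has only the 15 split reads -> covered 15 < 20, excluded
  expect_equal(nrow(js[js$site == "three_prime", ]), 0)

  # 10 split + 9 nonsplit = 19 < 20 -> excluded
  gal19 <- make_gal(rep("chrN", 19),
                    c(rep(171L, 10), rep(181L, 9)),
                    c(rep("30M100N45M", 10), rep("75M", 9)), sl)
  expect_equal(nrow(junction_stats(gal19, tx, min_cov = 20)), 0)
  expect_equal(nrow(junction_stats(gal19, tx, min_cov = 19)), 1)
})

test_that("raising min_cov never increases retained junctions", {
  fx <- small_txome(seed = 23, n = 40, intron_fraction = 1,
                    n_read_pairs = 20000, retention_rate = 0.2)
  gal <- as_galignments(simulate_reads(fx$txome, fx$cfg, "eluate"),
                        fx$txome, "genome")
  retained <- vapply(c(1, 5, 10, 20, 40, 80),
                     function(mc) nrow(junction_stats(gal, fx$txome, min_cov = mc)),
                     numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("zero retention yields all-zero unspliced fractions", {
  fx <- small_txome(seed = 29, n = 30, intron_fraction = 1,
                    n_read_pairs = 20000, retention_rate = 0)
  gal <- as_galignments(simulate_reads(fx$txome, fx$cfg, "lysate"),
                        fx$txome, "genome")
  js <- junction_stats(gal, fx$txome, min_cov = 20)
  expect_gt(nrow(js), 0)
  expect_true(all(js$unspliced_fraction == 0))
})

test_that("unspliced-fraction comparison behaves under symmetry and identity", {
  a <- tibble::tibble(unspliced_fraction = rep(c(0.1, 0.2, 0.3, 0.4), 25))
  b <- tibble::tibble(unspliced_fraction = rep(c(0.1, 0.2, 0.3, 0.4), 25))
  res <- compare_unspliced(a, b)
  expect_false(res$degenerate)
  expect_gt(res$p_value, 0.9) # identical large samples

  b2 <- tibble::tibble(unspliced_fraction = rep(c(0.5, 0.6, 0.7, 0.8), 25))
  r12 <- compare_unspliced(a, b2)
  r21 <- compare_unspliced(b2, a)
  expect_equal(r12$p_value, r21$p_value)
  expect_equal(r12$statistic, 100 * 100 - r21$statistic) # mirrored W

  same <- tibble::tibble(unspliced_fraction = rep(0.2, 10))
  expect_true(compare_unspliced(same, same)$degenerate)
})

test_that("median-of-ratios normalization absorbs global scale", {
  l <- setNames(c(100L, 50L, 10L, 400L, 33L), paste0("t", 1:5))
  e <- 2L * l
  enr <- enrichment_table(l, e, pseudocount = 0.5)
  expect_true(all(abs(enr$log2fc) < 1e-9))
  sf <- attr(enr, "size_factors")
  expect_equal(unname(sf[["eluate"]] / sf[["lysate"]]), 2)

  # equal counts, equal factors, any pseudocount -> log2fc 0
  enr2 <- enrichment_table(c(a = 100L), c(a = 100L))
  expect_equal(enr2$log2fc, 0)
  expect_error(enrichment_table(c(a = 0L, b = 0L), c(a = 1L, b = 2L)),
               "all-zero")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  set.seed(77)
  l <- rpois(200, 50) + 1L
  e <- rpois(200, 80) + 1L
  names(l) <- names(e) <- sprintf("t%03d", 1:200)
  sf <- attr(enrichment_table(l, e), "size_factors")
  mat <- cbind(lysate = l, eluate = e)
  ref <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(mat))
  # size factors are defined up to a common scale; compare the ratio
  expect_equal(sf[["eluate"]] / sf[["lysate"]],
               unname(ref["eluate"] / ref["lysate"]), tolerance = 1e-6)
})

test_that("Spearman correlation of enrichment behaves on exact ranks", {
  rec <- tibble::tibble(transcript_id = paste0("t", 1:10),
                        log2fc = seq(0.1, 1, by = 0.1))
  cov <- setNames(1:10, rec$transcript_id)
  res <- correlate_enrichment(rec, cov, "length")
  expect_equal(res$rho, 1)
  expect_error(correlate_enrichment(rec, setNames(rep(1, 10), rec$transcript_id)),
               "constant")
  expect_error(correlate_enrichment(rec[1:2, ], cov[1:2]), ">= 3")
})

test_that("simulated length effect surfaces as positive rank correlation", {
  cfg <- generator_config(n_transcripts = 300, intron_fraction = 0,
                          mito_fraction = 0,
                          enrichment_coefficients = c(0, 0.8),
                          n_read_pairs = 40000, seed = 37)
  txome <- generate_transcriptome(cfg)
  enr <- enrichment_table(
    count_read_pairs(simulate_reads(txome, cfg, "lysate"),
                     txome$transcripts$transcript_id),
    count_read_pairs(simulate_reads(txome, cfg, "eluate"),
                     txome$transcripts$transcript_id))
  res <- correlate_enrichment(
    enr, setNames(txome$transcripts$length, txome$transcripts$transcript_id),
    "length")
  expect_gt(res$rho, 0.3)
})
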