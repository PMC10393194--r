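#' Split/nonsplit read statistics at annotated splice sites
#'
#' For every annotated intron, the 5' and 3' splice sites are scored as
#' separate junction records. A read counts as *split* at a site when it
#' carries an alignment gap (CIGAR N) identical to the annotated intron and
#' is anchored by at least `min_anchor` aligned nucleotides on both sides of
#' the gap. A read counts as *nonsplit* when it is gapless and covers the
#' junction point contiguously with at least `min_anchor` aligned
#' nucleotides on each side. Reads whose gap disagrees with the annotation
#' are discarded from both counts. Junctions with fewer than `min_cov`
#' counted reads (split + nonsplit) are excluded; the unspliced fraction is
#' nonsplit / split, defined only when split > 0.
#'
#' @param alignments A `GAlignments` in genome coordinates.
#' @param txome An `mrnp_transcriptome`, or its `transcripts` tibble, or a
#'   tibble from [read_transcriptome_gff3()].
#' @param min_cov Minimum counted reads for a junction to be retained
#'   (default 20).
#' @param min_anchor Minimum aligned nucleotides flanking the junction point
#'   (default 3).
#' @return A tibble with one row per retained junction: `junction_id`,
#'   `transcript_id`, `site` (`"five_prime"`/`"three_prime"`),
#'   `split_count`, `nonsplit_count`, `covered`, `unspliced_fraction`.
#' @export
junction_stats <- function(alignments, txome, min_cov = 20L, min_anchor = 3L) {
  tx <- if (inherits(txome, "mrnp_transcriptome")) txome$transcripts else txome
  introns <- tx[tx$has_intron, , drop = FALSE]
  if (nrow(introns) > 0 && any(introns$intron_length <= 0)) {
    stop("intron with nonpositive length", call. = FALSE)
  }
  out <- tibble::tibble(junction_id = character(), transcript_id = character(),
                        site = character(), split_count = integer(),
                        nonsplit_count = integer(), covered = integer(),
                        unspliced_fraction = numeric())
  if (nrow(introns) == 0 || length(alignments) == 0) return(out)

  chrom <- as.character(GenomicAlignments::seqnames(alignments))
  astart <- GenomicAlignments::start(alignments)
  aend <- GenomicAlignments::end(alignments)
  nj <- GenomicAlignments::njunc(alignments)
  ni <- nrow(introns)

  # split reads: gap must equal an annotated intron exactly, with anchors
  intron_key <- paste(introns$chrom, introns$intron_start,
                      introns$intron_end, sep = ":")
  split_n <- integer(ni)
  has_gap <- nj > 0
  if (any(has_gap)) {
    jr <- GenomicAlignments::junctions(alignments[has_gap])
    flat <- unlist(jr, use.names = FALSE)
    ridx <- which(has_gap)[rep(seq_along(jr), S4Vectors::elementNROWS(jr))]
    gap_key <- paste(chrom[ridx], GenomicRanges::start(flat),
                     GenomicRanges::end(flat), sep = ":")
    midx <- match(gap_key, intron_key)
    ok <- !is.na(midx)
    ok[ok] <- astart[ridx[ok]] <= introns$intron_start[midx[ok]] - min_anchor &
      aend[ridx[ok]] >= introns$intron_end[midx[ok]] + min_anchor
    split_n <- tabulate(midx[ok], nbins = ni)
  }

  gapless <- GenomicRanges::GRanges(
    chrom[nj == 0], IRanges::IRanges(astart[nj == 0], aend[nj == 0]))
  win5 <- GenomicRanges::GRanges(
    introns$chrom,
    IRanges::IRanges(introns$intron_start - min_anchor,
                     introns$intron_start + min_anchor - 1L))
  win3 <- GenomicRanges::GRanges(
    introns$chrom,
    IRanges::IRanges(introns$intron_end - min_anchor + 1L,
                     introns$intron_end + min_anchor))
  ns5 <- GenomicRanges::countOverlaps(win5, gapless, type = "within")
  ns3 <- GenomicRanges::countOverlaps(win3, gapless, type = "within")

  res <- tibble::tibble(
    junction_id = c(paste0(introns$transcript_id, ":5p"),
                    paste0(introns$transcript_id, ":3p")),
    transcript_id = rep(introns$transcript_id, 2L),
    site = rep(c("five_prime", "three_prime"), each = ni),
    split_count = rep(split_n, 2L),
    nonsplit_count = c(ns5, ns3)
  )
  res$covered <- res$split_count + res$nonsplit_count
  res$unspliced_fraction <- ifelse(res$split_count > 0,
                                   res$nonsplit_count / res$split_count, NA_real_)
  res[res$covered >= min_cov, , drop = FALSE]
}

#' Compare unspliced-fraction distributions between two samples
#'
#' Two-sided Wilcoxon rank-sum test on the per-junction unspliced fractions
#' (normal approximation with continuity and tie correction). Junctions with
#' undefined fractions (no split reads) are dropped. When every value in
#' both samples is identical the comparison is degenerate and the p-value is
#' reported as `NA`.
#'
#' @param stats_a,stats_b Junction tibbles from [junction_stats()] (or any
#'   tibbles with an `unspliced_fraction` column).
#' @return List with `statistic` (W), `p_value`, `n` (per-sample counts),
#'   `degenerate`.
#' @export
compare_unspliced <- function(stats_a, stats_b) {
  x <- stats_a$unspliced_fraction
  y <- stats_b$unspliced_fraction
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 retained junctions with defined fractions per sample",
         call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = c(length(x), length(y)), degenerate = TRUE))
  }
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(x), length(y)), degenerate = FALSE)
}
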