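#' Generate a synthetic annotated transcriptome
#'
#' Builds a set of transcripts with the structural features the downstream
#' analyses assume: a deterministic number of monointronic transcripts
#' (exactly two exons each), a deterministic number of
#' mitochondrial-encoded transcripts, a log-uniform half-life covariate, and
#' genome coordinates obtained by tiling the transcripts on two synthetic
#' chromosomes (`chrN` nuclear, `chrM` mitochondrial) separated by fixed
#' intergenic gaps. All transcripts are on the plus strand. Mature
#' (spliced) sequences are extracted from random chromosome sequences.
#'
#' @param config A [generator_config()].
#' @return An object of class `mrnp_transcriptome`: a list with
#'   `transcripts` (tibble of per-transcript annotation, 1-based closed
#'   genome coordinates), `sequences` (mature transcript `DNAStringSet`) and
#'   `genome` (chromosome `DNAStringSet`).
#' @export
#' @examples
#' txome <- generate_transcriptome(generator_config(n_transcripts = 20, seed = 3))
#' nrow(txome$transcripts)
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "mrnp_generator_config"))
  set.seed(sub_seed(config$seed, "transcriptome"))
  n <- config$n_transcripts
  ld <- config$length_distribution

  len <- as.integer(round(ld[["min_nt"]] +
    (ld[["max_nt"]] - ld[["min_nt"]]) * runif(n)^ld[["shape"]]))
  # junction placement needs room on both sides; enforce a small floor
  len <- pmax(len, 50L)

  n_intron <- as.integer(round(config$intron_fraction * n))
  n_mito <- as.integer(round(config$mito_fraction * n))
  has_intron <- rep(FALSE, n)
  if (n_intron > 0) has_intron[sample.int(n, n_intron)] <- TRUE
  genome_of <- rep("nuclear", n)
  if (n_mito > 0) genome_of[sample.int(n, n_mito)] <- "mito"

  hl <- config$halflife_range
  half_life <- exp(runif(n, log(hl[["min_min"]]), log(hl[["max_min"]])))

  # junction position = last mature base of exon 1 (mature coordinates)
  junction <- ifelse(has_intron,
                     pmax(2L, pmin(len - 2L,
                                   as.integer(round(len * runif(n, 0.2, 0.8))))),
                     NA_integer_)
  intron_len <- ifelse(has_intron,
                       as.integer(round(runif(n, 80, 400))), 0L)

  gap <- 200L
  span <- len + intron_len
  tx <- tibble::tibble(
    transcript_id = sprintf("TX%04d", seq_len(n)),
    length = len,
    genome = genome_of,
    has_intron = has_intron,
    half_life_min = round(half_life, 3),
    junction = junction,
    intron_length = intron_len
  )

  tx$chrom <- ifelse(tx$genome == "mito", "chrM", "chrN")
  tx$tx_start <- NA_integer_
  for (chr in c("chrN", "chrM")) {
    i <- which(tx$chrom == chr)
    if (!length(i)) next
    starts <- gap + cumsum(c(0L, (span[i] + gap)[-length(i)]))
    tx$tx_start[i] <- starts + 1L
  }
  tx$tx_end <- tx$tx_start + span - 1L
  tx$exon1_end <- ifelse(tx$has_intron, tx$tx_start + tx$junction - 1L, tx$tx_end)
  tx$intron_start <- ifelse(tx$has_intron, tx$exon1_end + 1L, NA_integer_)
  tx$intron_end <- ifelse(tx$has_intron, tx$intron_start + tx$intron_length - 1L,
                          NA_integer_)
  tx$exon2_start <- ifelse(tx$has_intron, tx$intron_end + 1L, NA_integer_)

  chrom_len <- vapply(c("chrN", "chrM"), function(chr) {
    i <- tx$chrom == chr
    if (!any(i)) 2L * gap else max(tx$tx_end[i]) + gap
  }, integer(1))
  genome_seq <- Biostrings::DNAStringSet(vapply(chrom_len, random_dna, character(1)))
  names(genome_seq) <- names(chrom_len)

  mature <- vapply(seq_len(n), function(i) {
    chr <- as.character(genome_seq[[tx$chrom[i]]])
    if (tx$has_intron[i]) {
      paste0(substr(chr, tx$tx_start[i], tx$exon1_end[i]),
             substr(chr, tx$exon2_start[i], tx$tx_end[i]))
    } else {
      substr(chr, tx$tx_start[i], tx$tx_end[i])
    }
  }, character(1))
  sequences <- Biostrings::DNAStringSet(mature)
  names(sequences) <- tx$transcript_id

  structure(list(transcripts = tx, sequences = sequences, genome = genome_seq),
            class = "mrnp_transcriptome")
}

#' @export
print.mrnp_transcriptome <- function(x, ...) {
  cat(sprintf("mrnp_transcriptome: %d transcripts (%d intronic, %d mitochondrial)\n",
              nrow(x$transcripts), sum(x$transcripts$has_intron),
              sum(x$transcripts$genome == "mito")))
  invisible(x)
}

#' Write a transcriptome annotation as GFF3
#'
#' Emits `transcript` and `exon` features in 1-based closed coordinates with
#' `half_life_min` and `genome` attributes on the transcript records, via
#' rtracklayer.
#'
#' @param txome An `mrnp_transcriptome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_gff3 <- function(txome, path) {
  tx <- txome$transcripts
  feats <- list()
  for (i in seq_len(nrow(tx))) {
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = tx$chrom[i], start = tx$tx_start[i], end = tx$tx_end[i],
      type = "transcript", ID = tx$transcript_id[i], Parent = NA_character_,
      half_life_min = tx$half_life_min[i], genome = tx$genome[i]
    )
    ex <- if (tx$has_intron[i]) {
      data.frame(start = c(tx$tx_start[i], tx$exon2_start[i]),
                 end = c(tx$exon1_end[i], tx$tx_end[i]))
    } else {
      data.frame(start = tx$tx_start[i], end = tx$tx_end[i])
    }
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = tx$chrom[i], start = ex$start, end = ex$end, type = "exon",
      ID = sprintf("%s.exon%d", tx$transcript_id[i], seq_len(nrow(ex))),
      Parent = tx$transcript_id[i],
      half_life_min = NA_real_, genome = NA_character_
    )
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$half_life_min <- df$half_life_min
  S4Vectors::mcols(gr)$genome <- df$genome
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a transcriptome annotation from GFF3
#'
#' Reconstructs the per-transcript annotation tibble (transcript bounds,
#' exon structure, half-life and genome-of-origin attributes) from a GFF3
#' file written by [write_transcriptome_gff3()] or any file following the
#' same two-level transcript/exon layout.
#'
#' @param path GFF3 file path.
#' @return A tibble in the layout of `mrnp_transcriptome$transcripts`.
#' @export
read_transcriptome_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  is_tx <- m$type == "transcript"
  txg <- gr[is_tx]
  txm <- S4Vectors::mcols(txg)
  exg <- gr[m$type == "exon"]
  parent <- as.character(S4Vectors::mcols(exg)$Parent)

  out <- tibble::tibble(
    transcript_id = as.character(txm$ID),
    chrom = as.character(GenomicRanges::seqnames(txg)),
    tx_start = GenomicRanges::start(txg),
    tx_end = GenomicRanges::end(txg),
    genome = as.character(txm$genome),
    half_life_min = as.numeric(txm$half_life_min)
  )
  ex_by <- split(exg, parent)
  info <- lapply(out$transcript_id, function(id) {
    ex <- ex_by[[id]]
    ex <- ex[order(GenomicRanges::start(ex))]
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    if (length(ex) == 2) {
      list(has_intron = TRUE, length = sum(e - s + 1L),
           exon1_end = e[1], intron_start = e[1] + 1L,
           intron_end = s[2] - 1L, exon2_start = s[2],
           junction = e[1] - s[1] + 1L, intron_length = s[2] - e[1] - 1L)
    } else {
      list(has_intron = FALSE, length = sum(e - s + 1L),
           exon1_end = e[length(e)], intron_start = NA_integer_,
           intron_end = NA_integer_, exon2_start = NA_integer_,
           junction = NA_integer_, intron_length = 0L)
    }
  })
  for (f in c("has_intron", "length", "exon1_end", "intron_start",
              "intron_end", "exon2_start", "junction", "intron_length")) {
    out[[f]] <- vapply(info, function(x) x[[f]],
                       if (f == "has_intron") logical(1) else integer(1))
  }
  out
}
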