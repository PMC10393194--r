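#' Write simulated reads as SAM
#'
#' Serializes an `mrnp_reads` object to a valid SAM file with an `@SQ`
#' header per reference, proper paired flags (99/147), CIGAR restricted to
#' M and N operations, reference-derived read sequences and a constant
#' placeholder quality string.
#'
#' @param reads An `mrnp_reads` object.
#' @param txome The source `mrnp_transcriptome` (reference names, lengths
#'   and sequences).
#' @param path Output path.
#' @param mode `"transcript"` (per-transcript references) or `"genome"`
#'   (synthetic chromosomes).
#' @param with_seq Emit actual read sequences (`TRUE`) or `*` placeholders.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, txome, path, mode = c("transcript", "genome"),
                      with_seq = TRUE) {
  mode <- match.arg(mode)
  tbl <- reads[[mode]]
  if (mode == "transcript") {
    refs <- setNames(txome$transcripts$length, txome$transcripts$transcript_id)
    refseq <- setNames(as.character(txome$sequences), names(txome$sequences))
    rname <- tbl$rname
    pos <- tbl$start
  } else {
    refs <- setNames(Biostrings::width(txome$genome), names(txome$genome))
    refseq <- setNames(as.character(txome$genome), names(txome$genome))
    rname <- tbl$chrom
    pos <- tbl$pos
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs),
              "@PG\tID:mrnpAtlas\tPN:mrnpAtlas")

  n <- nrow(tbl)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  flag <- ifelse(tbl$mate == 1L, 99L, 147L)

  # mate coordinates: records come as all mate-1 rows then all mate-2 rows
  half <- n / 2L
  pnext_ <- c(pos[(half + 1L):n], pos[1:half])
  aln_end <- pos + cigar_ref_width(tbl$cigar) - 1L
  tlen <- integer(n)
  tlen[1:half] <- pmax(aln_end[(half + 1L):n], aln_end[1:half]) - pos[1:half] + 1L
  tlen[(half + 1L):n] <- -tlen[1:half]

  if (with_seq) {
    seqs <- extract_read_seq(refseq, rname, pos, tbl$cigar)
    quals <- strrep("I", nchar(seqs))
  } else {
    seqs <- rep("*", n)
    quals <- rep("*", n)
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t%s\t%s",
                 tbl$qname, flag, rname, pos, tbl$cigar, pnext_, tlen,
                 seqs, quals)
  con <- file(path, "wb") # binary connection => byte-identical across platforms
  on.exit(close(con))
  writeLines(c(header, rec), con)
  invisible(path)
}

# reference-space width of an M/N/D/I/S CIGAR
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# read sequence = concatenated reference bases under the M segments
extract_read_seq <- function(refseq, rname, pos, cigar) {
  simple <- !grepl("N", cigar, fixed = TRUE)
  out <- character(length(cigar))
  full <- refseq[rname]
  w <- cigar_ref_width(cigar)
  if (any(simple)) {
    out[simple] <- substr(full[simple], pos[simple], pos[simple] + w[simple] - 1L)
  }
  for (i in which(!simple)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[i])[[1]]
    p <- pos[i]
    parts <- character(0)
    for (k in seq_along(ops)) {
      if (ops[k] == "M") parts <- c(parts, substr(full[i], p, p + lens[k] - 1L))
      p <- p + lens[k]
    }
    out[i] <- paste(parts, collapse = "")
  }
  out
}

#' Read a SAM file into a GAlignments object
#'
#' Converts the SAM to BAM via Rsamtools and loads it with
#' GenomicAlignments, preserving read names.
#'
#' @param path SAM file path.
#' @return A `GAlignments` named by read name.
#' @export
read_sam <- function(path) {
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, destination = dest,
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  GenomicAlignments::readGAlignments(bam, use.names = TRUE)
}
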