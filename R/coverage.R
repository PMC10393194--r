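#' Per-nucleotide coverage profile of one transcript
#'
#' Depth at position p is the number of aligned (CIGAR M) segments covering
#' p; N gaps contribute nothing (I/D are handled by GenomicAlignments as
#' coverage-neutral length adjustments).
#'
#' @param alignments A `GAlignments` in transcript coordinates.
#' @param transcript_id Reference (transcript) name.
#' @param length Transcript length; taken from `seqlengths(alignments)` when
#'   missing.
#' @return Integer vector of depths, 5' to 3', of length `length`.
#' @export
#' @examples
#' gal <- GenomicAlignments::GAlignments(
#'   seqnames = factor("TX1"), pos = 10L, cigar = "75M",
#'   strand = factor("+", levels = c("+", "-", "*")),
#'   seqlengths = c(TX1 = 200L))
#' depth <- coverage_profile(gal, "TX1")
#' sum(depth)
coverage_profile <- function(alignments, transcript_id, length = NULL) {
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (!transcript_id %in% names(sl)) {
    stop(sprintf("transcript '%s' absent from alignment header", transcript_id),
         call. = FALSE)
  }
  if (is.null(length)) length <- unname(sl[transcript_id])
  if (is.na(length)) stop("transcript length unknown", call. = FALSE)
  sub <- alignments[as.character(GenomicAlignments::seqnames(alignments)) ==
                      transcript_id]
  if (!methods::is(sub, "GAlignments") || length(sub) == 0) {
    return(integer(length))
  }
  cvg <- GenomicAlignments::coverage(sub)[[transcript_id]]
  depth <- as.integer(cvg)
  if (base::length(depth) < length) depth <- c(depth, integer(length - base::length(depth)))
  depth[seq_len(length)]
}

#' Coverage profiles for a set of transcripts
#'
#' @param alignments A `GAlignments` in transcript coordinates with
#'   seqlengths set.
#' @param transcript_ids Transcripts to profile; defaults to every reference
#'   in the header.
#' @return Named list of integer depth vectors.
#' @export
coverage_profiles <- function(alignments, transcript_ids = NULL) {
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (is.null(transcript_ids)) transcript_ids <- names(sl)
  cvg <- GenomicAlignments::coverage(alignments)
  out <- lapply(transcript_ids, function(id) {
    depth <- if (id %in% names(cvg)) as.integer(cvg[[id]]) else integer(0)
    len <- unname(sl[id])
    if (length(depth) < len) depth <- c(depth, integer(len - length(depth)))
    depth[seq_len(len)]
  })
  names(out) <- transcript_ids
  out
}

#' Metagene matrix: 100-bin scaled coverage across transcripts
#'
#' Each transcript's coverage is averaged within `bins` equal-width bins
#' over its own length and min-max scaled to \[0, 1\] (a constant binned
#' profile scales to all zeros: a flat profile carries no positional
#' signal). The per-bin average over transcripts is then min-max rescaled to
#' \[0%, 100%\].
#'
#' @param profiles Named list of per-transcript depth vectors
#'   (see [coverage_profiles()]).
#' @param transcripts Optional character vector restricting the cohort
#'   (typically nuclear, intronless transcripts).
#' @param bins Number of positional bins (default 100).
#' @return An object of class `mrnp_metagene`: list with `matrix`
#'   (transcripts x bins, values in \[0,1\]) and `summary` (per-bin average
#'   rescaled to \[0,100\]).
#' @export
metagene_matrix <- function(profiles, transcripts = NULL, bins = 100L) {
  if (!is.null(transcripts)) profiles <- profiles[intersect(transcripts, names(profiles))]
  if (length(profiles) == 0) stop("empty transcript subset", call. = FALSE)
  rows <- t(vapply(profiles, function(depth) {
    L <- length(depth)
    if (L == 0) return(numeric(bins))
    bin <- as.integer(floor((seq_len(L) - 1) * bins / L)) + 1L
    means <- vapply(split(depth, factor(bin, levels = seq_len(bins))),
                    function(v) if (length(v)) mean(v) else 0, numeric(1))
    scale_minmax(means)
  }, numeric(bins)))
  rownames(rows) <- names(profiles)
  colnames(rows) <- sprintf("bin%03d", seq_len(bins))
  avg <- colMeans(rows)
  structure(list(matrix = rows, summary = 100 * scale_minmax(avg)),
            class = "mrnp_metagene")
}

#' @export
print.mrnp_metagene <- function(x, ...) {
  cat(sprintf("mrnp_metagene: %d transcripts x %d bins; summary peak at bin %d\n",
              nrow(x$matrix), ncol(x$matrix), which.max(x$summary)))
  invisible(x)
}

#' 5'-versus-3' contrast of a metagene summary
#'
#' Difference between the first and the last bin of the column summary; a
#' positive value indicates 5'-biased coverage.
#'
#' @param metagene An `mrnp_metagene`.
#' @return Numeric scalar in \[-100, 100\].
#' @export
metagene_end_contrast <- function(metagene) {
  s <- metagene$summary
  unname(s[1] - s[length(s)])
}
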