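#' Validate pipeline input/output files
#'
#' Lightweight schema validation with line-anchored diagnostics for the
#' formats the pipeline exchanges: GFF3 (9 tab-separated columns, numeric
#' bounds, start <= end), SAM (header with `@SQ` lines, 11+ fields per
#' record, CIGAR syntax, position within the reference), FASTA (header
#' lines, nonempty records) and TSV (cross-link tables additionally checked
#' for the residue-within-peptide-interval invariant; peptide tables for
#' their required columns).
#'
#' @param files Character vector of paths. Format is inferred from the
#'   extension (`.gff3`, `.sam`, `.fasta`/`.fa`, `.tsv`).
#' @return Tibble of diagnostics: `file`, `line`, `message`. Zero rows
#'   means every file passed.
#' @export
validate_inputs <- function(files) {
  diags <- list()
  note <- function(file, line, message) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      file = file, line = as.integer(line), message = message)
  }
  for (f in files) {
    if (!file.exists(f)) {
      note(f, NA, "file not readable")
      next
    }
    ext <- tolower(tools::file_ext(f))
    lines <- readLines(f, warn = FALSE)
    switch(ext,
      gff3 = validate_gff3(f, lines, note),
      sam = validate_sam(f, lines, note),
      fasta = ,
      fa = validate_fasta(f, lines, note),
      tsv = validate_tsv(f, lines, note),
      note(f, NA, sprintf("unknown format '.%s'", ext))
    )
  }
  if (!length(diags)) {
    return(tibble::tibble(file = character(), line = integer(),
                          message = character()))
  }
  dplyr::bind_rows(diags)
}

validate_gff3 <- function(f, lines, note) {
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 9) {
      note(f, i, sprintf("GFF3 record has %d columns, expected 9", length(parts)))
      next
    }
    s <- suppressWarnings(as.integer(parts[4]))
    e <- suppressWarnings(as.integer(parts[5]))
    if (is.na(s) || is.na(e)) {
      note(f, i, "non-numeric start/end")
    } else if (s > e) {
      note(f, i, "start > end")
    } else if (s < 1) {
      note(f, i, "start < 1 (GFF3 is 1-based)")
    }
  }
}

validate_sam <- function(f, lines, note) {
  sq <- list()
  header <- startsWith(lines, "@")
  if (!any(header)) note(f, 1, "SAM header missing")
  for (i in which(header)) {
    if (startsWith(lines[i], "@SQ")) {
      sn <- sub(".*\tSN:([^\t]+).*", "\\1", lines[i])
      ln <- suppressWarnings(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", lines[i])))
      sq[[sn]] <- ln
    }
  }
  if (!length(sq)) note(f, 1, "no @SQ reference lines in header")
  cigar_re <- "^(\\*|([0-9]+[MIDNSHP=X])+)$"
  for (i in which(!header & nzchar(lines))) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 11) {
      note(f, i, sprintf("SAM record '%s' has %d fields, expected >= 11",
                         parts[1], length(parts)))
      next
    }
    if (!grepl(cigar_re, parts[6])) {
      note(f, i, sprintf("SAM record '%s' has malformed CIGAR '%s'",
                         parts[1], parts[6]))
      next
    }
    rname <- parts[3]
    pos <- suppressWarnings(as.integer(parts[4]))
    if (rname != "*" && !is.null(sq[[rname]]) && !is.na(pos) &&
        parts[6] != "*") {
      w <- GenomicAlignments::cigarWidthAlongReferenceSpace(parts[6])
      if (pos < 1 || pos + w - 1L > sq[[rname]]) {
        note(f, i, sprintf("SAM record '%s' outside reference %s bounds",
                           parts[1], rname))
      }
    }
  }
}

validate_fasta <- function(f, lines, note) {
  if (!length(lines) || !startsWith(lines[1], ">")) {
    note(f, 1, "FASTA must start with a '>' header")
    return(invisible())
  }
  hdr <- which(startsWith(lines, ">"))
  for (k in seq_along(hdr)) {
    from <- hdr[k] + 1L
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    if (from > to || !any(nzchar(lines[from:to]))) {
      note(f, hdr[k], "FASTA record has no sequence")
    }
  }
}

validate_tsv <- function(f, lines, note) {
  if (!length(lines)) {
    note(f, 1, "empty TSV")
    return(invisible())
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  xl_cols <- c("protein_a", "residue_a", "pep_a_start", "pep_a_end",
               "protein_b", "residue_b", "pep_b_start", "pep_b_end")
  pep_cols <- c("protein", "peptide_seq", "replicate", "condition", "intensity")
  if (all(xl_cols %in% header)) {
    tab <- utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
    for (side in c("a", "b")) {
      r <- tab[[paste0("residue_", side)]]
      s <- tab[[paste0("pep_", side, "_start")]]
      e <- tab[[paste0("pep_", side, "_end")]]
      bad <- which(!is.na(r) & (is.na(s) | is.na(e) | r < s | r > e))
      for (i in bad) {
        note(f, i + 1L,
             sprintf("cross-link residue_%s=%d outside peptide interval [%s,%s]",
                     side, r[i], s[i], e[i]))
      }
    }
  } else if (any(pep_cols %in% header) && !all(pep_cols %in% header)) {
    note(f, 1, paste("peptide TSV missing column(s):",
                     paste(setdiff(pep_cols, header), collapse = ", ")))
  }
  ncol_header <- length(header)
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    # count separators (trailing empty fields must still count)
    n <- nchar(lines[i]) - nchar(gsub("\t", "", lines[i], fixed = TRUE)) + 1L
    if (n != ncol_header) {
      note(f, i, sprintf("TSV row has %d fields, header has %d", n, ncol_header))
    }
  }
}
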