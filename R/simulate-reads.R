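#' Simulate paired-end reads from a synthetic transcriptome
#'
#' Draws read pairs under the abundance model that distinguishes the eluted
#' mRNP fraction from the total lysate, then places fragments on source
#' molecules that may be 3'-truncated (the nascent-transcription proxy
#' behind 5'-biased coverage). Per-transcript baseline abundances depend
#' only on `config$seed`, so lysate and eluate simulated from the same
#' config share baselines and differ only by the enrichment model:
#' eluate log-abundance is shifted by
#' `beta_halflife * z(log half-life) + beta_length * z(log length)` and
#' mitochondrial transcripts are scaled by `mito_depletion_factor`.
#' Read counts per transcript are Poisson around the model means.
#'
#' Junction-spanning reads on intron-carrying transcripts are emitted split
#' (alignment gap exactly spanning the annotated intron) with probability
#' `1 - retention_rate`, else unspliced: a contiguous alignment anchored
#' with equal probability at the 5' or the 3' splice site, running into the
#' intron.
#'
#' Alignments are produced in two coordinate systems at once: transcript
#' coordinates (per-transcript references; used for coverage and counting)
#' and genome coordinates (transcripts tiled on the synthetic chromosomes;
#' used for splice-junction statistics).
#'
#' @param txome An `mrnp_transcriptome` from [generate_transcriptome()].
#' @param config The [generator_config()] used to build `txome`.
#' @param sample_label `"lysate"` or `"eluate"`; selects the abundance model.
#' @param seed Seed for the sample-specific randomness (fragment placement,
#'   truncation, retention); defaults to `config$seed`.
#' @param n_pairs Number of read pairs; defaults to `config$n_read_pairs`.
#' @return An object of class `mrnp_reads`: list with `transcript` and
#'   `genome` alignment tibbles (1-based positions, CIGAR with M/N only),
#'   `counts` (named read-pair counts per transcript), `sample`,
#'   `read_length`.
#' @export
#' @examples
#' cfg <- generator_config(n_transcripts = 10, n_read_pairs = 200, seed = 5)
#' txome <- generate_transcriptome(cfg)
#' reads <- simulate_reads(txome, cfg, "lysate")
#' head(reads$transcript)
simulate_reads <- function(txome, config,
                           sample_label = c("lysate", "eluate"),
                           seed = config$seed,
                           n_pairs = config$n_read_pairs) {
  stopifnot(inherits(txome, "mrnp_transcriptome"),
            inherits(config, "mrnp_generator_config"))
  sample_label <- match.arg(sample_label)
  tx <- txome$transcripts
  n <- nrow(tx)

  # shared baseline: depends on config$seed only
  set.seed(sub_seed(config$seed, "abundance-baseline"))
  base_log <- rnorm(n, 0, 1)

  log_ab <- base_log + log(tx$length) # longer molecules shed more fragments
  if (sample_label == "eluate") {
    ec <- config$enrichment_coefficients
    z_hl <- as.numeric(scale(log(tx$half_life_min)))
    z_len <- as.numeric(scale(log(tx$length)))
    if (any(is.nan(z_hl))) z_hl[] <- 0
    if (any(is.nan(z_len))) z_len[] <- 0
    log_ab <- log_ab + ec[["beta_halflife"]] * z_hl + ec[["beta_length"]] * z_len
    mito <- tx$genome == "mito"
    log_ab[mito] <- log_ab[mito] + log(max(config$mito_depletion_factor, 1e-12))
  }
  p <- exp(log_ab - max(log_ab))
  p <- p / sum(p)

  set.seed(sub_seed(seed, paste0("reads-", sample_label)))
  counts <- rpois(n, n_pairs * p)
  total <- sum(counts)
  rl <- config$read_length

  if (total == 0) {
    empty <- tibble::tibble(qname = character(), mate = integer(),
                            rname = character(), start = integer(),
                            end = integer(), cigar = character(),
                            strand = character())
    gempty <- tibble::tibble(qname = character(), mate = integer(),
                             chrom = character(), pos = integer(),
                             end = integer(), cigar = character(),
                             strand = character(), transcript_id = character())
    return(structure(list(transcript = empty, genome = gempty,
                          counts = setNames(counts, tx$transcript_id),
                          sample = sample_label, read_length = rl),
                     class = "mrnp_reads"))
  }

  idx <- rep.int(seq_len(n), counts)
  L <- tx$length[idx]

  trunc <- runif(total) < config$nascent_truncation_fraction
  tpoint <- pmax(1L, as.integer(ceiling(runif(total) * L)))
  M <- ifelse(trunc, tpoint, L)

  ins <- as.integer(round(rnorm(total, config$insert_size[["mean"]],
                                config$insert_size[["sd"]])))
  ins <- pmin(pmax(ins, 1L), M)
  s <- 1L + as.integer(floor(runif(total) * (M - ins + 1L)))
  rlen <- pmin(rl, ins)

  a1 <- s; b1 <- s + rlen - 1L
  b2 <- s + ins - 1L; a2 <- b2 - rlen + 1L

  qname <- sprintf("%s.%07d", sample_label, seq_len(total))
  tx_tbl <- tibble::tibble(
    qname = rep(qname, 2L),
    mate = rep(c(1L, 2L), each = total),
    rname = rep(tx$transcript_id[idx], 2L),
    start = c(a1, a2),
    end = c(b1, b2),
    cigar = sprintf("%dM", rep(rlen, 2L)),
    strand = rep(c("+", "-"), each = total)
  )

  # genome-coordinate projection
  gi <- rep(idx, 2L)
  a <- tx_tbl$start; b <- tx_tbl$end
  j <- tx$junction[gi]
  ilen <- tx$intron_length[gi]
  ts <- tx$tx_start[gi]
  spans <- !is.na(j) & a <= j & b > j
  after <- !is.na(j) & a > j

  gpos <- ts + a - 1L
  gpos[after] <- gpos[after] + ilen[after]
  cig <- tx_tbl$cigar
  gend <- gpos + (b - a)

  if (any(spans)) {
    unspl <- spans & (runif(2L * total) < config$retention_rate)
    spl <- spans & !unspl
    if (any(spl)) {
      x <- j[spl] - a[spl] + 1L
      y <- b[spl] - j[spl]
      cig[spl] <- sprintf("%dM%dN%dM", x, ilen[spl], y)
      gend[spl] <- gpos[spl] + x + ilen[spl] + y - 1L
    }
    if (any(unspl)) {
      len <- b[unspl] - a[unspl] + 1L
      anchor3 <- runif(sum(unspl)) < 0.5
      w <- which(unspl)
      # 5'-anchored: start unchanged, contiguous M into the intron
      gend[w] <- gpos[w] + len - 1L
      # 3'-anchored: contiguous M ending at the genomic position of b
      w3 <- w[anchor3]
      if (length(w3)) {
        ge <- ts[w3] + b[w3] - 1L + ilen[w3]
        gpos[w3] <- ge - len[anchor3] + 1L
        gend[w3] <- ge
      }
      cig[unspl] <- sprintf("%dM", len)
    }
  }

  g_tbl <- tibble::tibble(
    qname = tx_tbl$qname,
    mate = tx_tbl$mate,
    chrom = tx$chrom[gi],
    pos = gpos,
    end = gend,
    cigar = cig,
    strand = tx_tbl$strand,
    transcript_id = tx$transcript_id[gi]
  )

  structure(list(transcript = tx_tbl, genome = g_tbl,
                 counts = setNames(counts, tx$transcript_id),
                 sample = sample_label, read_length = rl),
            class = "mrnp_reads")
}

#' @export
print.mrnp_reads <- function(x, ...) {
  cat(sprintf("mrnp_reads: %s, %d read pairs over %d transcripts\n",
              x$sample, sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Count read pairs per transcript
#'
#' A read pair counts once for a transcript if either mate aligns to it; in
#' the simulator every pair derives from exactly one transcript, and for SAM
#' input distinct pair names per reference are counted.
#'
#' @param x An `mrnp_reads` object, or a `GAlignments` in transcript
#'   coordinates with read names.
#' @param transcript_ids Optional transcript universe; absent transcripts
#'   get count 0.
#' @return Named integer vector of pair counts.
#' @export
count_read_pairs <- function(x, transcript_ids = NULL) {
  if (inherits(x, "mrnp_reads")) {
    counts <- x$counts
  } else if (inherits(x, "GAlignments")) {
    qn <- names(x)
    if (is.null(qn)) stop("alignments must carry read names", call. = FALSE)
    rn <- as.character(GenomicAlignments::seqnames(x))
    key <- !duplicated(paste(qn, rn))
    tab <- table(rn[key])
    counts <- setNames(as.integer(tab), names(tab))
  } else {
    stop("unsupported input for count_read_pairs", call. = FALSE)
  }
  if (!is.null(transcript_ids)) {
    out <- setNames(integer(length(transcript_ids)), transcript_ids)
    out[intersect(names(counts), transcript_ids)] <-
      counts[intersect(names(counts), transcript_ids)]
    counts <- out
  }
  counts
}

#' Convert simulated reads to a GAlignments object
#'
#' @param reads An `mrnp_reads` object.
#' @param txome The `mrnp_transcriptome` the reads were simulated from
#'   (provides reference lengths).
#' @param mode `"transcript"` or `"genome"` coordinates.
#' @return A `GenomicAlignments::GAlignments` named by read (pair) name.
#' @export
as_galignments <- function(reads, txome, mode = c("transcript", "genome")) {
  mode <- match.arg(mode)
  tbl <- reads[[mode]]
  if (mode == "transcript") {
    seqlen <- setNames(txome$transcripts$length, txome$transcripts$transcript_id)
    sq <- tbl$rname
  } else {
    seqlen <- setNames(Biostrings::width(txome$genome), names(txome$genome))
    sq <- tbl$chrom
  }
  GenomicAlignments::GAlignments(
    seqnames = factor(sq, levels = names(seqlen)),
    pos = as.integer(if ("pos" %in% names(tbl)) tbl$pos else tbl$start),
    cigar = tbl$cigar,
    strand = factor(tbl$strand, levels = c("+", "-", "*")),
    names = tbl$qname,
    seqlengths = seqlen
  )
}
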