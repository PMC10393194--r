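#' Construct a substrate/probe pair for the annealing assay
#'
#' Emulates the assay design: a random RNA substrate and a probe carrying a
#' perfectly complementary core (the reverse complement of a window of the
#' substrate) flanked on both sides by non-pairing extensions. Flank bases
#' are verified base-by-base against the substrate at the annealed
#' register: wherever the register extends past the core, a flank base that
#' would pair Watson-Crick with the substrate is replaced.
#'
#' @param substrate_len Substrate length in nt (assay design: 315).
#' @param core_len Perfectly complementary core length (assay design: 60).
#' @param flank_len Non-pairing flank length on each side (assay design:
#'   10), so the probe is `core_len + 2 * flank_len` nt.
#' @param seed Integer seed.
#' @return List with `substrate`, `probe` (RNA character strings,
#'   5' to 3'), `core_start` (1-based start of the complementary window on
#'   the substrate) and `core_len`.
#' @export
#' @examples
#' pair <- make_annealing_pair(315, 60, 10, seed = 1)
#' nchar(pair$probe) # 80
make_annealing_pair <- function(substrate_len, core_len, flank_len = 0L,
                                seed = 1L) {
  if (core_len > substrate_len) {
    stop("core_len exceeds substrate_len", call. = FALSE)
  }
  stopifnot(core_len >= 1, flank_len >= 0)
  set.seed(sub_seed(seed, "annealing-pair"))
  substrate <- random_rna(substrate_len)
  core_start <- 1L + as.integer(floor(runif(1) * (substrate_len - core_len + 1L)))
  core <- substr(substrate, core_start, core_start + core_len - 1L)
  probe_core <- rna_revcomp(core)

  comp <- c(A = "U", C = "G", G = "C", U = "A")
  nonpairing_flank <- function(n, sub_positions) {
    # sub_positions: substrate coordinates each flank base would face at the
    # annealed register (NA when off the substrate end)
    vapply(seq_len(n), function(i) {
      pos <- sub_positions[i]
      forbidden <- if (!is.na(pos) && pos >= 1 && pos <= substrate_len) {
        comp[[substr(substrate, pos, pos)]]
      } else NA_character_
      pick <- sample(c("A", "C", "G", "U"), 1)
      while (!is.na(forbidden) && pick == forbidden) {
        pick <- sample(c("A", "C", "G", "U"), 1)
      }
      pick
    }, character(1))
  }
  # probe is antiparallel: its 5' flank faces substrate positions just 3' of
  # the core; its 3' flank faces positions just 5' of the core
  five_faces <- (core_start + core_len - 1L) + rev(seq_len(flank_len))
  three_faces <- core_start - seq_len(flank_len)
  five_faces[five_faces > substrate_len] <- NA_integer_
  three_faces[three_faces < 1L] <- NA_integer_

  probe <- paste0(paste(nonpairing_flank(flank_len, five_faces), collapse = ""),
                  probe_core,
                  paste(nonpairing_flank(flank_len, three_faces), collapse = ""))
  list(substrate = substrate, probe = probe,
       core_start = core_start, core_len = as.integer(core_len))
}

#' Find annealed duplex regions between two RNAs
#'
#' Enumerates all maximal exact antiparallel Watson-Crick matches of length
#' at least `min_duplex` between the two molecules (no G-U wobble, no
#' thermodynamics), then greedily selects a non-overlapping set by
#' descending length, ties broken by leftmost substrate coordinate.
#'
#' @param substrate,probe RNA character strings (ACGU, 5' to 3').
#' @param min_duplex Minimum duplex length in nt (default 15; suppresses
#'   spurious short matches in random flanks).
#' @return Tibble of duplex regions: `sub_start`, `sub_end`, `probe_start`,
#'   `probe_end` (1-based inclusive), `length`.
#' @export
anneal <- function(substrate, probe, min_duplex = 15L) {
  if (min_duplex < 1) stop("min_duplex must be >= 1", call. = FALSE)
  check_rna <- function(x, name) {
    if (!nzchar(x) || grepl("[^ACGU]", x)) {
      stop(sprintf("%s must be a nonempty ACGU string", name), call. = FALSE)
    }
  }
  check_rna(substrate, "substrate"); check_rna(probe, "probe")

  rp <- rna_revcomp(probe) # match substrate against revcomp(probe)
  s <- strsplit(substrate, "")[[1]]
  q <- strsplit(rp, "")[[1]]
  n <- length(s); m <- length(q)

  hits <- list()
  # diagonal run-length scan over all alignment offsets
  for (d in (-(m - 1)):(n - 1)) {
    i0 <- max(1L, 1L + d)          # substrate start on this diagonal
    j0 <- i0 - d                   # matching revcomp(probe) position
    len <- min(n - i0, m - j0) + 1L
    if (len < min_duplex) next
    eq <- s[i0:(i0 + len - 1L)] == q[j0:(j0 + len - 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_duplex
    for (k in which(keep)) {
      si <- i0 + starts[k] - 1L
      qi <- j0 + starts[k] - 1L
      l <- r$lengths[k]
      hits[[length(hits) + 1L]] <- c(sub_start = si, sub_end = si + l - 1L,
                                     q_start = qi, q_end = qi + l - 1L,
                                     length = l)
    }
  }
  empty <- tibble::tibble(sub_start = integer(), sub_end = integer(),
                          probe_start = integer(), probe_end = integer(),
                          length = integer())
  if (!length(hits)) return(empty)
  h <- tibble::as_tibble(do.call(rbind, hits))
  # map revcomp(probe) coordinates back to probe coordinates (antiparallel)
  h$probe_start <- m - h$q_end + 1L
  h$probe_end <- m - h$q_start + 1L
  h <- h[order(-h$length, h$sub_start), ]

  taken_sub <- logical(nchar(substrate))
  taken_probe <- logical(nchar(probe))
  sel <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    si <- h$sub_start[i]:h$sub_end[i]
    pi <- h$probe_start[i]:h$probe_end[i]
    if (!any(taken_sub[si]) && !any(taken_probe[pi])) {
      sel[i] <- TRUE
      taken_sub[si] <- TRUE
      taken_probe[pi] <- TRUE
    }
  }
  out <- h[sel, c("sub_start", "sub_end", "probe_start", "probe_end", "length")]
  out[order(out$sub_start), ]
}

#' In-silico RNase T1 digestion of annealed molecules
#'
#' In `idealized` mode every unpaired nucleotide is removed, so the
#' protected fragments are exactly the duplexed intervals of each molecule.
#' In `g_specific` mode the enzyme cleaves only 3' of unpaired G residues;
#' fragments containing at least one paired position survive and may carry
#' single-stranded overhangs extending to the nearest unpaired G (fully
#' unpaired fragments are treated as degraded).
#'
#' @param molecules Named character vector of RNA sequences (e.g.
#'   `c(substrate = ..., probe = ...)`).
#' @param duplexes Duplex tibble from [anneal()]; `sub_*` intervals refer to
#'   the first molecule, `probe_*` to the second.
#' @param mode `"idealized"` (default) or `"g_specific"`.
#' @return Tibble of protected fragments: `molecule`, `start`, `end`,
#'   `length`.
#' @export
rnase_t1_digest <- function(molecules, duplexes,
                            mode = c("idealized", "g_specific")) {
  mode <- match.arg(mode)
  stopifnot(is.character(molecules), length(molecules) >= 1,
            !is.null(names(molecules)))
  ivl_for <- function(which_mol) {
    if (is.null(duplexes) || nrow(duplexes) == 0) {
      return(IRanges::IRanges())
    }
    if (which_mol == 1L) {
      IRanges::IRanges(duplexes$sub_start, duplexes$sub_end)
    } else {
      IRanges::IRanges(duplexes$probe_start, duplexes$probe_end)
    }
  }
  frags <- lapply(seq_along(molecules), function(mi) {
    if (mi > 2) stop("duplexes describe at most two molecules", call. = FALSE)
    seq_ <- molecules[[mi]]
    L <- nchar(seq_)
    paired <- IRanges::reduce(ivl_for(mi))
    if (length(paired) && max(IRanges::end(paired)) > L) {
      stop("duplex outside molecule bounds", call. = FALSE)
    }
    if (mode == "idealized") {
      if (!length(paired)) return(NULL)
      return(tibble::tibble(molecule = names(molecules)[mi],
                            start = IRanges::start(paired),
                            end = IRanges::end(paired),
                            length = IRanges::width(paired)))
    }
    # g_specific: cut 3' of each unpaired G
    is_paired <- logical(L)
    for (k in seq_along(paired)) {
      is_paired[IRanges::start(paired)[k]:IRanges::end(paired)[k]] <- TRUE
    }
    bases <- strsplit(seq_, "")[[1]]
    cuts <- which(bases == "G" & !is_paired)
    cuts <- cuts[cuts < L]
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    keep <- vapply(seq_along(starts),
                   function(k) any(is_paired[starts[k]:ends[k]]), logical(1))
    if (!any(keep)) return(NULL)
    tibble::tibble(molecule = names(molecules)[mi],
                   start = starts[keep], end = ends[keep],
                   length = ends[keep] - starts[keep] + 1L)
  })
  out <- dplyr::bind_rows(frags)
  if (nrow(out) == 0) {
    out <- tibble::tibble(molecule = character(), start = integer(),
                          end = integer(), length = integer())
  }
  out
}

#' Run the in-silico annealing / RNase protection assay
#'
#' Models the gel readout: when annealing is active (annealing-competent
#' protein present) the substrate and probe are annealed and digested;
#' when inactive, digestion proceeds with no duplexes and the lanes are
#' empty. Lanes report fragment lengths sorted descending, per molecule.
#'
#' @param substrate RNA character string; the lane is empty when `probe` is
#'   `NULL` (nothing to pair with).
#' @param probe Optional RNA character string.
#' @param annealing_active Logical switch for the annealing activity.
#' @param min_duplex Passed to [anneal()].
#' @param mode Passed to [rnase_t1_digest()].
#' @return List with `lanes` (named list of descending fragment lengths per
#'   molecule), `duplexes`, `fragments`.
#' @export
#' @examples
#' pair <- make_annealing_pair(315, 60, 10, seed = 2)
#' annealing_assay(pair$substrate, pair$probe)$lanes$substrate # 60
annealing_assay <- function(substrate, probe = NULL, annealing_active = TRUE,
                            min_duplex = 15L,
                            mode = c("idealized", "g_specific")) {
  mode <- match.arg(mode)
  molecules <- c(substrate = substrate)
  if (!is.null(probe)) molecules <- c(molecules, probe = probe)
  duplexes <- if (annealing_active && !is.null(probe)) {
    anneal(substrate, probe, min_duplex)
  } else {
    NULL
  }
  fragments <- rnase_t1_digest(molecules, duplexes, mode)
  lanes <- lapply(names(molecules), function(mol) {
    sort(fragments$length[fragments$molecule == mol], decreasing = TRUE)
  })
  names(lanes) <- names(molecules)
  list(lanes = lanes, duplexes = duplexes, fragments = fragments)
}
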