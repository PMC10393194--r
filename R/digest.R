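#' In-silico protease digestion
#'
#' Cleavage rules: LysC cuts C-terminal to lysine (K); Trypsin/P cuts
#' C-terminal to lysine or arginine (K/R), including before proline.
#' Peptides are reported for 0 up to `missed_cleavages` missed sites, with
#' 1-based inclusive positions on the protein.
#'
#' @param sequence Amino-acid string (standard 20-letter alphabet, `X`
#'   tolerated).
#' @param protease `"LysC"` or `"TrypsinP"`.
#' @param missed_cleavages Maximum number of missed cleavage sites
#'   (default 0).
#' @return A tibble: `peptide`, `start`, `end`, `n_missed`.
#' @export
#' @examples
#' digest_protein("ACKDEFKGH", "LysC")$peptide
#' digest_protein("MKRPG", "TrypsinP")$peptide # cleaves R-P too
digest_protein <- function(sequence, protease = c("LysC", "TrypsinP"),
                           missed_cleavages = 0L) {
  protease <- match.arg(protease)
  stopifnot(missed_cleavages >= 0)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% c(AA_ALPHABET20, "X"))) {
    stop("sequence contains non-amino-acid characters", call. = FALSE)
  }
  L <- length(aa)
  targets <- if (protease == "LysC") "K" else c("K", "R")
  cut_after <- which(aa %in% targets)
  cut_after <- cut_after[cut_after < L] # no cut after the last residue

  # fully cleaved segment boundaries
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, L)
  nseg <- length(starts)

  recs <- list()
  for (m in 0:missed_cleavages) {
    i <- seq_len(max(0L, nseg - m))
    if (!length(i)) break
    recs[[m + 1L]] <- tibble::tibble(
      start = starts[i], end = ends[i + m], n_missed = m
    )
  }
  out <- dplyr::bind_rows(recs)
  out$peptide <- substring(sequence, out$start, out$end)
  out[, c("peptide", "start", "end", "n_missed")]
}

#' Count theoretically observable peptides
#'
#' Number of fully cleaved (zero missed cleavages) peptides whose length
#' falls within `length_range` (inclusive) — the iBAQ denominator. A floor
#' of 1 is applied when no peptide qualifies, so short or cleavage-poor
#' proteins never divide by zero.
#'
#' @inheritParams digest_protein
#' @param length_range Inclusive peptide-length bounds in residues
#'   (default `c(7, 30)`).
#' @return Integer count (>= 1).
#' @export
count_observable_peptides <- function(sequence, protease = c("LysC", "TrypsinP"),
                                      length_range = c(7L, 30L)) {
  protease <- match.arg(protease)
  pep <- digest_protein(sequence, protease, missed_cleavages = 0L)
  len <- pep$end - pep$start + 1L
  n <- sum(len >= length_range[1] & len <= length_range[2])
  max(n, 1L)
}

# average residue masses (Da); X excluded from mass computation
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.01524

#' Theoretical protein molecular weight
#'
#' Sum of average residue masses plus one water, in Daltons. `X` residues
#' are tolerated and excluded from the sum.
#'
#' @param sequence Amino-acid string.
#' @return Molecular weight in Da.
#' @export
protein_mw <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  aa <- aa[aa != "X"]
  if (!all(aa %in% names(AA_AVG_MASS))) {
    stop("sequence contains non-amino-acid characters", call. = FALSE)
  }
  sum(AA_AVG_MASS[aa]) + WATER_AVG_MASS
}
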