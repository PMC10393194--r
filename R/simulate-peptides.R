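#' Specification of a synthetic protein stoichiometry experiment
#'
#' Describes the proteins, their per-condition copy-number weights, the
#' replicate structure and the intensity noise used by
#' [simulate_peptides()].
#'
#' @param proteins Named character vector of protein sequences.
#' @param weights Numeric matrix (proteins x conditions) of copy-number
#'   weights, rownames matching `names(proteins)`; all weights >= 0.
#' @param n_replicates Replicates per condition (default 3, the study's
#'   mass-spectrometry design).
#' @param intensity_noise_sd Log-scale (natural log) standard deviation of
#'   the replicate-level intensity noise.
#' @param protease Protease generating the observable peptides
#'   (default `"LysC"`).
#' @param length_range Observable-peptide length bounds.
#' @return A list of class `mrnp_stoichiometry_spec`.
#' @export
stoichiometry_spec <- function(proteins, weights, n_replicates = 3L,
                               intensity_noise_sd = 0.1,
                               protease = "LysC",
                               length_range = c(7L, 30L)) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) rownames(weights) <- names(proteins)
  if (!setequal(rownames(weights), names(proteins))) {
    stop("weights rownames must match protein names", call. = FALSE)
  }
  if (any(weights < 0)) stop("copy-number weights must be >= 0", call. = FALSE)
  if (is.null(colnames(weights))) {
    stop("weights must have condition column names", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(proteins = proteins,
                 weights = weights[names(proteins), , drop = FALSE],
                 conditions = colnames(weights),
                 n_replicates = as.integer(n_replicates),
                 intensity_noise_sd = intensity_noise_sd,
                 protease = protease,
                 length_range = length_range),
            class = "mrnp_stoichiometry_spec")
}

#' Default stoichiometry spec emulating the purified-particle proteome
#'
#' Random protein sequences with natural amino-acid composition stand in
#' for the real proteins; classes and weights emulate the study's
#' qualitative picture: five THO-like components at unit stoichiometry, a
#' Sub2-like helicase, an overstoichiometric Yra1-like export adaptor (10x
#' in the intact eluate, reduced after nuclease treatment), plus
#' cap-binding and tail-binding proteins. Conditions are `eluate`,
#' `flowthrough`, `benzonase_eluate`, `benzonase_flowthrough`.
#'
#' @param seed Seed for the random protein sequences.
#' @param yra1_weight Copy-number weight of the Yra1-like protein in the
#'   intact eluate (default 10).
#' @return A list with `spec` (an `mrnp_stoichiometry_spec`) and `classes`
#'   (named class map for [stoichiometry_report()]).
#' @export
default_stoichiometry_spec <- function(seed = 1L, yra1_weight = 10) {
  set.seed(sub_seed(seed, "default-proteome"))
  defs <- tibble::tibble(
    protein = c("THO1", "THO2", "THO3", "THO4", "THO5",
                "SUB2L", "YRA1L", "CBP1", "CBP2", "PAB1L", "NAB2L"),
    class = c(rep("THO", 5), "Sub2-like", "Yra1-like",
              "cap-binding", "cap-binding", "tail-binding", "tail-binding"),
    length = c(1200, 900, 450, 400, 300, 450, 220, 800, 200, 580, 520)
  )
  proteins <- setNames(vapply(defs$length, random_protein, character(1)),
                       defs$protein)
  w_el <- ifelse(defs$class == "Yra1-like", yra1_weight, 1)
  w_ft <- ifelse(defs$class %in% c("Yra1-like", "Sub2-like"), 3, 0.2)
  w_bel <- ifelse(defs$class == "Yra1-like", yra1_weight / 5, 1)
  w_bft <- ifelse(defs$class %in% c("Yra1-like", "Sub2-like"), 4, 0.2)
  weights <- cbind(eluate = w_el, flowthrough = w_ft,
                   benzonase_eluate = w_bel, benzonase_flowthrough = w_bft)
  rownames(weights) <- defs$protein
  list(spec = stoichiometry_spec(proteins, weights),
       classes = setNames(defs$class, defs$protein))
}

#' Simulate a peptide-intensity table
#'
#' Peptides are the observable peptides of each protein's in-silico digest
#' (fully cleaved, length within the spec's bounds). Each peptide carries a
#' fixed log-normal detectability (shared across conditions and
#' replicates); the reported intensity is
#' `copy-number weight x detectability x exp(N(0, noise_sd))`, scaled to a
#' mass-spectrometry-like magnitude. Proteins with weight 0 in a condition
#' produce no rows for that condition.
#'
#' @param spec An `mrnp_stoichiometry_spec`.
#' @param seed Integer seed.
#' @return Tibble with `protein`, `peptide_seq`, `replicate`, `condition`,
#'   `intensity`.
#' @export
simulate_peptides <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mrnp_stoichiometry_spec"))
  if (length(spec$proteins) == 0) stop("empty protein list", call. = FALSE)

  peps <- lapply(names(spec$proteins), function(p) {
    d <- digest_protein(spec$proteins[[p]], spec$protease, 0L)
    len <- d$end - d$start + 1L
    d <- d[len >= spec$length_range[1] & len <= spec$length_range[2], ]
    if (nrow(d) == 0) return(NULL)
    tibble::tibble(protein = p, peptide_seq = d$peptide)
  })
  peps <- dplyr::bind_rows(peps)

  set.seed(sub_seed(seed, "peptide-detectability"))
  peps$detectability <- exp(rnorm(nrow(peps), 0, 0.5))

  set.seed(sub_seed(seed, "peptide-noise"))
  rows <- list()
  for (cond in spec$conditions) {
    w <- spec$weights[, cond]
    present <- peps[w[peps$protein] > 0, , drop = FALSE]
    if (nrow(present) == 0) next
    for (rep_i in seq_len(spec$n_replicates)) {
      noise <- exp(rnorm(nrow(present), 0, spec$intensity_noise_sd))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein = present$protein,
        peptide_seq = present$peptide_seq,
        replicate = rep_i,
        condition = cond,
        intensity = 1e6 * w[present$protein] * present$detectability * noise
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(protein = character(), peptide_seq = character(),
                          replicate = integer(), condition = character(),
                          intensity = numeric()))
  }
  dplyr::bind_rows(rows)
}
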