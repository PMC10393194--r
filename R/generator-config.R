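#' Configuration for the synthetic mRNP data generator
#'
#' Bundles every tunable of the RNA-side simulator: transcriptome geometry,
#' the abundance model that differentiates eluate from lysate, the nascent
#' 5'-bias model, intron-retention rate and read geometry. All generators are
#' pure functions of (config, seed): identical inputs give byte-identical
#' outputs.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param length_distribution Numeric triple `(min_nt, max_nt, shape)`.
#'   Mature transcript lengths are drawn as
#'   `round(min + (max - min) * u^shape)` with `u ~ U(0,1)`; `shape > 1`
#'   skews the distribution toward short transcripts, as in a real
#'   transcriptome.
#' @param intron_fraction Fraction of transcripts carrying exactly one
#'   intron. The simulated count is `round(intron_fraction * n_transcripts)`
#'   (membership is random, the count is deterministic).
#' @param mito_fraction Fraction of transcripts flagged as
#'   mitochondrial-encoded; count deterministic as for `intron_fraction`.
#' @param halflife_range mRNA half-life range in minutes `(min, max)`;
#'   half-lives are drawn log-uniformly over this range.
#' @param read_length Nucleotides per mate (default 75, paired-end).
#' @param insert_size Mean and standard deviation of the fragment
#'   (insert) length in nt; fragments are clipped at molecule ends.
#' @param nascent_truncation_fraction Fraction of source molecules truncated
#'   at a uniform random 3' point, the nascent-transcription proxy that
#'   produces 5'-biased coverage.
#' @param retention_rate Probability that a junction-spanning read is emitted
#'   unspliced (contiguous alignment running into the intron) rather than
#'   split (gap exactly spanning the intron).
#' @param enrichment_coefficients `(beta_halflife, beta_length)` acting on
#'   the eluate log-abundance: `beta_halflife * z(log half-life) +
#'   beta_length * z(log length)`. `beta_halflife` must be <= 0 and
#'   `beta_length` >= 0, the directions the purification exhibits.
#' @param mito_depletion_factor Multiplicative depletion of mitochondrial
#'   transcripts in the eluate.
#' @param n_read_pairs Library depth per sample in read pairs.
#' @param seed Integer seed controlling the transcriptome and the shared
#'   baseline abundances.
#'
#' @return A list of class `mrnp_generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_transcripts = 50, seed = 1)
#' cfg$read_length
generator_config <- function(n_transcripts = 500L,
                             length_distribution = c(min_nt = 200, max_nt = 4000, shape = 2),
                             intron_fraction = 0.1,
                             mito_fraction = 0.05,
                             halflife_range = c(min_min = 3, max_min = 100),
                             read_length = 75L,
                             insert_size = c(mean = 200, sd = 20),
                             nascent_truncation_fraction = 0.3,
                             retention_rate = 0.1,
                             enrichment_coefficients = c(beta_halflife = -0.5, beta_length = 0.5),
                             mito_depletion_factor = 0.05,
                             n_read_pairs = 1e6,
                             seed = 1L) {
  stopifnot(n_transcripts >= 1, length(length_distribution) == 3)
  ld <- unname(length_distribution)
  if (ld[1] > ld[2]) stop("length range degenerate: min_nt > max_nt", call. = FALSE)
  if (ld[1] < 1 || ld[3] <= 0) stop("invalid length_distribution", call. = FALSE)
  check_fraction(intron_fraction, "intron_fraction")
  check_fraction(mito_fraction, "mito_fraction")
  check_fraction(nascent_truncation_fraction, "nascent_truncation_fraction")
  check_fraction(retention_rate, "retention_rate")
  hl <- unname(halflife_range)
  if (length(hl) != 2 || hl[1] <= 0 || hl[1] > hl[2]) {
    stop("invalid halflife_range", call. = FALSE)
  }
  if (read_length < 1) stop("read_length must be >= 1", call. = FALSE)
  ec <- unname(enrichment_coefficients)
  if (length(ec) != 2 || ec[1] > 0 || ec[2] < 0) {
    stop("enrichment_coefficients must satisfy beta_halflife <= 0, beta_length >= 0",
         call. = FALSE)
  }
  if (mito_depletion_factor < 0) stop("mito_depletion_factor must be >= 0", call. = FALSE)
  if (n_read_pairs < 1) stop("n_read_pairs must be >= 1", call. = FALSE)

  structure(list(
    n_transcripts = as.integer(n_transcripts),
    length_distribution = c(min_nt = ld[1], max_nt = ld[2], shape = ld[3]),
    intron_fraction = intron_fraction,
    mito_fraction = mito_fraction,
    halflife_range = c(min_min = hl[1], max_min = hl[2]),
    read_length = as.integer(read_length),
    insert_size = c(mean = unname(insert_size[1]), sd = unname(insert_size[2])),
    nascent_truncation_fraction = nascent_truncation_fraction,
    retention_rate = retention_rate,
    enrichment_coefficients = c(beta_halflife = ec[1], beta_length = ec[2]),
    mito_depletion_factor = mito_depletion_factor,
    n_read_pairs = n_read_pairs,
    seed = as.integer(seed)
  ), class = "mrnp_generator_config")
}
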