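#' Eluate/lysate enrichment with median-of-ratios normalization
#'
#' Size factors follow the median-of-ratios scheme: a pseudo-reference is
#' the per-transcript geometric mean across the two samples (transcripts
#' with a zero count in any sample are excluded from factor estimation),
#' and each sample's factor is the median of its counts over the reference.
#' The log2 fold change is computed on normalized counts with a pseudocount:
#' `log2((eluate/sf_e + c) / (lysate/sf_l + c))`.
#'
#' @param lysate_counts,eluate_counts Named integer vectors of read(-pair)
#'   counts over a shared transcript set.
#' @param pseudocount Pseudocount `c` (default 0.5).
#' @return A tibble with `transcript_id`, `lysate_count`, `eluate_count`,
#'   `log2fc`; size factors are attached as the `size_factors` attribute
#'   (named `lysate`, `eluate`).
#' @export
#' @examples
#' l <- c(a = 100L, b = 50L, c = 10L)
#' e <- c(a = 200L, b = 100L, c = 20L)
#' enrichment_table(l, e) # doubling is absorbed by the size factors
enrichment_table <- function(lysate_counts, eluate_counts, pseudocount = 0.5) {
  ids <- intersect(names(lysate_counts), names(eluate_counts))
  if (length(ids) == 0) stop("no shared transcripts", call. = FALSE)
  l <- as.numeric(lysate_counts[ids])
  e <- as.numeric(eluate_counts[ids])
  if (all(l == 0) || all(e == 0)) {
    stop("a sample has all-zero counts", call. = FALSE)
  }
  pos <- l > 0 & e > 0
  if (!any(pos)) stop("no transcript has nonzero counts in both samples", call. = FALSE)
  ref <- sqrt(l[pos] * e[pos]) # geometric mean of the two samples
  sf <- c(lysate = median(l[pos] / ref), eluate = median(e[pos] / ref))
  if (any(sf <= 0)) stop("nonpositive size factor", call. = FALSE)

  log2fc <- log2((e / sf[["eluate"]] + pseudocount) /
                   (l / sf[["lysate"]] + pseudocount))
  out <- tibble::tibble(transcript_id = ids, lysate_count = l,
                        eluate_count = e, log2fc = log2fc)
  attr(out, "size_factors") <- sf
  out
}

#' Spearman correlation of enrichment against a covariate
#'
#' Rank correlation (average ranks for ties) of per-transcript log2 fold
#' change against mRNA half-life or transcript length, over transcripts
#' present in both inputs with a non-missing covariate.
#'
#' @param records Tibble from [enrichment_table()].
#' @param covariate Named numeric vector (e.g. half-life in minutes, or
#'   length in nt) keyed by transcript id.
#' @param label Covariate label carried into the result.
#' @return List with `rho`, `p_value`, `n`, `covariate`.
#' @export
correlate_enrichment <- function(records, covariate, label = "covariate") {
  ids <- intersect(records$transcript_id, names(covariate)[!is.na(covariate)])
  if (length(ids) < 3) stop("need >= 3 transcripts with covariate", call. = FALSE)
  x <- records$log2fc[match(ids, records$transcript_id)]
  y <- as.numeric(covariate[ids])
  if (length(unique(y)) == 1L) stop("constant covariate", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(ids), covariate = label)
}
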