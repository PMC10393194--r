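# shared fixtures and independent oracles (kept deliberately naive)

# build a GAlignments directly from (rname, pos, cigar) triples
make_gal <- function(rname, pos, cigar, seqlengths, qname = NULL) {
  GenomicAlignments::GAlignments(
    seqnames = factor(rname, levels = names(seqlengths)),
    pos = as.integer(pos),
    cigar = cigar,
    strand = factor(rep("+", length(pos)), levels = c("+", "-", "*")),
    names = qname,
    seqlengths = seqlengths
  )
}

# brute-force per-position coverage: walk every read's CIGAR and count
# M-covered positions one by one
brute_coverage <- function(pos, cigar, len) {
  depth <- integer(len)
  for (i in seq_along(pos)) {
    p <- pos[i]
    ops <- GenomicAlignments::explodeCigarOps(cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[i])[[1]]
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        for (q in p:(p + lens[k] - 1L)) {
          if (q >= 1 && q <= len) depth[q] <- depth[q] + 1L
        }
      }
      if (ops[k] %in% c("M", "=", "X", "N", "D")) p <- p + lens[k]
    }
  }
  depth
}

# independent digestion oracle: fully cleave, then concatenate every run of
# <= m + 1 adjacent segments
brute_digest <- function(sequence, protease, missed = 0L) {
  aa <- strsplit(sequence, "")[[1]]
  targets <- if (protease == "LysC") "K" else c("K", "R")
  cuts <- which(aa %in% targets)
  cuts <- cuts[cuts < length(aa)]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(aa))
  out <- character(0)
  for (m in 0:missed) {
    for (i in seq_along(starts)) {
      j <- i + m
      if (j > length(ends)) next
      out <- c(out, substr(sequence, starts[i], ends[j]))
    }
  }
  out
}

# row-wise keys that tolerate empty frames (apply() chokes on 0 rows)
row_keys <- function(df, f) {
  if (nrow(df) == 0) character(0) else apply(df, 1, f)
}

random_protein_fixture <- function(n) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

small_txome <- function(seed = 42, n = 30, intron_fraction = 0.3,
                        n_read_pairs = 5000, ...) {
  cfg <- generator_config(n_transcripts = n, intron_fraction = intron_fraction,
                          n_read_pairs = n_read_pairs, seed = seed, ...)
  list(cfg = cfg, txome = generate_transcriptome(cfg))
}
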