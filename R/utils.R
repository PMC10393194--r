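# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rnorm runif rpois median setNames
#' @importFrom utils write.table read.delim
#' @importFrom rlang .data
#' @importFrom methods is
NULL

# deterministic sub-stream seed; stays below 2^31 - 1
sub_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

random_seq <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

random_dna <- function(n) random_seq(n, c("A", "C", "G", "T"))
random_rna <- function(n) random_seq(n, c("A", "C", "G", "U"))

# amino-acid background close to natural composition (K/R present so
# proteases always find sites in realistic-length proteins)
AA_ALPHABET20 <- c("A","R","N","D","C","E","Q","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")
AA_FREQ <- c(8.3, 5.2, 4.1, 5.5, 1.4, 6.8, 3.9, 7.1, 2.2, 6.0,
             9.7, 5.8, 2.4, 3.9, 4.7, 6.6, 5.4, 1.1, 3.1, 6.9)

random_protein <- function(n) random_seq(n, AA_ALPHABET20, prob = AA_FREQ)

rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# min-max scaling with the degenerate rule: constant input maps to all zeros
scale_minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
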