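#' iBAQ quantitation from a peptide-intensity table
#'
#' Intensity-based absolute quantification: per (protein, condition,
#' replicate), summed peptide intensity divided by the number of
#' theoretically observable peptides of that protein (see
#' [count_observable_peptides()]). Proteins absent from a replicate are
#' assigned intensity 0 for that replicate (absent, not unmeasured), so
#' condition means over replicates are comparable across proteins.
#'
#' @param peptides Tibble/data frame with columns `protein`, `peptide_seq`,
#'   `replicate`, `condition`, `intensity`.
#' @param proteins Named character vector (or `AAStringSet`) of protein
#'   sequences covering every protein referenced in `peptides`.
#' @param protease Protease used for the observable-peptide count
#'   (default `"LysC"`).
#' @param length_range Observable-peptide length bounds (default `c(7, 30)`).
#' @return An object of class `mrnp_ibaq`: list with `records` (one row per
#'   protein x condition x replicate: `summed_intensity`,
#'   `observable_peptides`, `ibaq`) and `means` (per protein x condition:
#'   `mean_ibaq`, `mw`).
#' @export
ibaq_table <- function(peptides, proteins, protease = "LysC",
                       length_range = c(7L, 30L)) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  need <- c("protein", "peptide_seq", "replicate", "condition", "intensity")
  if (!all(need %in% names(peptides))) {
    stop("peptide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(peptides$protein), names(proteins))
  if (length(unknown)) {
    stop("peptide rows reference unknown protein(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obs <- vapply(proteins, count_observable_peptides, integer(1),
                protease = protease, length_range = length_range)
  mw <- vapply(proteins, protein_mw, numeric(1))

  conditions <- unique(peptides$condition)
  replicates <- sort(unique(peptides$replicate))
  grid <- expand.grid(protein = names(proteins), condition = conditions,
                      replicate = replicates, stringsAsFactors = FALSE)

  sums <- dplyr::summarise(
    dplyr::group_by(peptides, .data$protein, .data$condition, .data$replicate),
    summed_intensity = sum(.data$intensity), .groups = "drop")
  records <- dplyr::left_join(tibble::as_tibble(grid), sums,
                              by = c("protein", "condition", "replicate"))
  records$summed_intensity[is.na(records$summed_intensity)] <- 0
  records$observable_peptides <- unname(obs[records$protein])
  records$ibaq <- records$summed_intensity / records$observable_peptides

  means <- dplyr::summarise(
    dplyr::group_by(records, .data$protein, .data$condition),
    mean_ibaq = mean(.data$ibaq), .groups = "drop")
  means$mw <- unname(mw[means$protein])

  structure(list(records = tibble::as_tibble(records),
                 means = tibble::as_tibble(means)),
            class = "mrnp_ibaq")
}

#' @export
print.mrnp_ibaq <- function(x, ...) {
  cat(sprintf("mrnp_ibaq: %d proteins x %d conditions\n",
              length(unique(x$means$protein)),
              length(unique(x$means$condition))))
  invisible(x)
}

#' Stoichiometry ratio between protein classes
#'
#' Per condition, the mean of the numerator-class proteins' mean iBAQ
#' values over the mean of the denominator-class proteins' mean iBAQ values
#' — e.g. a Yra1-like over THO-component ratio.
#'
#' @param ibaq An `mrnp_ibaq` from [ibaq_table()].
#' @param classes Named character vector mapping protein id to annotation
#'   class.
#' @param numerator_class,denominator_class Class labels to compare.
#' @return Tibble with `condition` and `ratio`.
#' @export
stoichiometry_report <- function(ibaq, classes, numerator_class,
                                 denominator_class) {
  m <- ibaq$means
  m$class <- unname(classes[m$protein])
  out <- lapply(unique(m$condition), function(cond) {
    sub <- m[m$condition == cond, ]
    num <- sub$mean_ibaq[sub$class %in% numerator_class]
    den <- sub$mean_ibaq[sub$class %in% denominator_class]
    if (!length(num) || !length(den)) {
      stop(sprintf("class missing in condition '%s'", cond), call. = FALSE)
    }
    tibble::tibble(condition = cond, ratio = mean(num) / mean(den))
  })
  dplyr::bind_rows(out)
}
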