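#' Classify cross-links into monolinks, intralinks and interlinks
#'
#' Partition rule: a row with an empty partner side is a monolink; both
#' residues in the same protein is an intralink; different proteins is an
#' interlink. Interlinks are canonicalized to lexicographic protein order
#' (and intralinks to ascending residue order) so A-B and B-A duplicates
#' collapse; identical links are merged with a multiplicity count.
#'
#' @param links Tibble with the cross-link schema: `protein_a`, `residue_a`,
#'   `pep_a_start`, `pep_a_end`, `protein_b`, `residue_b`, `pep_b_start`,
#'   `pep_b_end` (`NA` on the b side for monolinks).
#' @return An object of class `mrnp_xl_classified`: list with `links`
#'   (canonical, deduplicated, with `category` and `multiplicity`) and
#'   `counts` (named: `mono`, `intra`, `inter`).
#' @export
classify_links <- function(links) {
  links <- tibble::as_tibble(links)
  bad <- is.na(links$protein_a) & !is.na(links$residue_a) |
    (!is.na(links$residue_b) & is.na(links$protein_b))
  if (any(is.na(links$protein_a))) {
    stop("row with missing protein_a", call. = FALSE)
  }
  if (any(bad)) stop("row with a residue but no protein", call. = FALSE)

  category <- ifelse(is.na(links$protein_b), "mono",
                     ifelse(links$protein_a == links$protein_b, "intra", "inter"))
  links$category <- category

  swap <- (category == "inter" & links$protein_b < links$protein_a) |
    (category == "intra" & !is.na(links$residue_b) &
       links$residue_b < links$residue_a)
  if (any(swap)) {
    a_cols <- c("protein_a", "residue_a", "pep_a_start", "pep_a_end")
    b_cols <- c("protein_b", "residue_b", "pep_b_start", "pep_b_end")
    tmp <- links[swap, a_cols]
    links[swap, a_cols] <- setNames(links[swap, b_cols], a_cols)
    links[swap, b_cols] <- setNames(tmp, b_cols)
  }

  key <- paste(links$protein_a, links$residue_a, links$protein_b,
               links$residue_b, links$category, sep = "|")
  first <- !duplicated(key)
  out <- links[first, , drop = FALSE]
  out$multiplicity <- as.integer(table(key)[key[first]])

  counts <- c(mono = sum(out$category == "mono"),
              intra = sum(out$category == "intra"),
              inter = sum(out$category == "inter"))
  structure(list(links = out, counts = counts), class = "mrnp_xl_classified")
}

#' @export
print.mrnp_xl_classified <- function(x, ...) {
  cat(sprintf("mrnp_xl_classified: %d intra / %d inter / %d mono\n",
              x$counts[["intra"]], x$counts[["inter"]], x$counts[["mono"]]))
  invisible(x)
}

#' Flag intralinks carrying homo-oligomer evidence (self-links)
#'
#' An intralink is a self-link — evidence that two copies of the same
#' protein are in proximity — when its two residues are identical or its
#' two supporting peptide intervals overlap by at least one residue
#' (closed intervals). The rule is symmetric in the two link sides.
#'
#' @param classified An `mrnp_xl_classified` from [classify_links()], or a
#'   link tibble with a `category` column.
#' @return The link tibble with a logical `self_link` column (`FALSE` for
#'   non-intra rows).
#' @export
detect_self_links <- function(classified) {
  links <- if (inherits(classified, "mrnp_xl_classified")) classified$links
           else tibble::as_tibble(classified)
  is_intra <- links$category == "intra"
  same_res <- is_intra & links$residue_a == links$residue_b
  overlap <- is_intra &
    !is.na(links$pep_a_start) & !is.na(links$pep_b_start) &
    links$pep_a_start <= links$pep_b_end &
    links$pep_b_start <= links$pep_a_end
  links$self_link <- (same_res | overlap) & is_intra
  links$self_link[is.na(links$self_link)] <- FALSE
  links
}

#' Scale per-residue confidence (pLDDT) and annotate link endpoints
#'
#' Each protein's pLDDT profile is min-max scaled to \[0, 1\] (a constant
#' profile scales to all zeros); low scaled values correspond to lighter
#' shades on the circular map, i.e. predicted disorder. Each link endpoint
#' is annotated `structured` when its raw pLDDT is at least `threshold`
#' (default 70), else `disordered`.
#'
#' @param plddt Tibble with columns `protein`, `residue`, `plddt`
#'   (values in \[0, 100\], one row per residue).
#' @param protein_lengths Named integer vector; each profile must cover
#'   exactly the protein length.
#' @param links Optional link tibble (from [detect_self_links()] or
#'   [classify_links()]`$links`) whose endpoints are annotated.
#' @param threshold Structured/disordered pLDDT cutoff (default 70).
#' @return List with `profiles` (tibble: `protein`, `residue`, `plddt`,
#'   `scaled_shade`), `links` (with `end_a_state`/`end_b_state` when links
#'   were supplied) and `endpoint_summary` (counts of structured/disordered
#'   endpoints per link category).
#' @export
disorder_overlay <- function(plddt, protein_lengths, links = NULL,
                             threshold = 70) {
  plddt <- tibble::as_tibble(plddt)
  if (any(plddt$plddt < 0 | plddt$plddt > 100)) {
    stop("pLDDT values must lie in [0, 100]", call. = FALSE)
  }
  profs <- lapply(unique(plddt$protein), function(p) {
    sub <- plddt[plddt$protein == p, ]
    sub <- sub[order(sub$residue), ]
    L <- protein_lengths[[p]]
    if (is.null(L) || nrow(sub) != L ||
        !identical(as.integer(sub$residue), seq_len(L))) {
      stop(sprintf("pLDDT profile length mismatch for %s", p), call. = FALSE)
    }
    sub$scaled_shade <- scale_minmax(sub$plddt)
    sub
  })
  profiles <- dplyr::bind_rows(profs)

  lookup <- setNames(profiles$plddt,
                     paste(profiles$protein, profiles$residue, sep = ":"))
  state <- function(protein, residue) {
    v <- unname(lookup[paste(protein, residue, sep = ":")])
    ifelse(is.na(v), NA_character_,
           ifelse(v >= threshold, "structured", "disordered"))
  }
  endpoint_summary <- NULL
  if (!is.null(links)) {
    links <- tibble::as_tibble(links)
    links$end_a_state <- state(links$protein_a, links$residue_a)
    links$end_b_state <- ifelse(is.na(links$protein_b), NA_character_,
                                state(links$protein_b, links$residue_b))
    st <- c(links$end_a_state, links$end_b_state)
    cat_ <- rep(links$category, 2)
    ok <- !is.na(st)
    endpoint_summary <- as.data.frame(table(category = cat_[ok], state = st[ok]))
    names(endpoint_summary)[3] <- "n"
    endpoint_summary <- tibble::as_tibble(endpoint_summary)
  }
  list(profiles = profiles, links = links, endpoint_summary = endpoint_summary)
}

#' Circular-map layout for the cross-link network
#'
#' Assigns each protein a circular sector with width proportional to its
#' length (N to C terminus, clockwise), separated by fixed gaps, and maps
#' every link to a chord between its endpoint angles. By the figure
#' convention intralinks are drawn outside the circle and interlinks
#' inside.
#'
#' @param protein_lengths Named integer vector of protein lengths (all > 0).
#' @param links Link tibble with `category` (see [classify_links()]).
#' @param sector_order Order of proteins around the circle; defaults to
#'   `names(protein_lengths)`.
#' @param gap_deg Gap between adjacent sectors in degrees (default 2).
#' @return An object of class `mrnp_circular_layout`: list with `sectors`
#'   (tibble: `protein`, `start_deg`, `end_deg`, `span_deg`), `chords`
#'   (tibble: endpoint angles, `category`, `side`), and the vectorized
#'   mapping functions `residue_angle(protein, residue)` and
#'   `angle_residue(protein, angle)`.
#' @export
circular_layout <- function(protein_lengths, links = NULL,
                            sector_order = names(protein_lengths),
                            gap_deg = 2) {
  if (length(protein_lengths) == 0 || any(protein_lengths <= 0)) {
    stop("protein lengths must be positive", call. = FALSE)
  }
  lens <- protein_lengths[sector_order]
  np <- length(lens)
  total_gap <- gap_deg * np
  if (total_gap >= 360) stop("gaps exceed the circle", call. = FALSE)
  span <- (360 - total_gap) * lens / sum(lens)
  start <- cumsum(c(0, (span + gap_deg)[-np]))
  sectors <- tibble::tibble(protein = names(lens),
                            start_deg = start,
                            end_deg = start + span,
                            span_deg = unname(span))

  residue_angle <- function(protein, residue) {
    n <- max(length(protein), length(residue))
    i <- rep_len(match(protein, sectors$protein), n)
    residue <- rep_len(residue, n)
    L <- unname(lens[i])
    frac <- ifelse(L == 1, 0, (residue - 1) / pmax(L - 1, 1))
    unname(sectors$start_deg[i] + frac * sectors$span_deg[i])
  }
  angle_residue <- function(protein, angle) {
    n <- max(length(protein), length(angle))
    i <- rep_len(match(protein, sectors$protein), n)
    angle <- rep_len(angle, n)
    L <- unname(lens[i])
    frac <- (angle - sectors$start_deg[i]) / sectors$span_deg[i]
    as.integer(round(1 + frac * (L - 1)))
  }

  chords <- NULL
  if (!is.null(links)) {
    links <- tibble::as_tibble(links)
    both <- links[links$category %in% c("intra", "inter"), , drop = FALSE]
    chords <- tibble::tibble(
      protein_a = both$protein_a,
      angle_a = residue_angle(both$protein_a, both$residue_a),
      protein_b = both$protein_b,
      angle_b = residue_angle(both$protein_b, both$residue_b),
      category = both$category,
      side = ifelse(both$category == "intra", "outside", "inside")
    )
  }
  structure(list(sectors = sectors, chords = chords,
                 residue_angle = residue_angle,
                 angle_residue = angle_residue),
            class = "mrnp_circular_layout")
}
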