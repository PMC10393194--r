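#' Specification of a synthetic cross-linking topology
#'
#' Describes proteins (length and lysine positions) and the BS3 products to
#' plant: monolinks (one reacted end), intralinks, interlinks, and
#' self-links constructed to satisfy the homo-oligomer rule (identical
#' lysines or overlapping supporting peptides).
#'
#' @param proteins Tibble with columns `protein`, `length`, and a `lysines`
#'   list-column of 1-based lysine positions.
#' @param planted_links Tibble with columns `protein_a`, `residue_a`,
#'   `protein_b`, `residue_b`; monolinks have `NA` on the b side.
#' @param planted_self_links Optional tibble of intralinks (same columns,
#'   both sides set, `protein_a == protein_b`) intended as homo-oligomer
#'   evidence; peptide windows are centred so identical residues always
#'   yield overlapping peptides.
#' @param peptide_window Half-width (residues) of the synthetic supporting
#'   peptide interval around each linked residue (default 7).
#' @return A list of class `mrnp_crosslink_spec`.
#' @export
crosslink_topology_spec <- function(proteins, planted_links,
                                    planted_self_links = NULL,
                                    peptide_window = 7L) {
  stopifnot(all(c("protein", "length", "lysines") %in% names(proteins)))
  spec <- structure(list(proteins = tibble::as_tibble(proteins),
                         planted_links = tibble::as_tibble(planted_links),
                         planted_self_links =
                           if (is.null(planted_self_links)) NULL
                           else tibble::as_tibble(planted_self_links),
                         peptide_window = as.integer(peptide_window)),
                    class = "mrnp_crosslink_spec")
  check_planted <- function(tbl) {
    for (i in seq_len(nrow(tbl))) {
      for (side in c("a", "b")) {
        p <- tbl[[paste0("protein_", side)]][i]
        r <- tbl[[paste0("residue_", side)]][i]
        if (is.na(p) || is.na(r)) next
        row <- spec$proteins[spec$proteins$protein == p, ]
        if (nrow(row) == 0) stop("unknown protein: ", p, call. = FALSE)
        if (r < 1 || r > row$length[[1]]) {
          stop(sprintf("residue %d outside protein %s", r, p), call. = FALSE)
        }
        if (!r %in% row$lysines[[1]]) {
          stop(sprintf("planted residue %d of %s is not a lysine", r, p),
               call. = FALSE)
        }
      }
    }
  }
  check_planted(spec$planted_links)
  if (!is.null(spec$planted_self_links)) check_planted(spec$planted_self_links)
  spec
}

#' Simulate a cross-link table
#'
#' Every planted link appears exactly once, with supporting peptide
#' intervals of half-width `peptide_window` around each residue, clipped to
#' the protein bounds. Monolinks have empty partner fields. Row order is
#' shuffled with `seed` so downstream classification cannot rely on input
#' order.
#'
#' @param spec An `mrnp_crosslink_spec`.
#' @param seed Integer seed (controls row order only).
#' @return Tibble with the cross-link schema: `protein_a`, `residue_a`,
#'   `pep_a_start`, `pep_a_end`, `protein_b`, `residue_b`, `pep_b_start`,
#'   `pep_b_end`.
#' @export
simulate_crosslinks <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mrnp_crosslink_spec"))
  all_links <- dplyr::bind_rows(spec$planted_links, spec$planted_self_links)
  w <- spec$peptide_window
  plen <- setNames(spec$proteins$length, spec$proteins$protein)

  interval <- function(protein, residue) {
    if (is.na(protein) || is.na(residue)) return(c(NA_integer_, NA_integer_))
    c(max(1L, as.integer(residue) - w),
      min(unname(plen[protein]), as.integer(residue) + w))
  }
  rows <- lapply(seq_len(nrow(all_links)), function(i) {
    ia <- interval(all_links$protein_a[i], all_links$residue_a[i])
    ib <- interval(all_links$protein_b[i], all_links$residue_b[i])
    tibble::tibble(
      protein_a = all_links$protein_a[i], residue_a = all_links$residue_a[i],
      pep_a_start = ia[1], pep_a_end = ia[2],
      protein_b = all_links$protein_b[i], residue_b = all_links$residue_b[i],
      pep_b_start = ib[1], pep_b_end = ib[2]
    )
  })
  out <- dplyr::bind_rows(rows)
  set.seed(sub_seed(seed, "crosslink-order"))
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Default cross-link topology emulating the study's link classes
#'
#' Random lysine-bearing proteins with planted intralinks (including
#' Yra1-like and Nab2-like self-links between identical lysines),
#' interlinks among the THO-like components and export factors, and
#' monolinks.
#'
#' @param seed Seed for protein geometry.
#' @return An `mrnp_crosslink_spec`.
#' @export
default_crosslink_spec <- function(seed = 1L) {
  set.seed(sub_seed(seed, "default-xl-topology"))
  prots <- tibble::tibble(
    protein = c("THO2", "HPR1", "SUB2L", "YRA1L", "NAB2L"),
    length = c(900L, 750L, 450L, 220L, 520L)
  )
  prots$lysines <- lapply(prots$length, function(L) {
    sort(sample.int(L, max(10L, L %/% 25L)))
  })
  k <- function(p, i) prots$lysines[[match(p, prots$protein)]][i]
  planted <- tibble::tibble(
    protein_a = c("THO2", "THO2", "HPR1", "SUB2L", "YRA1L",
                  "THO2", "THO2", "HPR1", "SUB2L", "YRA1L",
                  "THO2", "NAB2L"),
    residue_a = c(k("THO2", 2), k("THO2", 10), k("HPR1", 3), k("SUB2L", 4),
                  k("YRA1L", 2),
                  k("THO2", 5), k("THO2", 12), k("HPR1", 6), k("SUB2L", 2),
                  k("YRA1L", 3),
                  k("THO2", 7), k("NAB2L", 4)),
    protein_b = c("THO2", "THO2", "HPR1", "SUB2L", "YRA1L",
                  "HPR1", "SUB2L", "SUB2L", "YRA1L", "NAB2L",
                  NA, NA),
    residue_b = c(k("THO2", 6), k("THO2", 14), k("HPR1", 8), k("SUB2L", 7),
                  k("YRA1L", 5),
                  k("HPR1", 2), k("SUB2L", 5), k("SUB2L", 3), k("YRA1L", 4),
                  k("NAB2L", 2),
                  NA, NA)
  )
  selfs <- tibble::tibble(
    protein_a = c("YRA1L", "NAB2L"),
    residue_a = c(k("YRA1L", 2), k("NAB2L", 5)),
    protein_b = c("YRA1L", "NAB2L"),
    residue_b = c(k("YRA1L", 2), k("NAB2L", 5))
  )
  crosslink_topology_spec(prots, planted, selfs)
}
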