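#' Simulate per-residue confidence (pLDDT) profiles
#'
#' Generates a smooth block-structured profile per protein: alternating
#' folded segments (high confidence, around 85) and disordered segments
#' (low confidence, around 40) with Gaussian noise, clipped to \[0, 100\].
#' Stands in for per-residue confidence scores consumed as input tables.
#'
#' @param protein_lengths Named integer vector.
#' @param seed Integer seed.
#' @return Tibble with `protein`, `residue`, `plddt`.
#' @export
simulate_plddt <- function(protein_lengths, seed = 1L) {
  set.seed(sub_seed(seed, "plddt"))
  rows <- lapply(names(protein_lengths), function(p) {
    L <- protein_lengths[[p]]
    vals <- numeric(0)
    state <- runif(1) < 0.5
    while (length(vals) < L) {
      blk <- as.integer(round(runif(1, 30, 120)))
      mu <- if (state) 85 else 40
      vals <- c(vals, rnorm(blk, mu, 5))
      state <- !state
    }
    tibble::tibble(protein = p, residue = seq_len(L),
                   plddt = pmin(100, pmax(0, round(vals[seq_len(L)], 2))))
  })
  dplyr::bind_rows(rows)
}

#' Default end-to-end pipeline configuration
#'
#' Nested list mirroring each stage's parameters. The RNA block holds one
#' generator config plus per-sample truncation/retention overrides: the
#' lysate is nearly mature (truncation 0.05, retention 0.05) while the
#' eluate is nascent-enriched (truncation 0.30, retention 0.30).
#'
#' @param seed Top-level seed propagated to all stages.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, rnaseq = TRUE, proteomics = TRUE,
                  xlms = TRUE, anneal = TRUE),
    rna = list(
      n_transcripts = 300L,
      n_read_pairs = 2e5,
      intron_fraction = 0.15,
      mito_fraction = 0.05,
      lysate = list(truncation = 0.05, retention = 0.05),
      eluate = list(truncation = 0.30, retention = 0.30),
      min_cov = 20L,
      bins = 100L,
      pseudocount = 0.5
    ),
    proteomics = list(yra1_weight = 10,
                      numerator_class = "Yra1-like",
                      denominator_class = "THO"),
    xlms = list(threshold = 70, gap_deg = 2),
    anneal = list(substrate_len = 315L, core_len = 60L, flank_len = 10L,
                  min_duplex = 15L, mode = "idealized")
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  extra <- setdiff(names(override), names(base))
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else {
      override[[k]]
    }
  }
  base
}

#' Run the full synthetic mRNP characterization pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic dataset:
#' simulate (transcriptome, reads, peptides, cross-links, annealing
#' substrates), rnaseq (metagene, junction statistics, enrichment),
#' proteomics (iBAQ, stoichiometry), xlms (classification, self-links,
#' disorder overlay, layout) and anneal (protection assay). Stage outputs
#' are written under `outdir` together with a resolved copy of the
#' configuration, and a consolidated JSON report aggregates the seven
#' headline summaries.
#'
#' @param config Configuration list; unknown keys are rejected. Partial
#'   lists are merged over [default_pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return The report as a named list (also written to
#'   `file.path(outdir, "report.json")`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("mrnp_run_"),
                         seed = NULL) {
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(outdir, "resolved-config.yaml"))

  report <- list()
  st <- cfg$stages
  sim <- NULL

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (isTRUE(st$simulate) || isTRUE(st$rnaseq)) {
    sim <- run_stage("simulate", function() {
      gc_ly <- generator_config(
        n_transcripts = cfg$rna$n_transcripts,
        intron_fraction = cfg$rna$intron_fraction,
        mito_fraction = cfg$rna$mito_fraction,
        nascent_truncation_fraction = cfg$rna$lysate$truncation,
        retention_rate = cfg$rna$lysate$retention,
        n_read_pairs = cfg$rna$n_read_pairs,
        seed = cfg$seed)
      gc_el <- generator_config(
        n_transcripts = cfg$rna$n_transcripts,
        intron_fraction = cfg$rna$intron_fraction,
        mito_fraction = cfg$rna$mito_fraction,
        nascent_truncation_fraction = cfg$rna$eluate$truncation,
        retention_rate = cfg$rna$eluate$retention,
        n_read_pairs = cfg$rna$n_read_pairs,
        seed = cfg$seed)
      txome <- generate_transcriptome(gc_ly)
      lysate <- simulate_reads(txome, gc_ly, "lysate",
                               seed = sub_seed(cfg$seed, "lysate"))
      eluate <- simulate_reads(txome, gc_el, "eluate",
                               seed = sub_seed(cfg$seed, "eluate"))
      write_transcriptome_gff3(txome, file.path(outdir, "annotation.gff3"))
      Biostrings::writeXStringSet(txome$sequences,
                                  file.path(outdir, "transcripts.fasta"))
      write_sam(lysate, txome, file.path(outdir, "lysate.tx.sam"),
                mode = "transcript")
      write_sam(eluate, txome, file.path(outdir, "eluate.tx.sam"),
                mode = "transcript")
      write_sam(lysate, txome, file.path(outdir, "lysate.genome.sam"),
                mode = "genome")
      write_sam(eluate, txome, file.path(outdir, "eluate.genome.sam"),
                mode = "genome")
      list(txome = txome, lysate = lysate, eluate = eluate)
    })
  }

  if (isTRUE(st$rnaseq)) {
    report <- c(report, run_stage("rnaseq", function() {
      txome <- sim$txome
      tx <- txome$transcripts
      gal_el <- as_galignments(sim$eluate, txome, "transcript")
      profiles <- coverage_profiles(gal_el)
      cohort <- tx$transcript_id[tx$genome == "nuclear" & !tx$has_intron]
      mg <- metagene_matrix(profiles, transcripts = cohort,
                            bins = cfg$rna$bins)
      utils::write.csv(mg$matrix, file.path(outdir, "metagene-matrix.csv"))
      utils::write.csv(data.frame(bin = seq_along(mg$summary),
                                  summary_pct = mg$summary),
                       file.path(outdir, "metagene-summary.csv"),
                       row.names = FALSE)

      js_ly <- junction_stats(as_galignments(sim$lysate, txome, "genome"),
                              txome, min_cov = cfg$rna$min_cov)
      js_el <- junction_stats(as_galignments(sim$eluate, txome, "genome"),
                              txome, min_cov = cfg$rna$min_cov)
      write_tsv_plain(js_ly, file.path(outdir, "junctions-lysate.tsv"))
      write_tsv_plain(js_el, file.path(outdir, "junctions-eluate.tsv"))
      wc <- compare_unspliced(js_ly, js_el)

      enr <- enrichment_table(count_read_pairs(sim$lysate),
                              count_read_pairs(sim$eluate),
                              pseudocount = cfg$rna$pseudocount)
      write_tsv_plain(enr, file.path(outdir, "enrichment.tsv"))
      rho_hl <- correlate_enrichment(
        enr, setNames(tx$half_life_min, tx$transcript_id), "half_life")
      rho_len <- correlate_enrichment(
        enr, setNames(tx$length, tx$transcript_id), "length")
      jsonlite::write_json(
        list(half_life = rho_hl, length = rho_len),
        file.path(outdir, "correlations.json"), auto_unbox = TRUE, digits = NA)

      list(metagene_end_bin_contrast = metagene_end_contrast(mg),
           junction_wilcoxon_p = wc$p_value,
           enrichment_correlations = list(half_life_rho = rho_hl$rho,
                                          length_rho = rho_len$rho))
    }))
  }

  if (isTRUE(st$proteomics)) {
    report <- c(report, run_stage("proteomics", function() {
      ds <- default_stoichiometry_spec(seed = cfg$seed,
                                       yra1_weight = cfg$proteomics$yra1_weight)
      pep <- simulate_peptides(ds$spec, seed = sub_seed(cfg$seed, "peptides"))
      write_tsv_plain(pep, file.path(outdir, "peptides.tsv"))
      aa <- Biostrings::AAStringSet(ds$spec$proteins)
      Biostrings::writeXStringSet(aa, file.path(outdir, "proteins.fasta"))
      ib <- ibaq_table(pep, ds$spec$proteins, protease = ds$spec$protease)
      write_tsv_plain(ib$records, file.path(outdir, "ibaq.tsv"))
      scatter <- ib$means
      scatter$class <- unname(ds$classes[scatter$protein])
      utils::write.csv(scatter[, c("protein", "class", "condition",
                                   "mw", "mean_ibaq")],
                       file.path(outdir, "ibaq-scatter.csv"),
                       row.names = FALSE)
      sto <- stoichiometry_report(ib, ds$classes,
                                  cfg$proteomics$numerator_class,
                                  cfg$proteomics$denominator_class)
      jsonlite::write_json(sto, file.path(outdir, "stoichiometry.json"),
                           auto_unbox = TRUE, digits = NA)
      list(stoichiometry_ratios =
             setNames(as.list(sto$ratio), sto$condition))
    }))
  }

  if (isTRUE(st$xlms)) {
    report <- c(report, run_stage("xlms", function() {
      xspec <- default_crosslink_spec(seed = cfg$seed)
      xl <- simulate_crosslinks(xspec, seed = sub_seed(cfg$seed, "xlinks"))
      write_tsv_plain(xl, file.path(outdir, "crosslinks.tsv"))
      cls <- classify_links(xl)
      flagged <- detect_self_links(cls)
      write_tsv_plain(flagged, file.path(outdir, "crosslinks-classified.tsv"))
      plens <- setNames(xspec$proteins$length, xspec$proteins$protein)
      pl <- simulate_plddt(plens, seed = sub_seed(cfg$seed, "plddt"))
      write_tsv_plain(pl, file.path(outdir, "plddt.tsv"))
      ov <- disorder_overlay(pl, plens, flagged,
                             threshold = cfg$xlms$threshold)
      lay <- circular_layout(plens, flagged, gap_deg = cfg$xlms$gap_deg)
      jsonlite::write_json(
        list(sectors = lay$sectors, chords = lay$chords,
             counts = as.list(cls$counts)),
        file.path(outdir, "xlms-layout.json"), auto_unbox = TRUE, digits = NA)
      list(link_category_counts = as.list(cls$counts),
           self_link_count = sum(flagged$self_link))
    }))
  }

  if (isTRUE(st$anneal)) {
    report <- c(report, run_stage("anneal", function() {
      an <- cfg$anneal
      pair <- make_annealing_pair(an$substrate_len, an$core_len, an$flank_len,
                                  seed = sub_seed(cfg$seed, "anneal"))
      res <- annealing_assay(pair$substrate, pair$probe,
                             min_duplex = an$min_duplex, mode = an$mode)
      Biostrings::writeXStringSet(
        Biostrings::RNAStringSet(c(substrate = pair$substrate,
                                   probe = pair$probe)),
        file.path(outdir, "annealing-rnas.fasta"))
      list(protected_fragment_lengths = res$lanes)
    }))
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
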