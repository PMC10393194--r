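# mrnpAtlas

Characterization toolkit for purified nuclear messenger ribonucleoprotein
(mRNP) particles, for researchers analyzing affinity-purified mRNP fractions
with RNA-seq, quantitative proteomics and cross-linking mass spectrometry
(XL-MS). The package implements the complete computational pipeline as
reusable, tested functions, driven by a synthetic-data generator that
emulates the statistical structure of such experiments — so every stage
runs and is testable without any external download, and the same code paths
accept real GFF3 / SAM / FASTA / TSV inputs.

## What it computes

**RNA content.** Per-transcript coverage profiles (CIGAR M segments only);
the 100-bin metagene matrix, with each transcript's binned coverage min–max
scaled to [0, 1] and the per-bin average rescaled to [0, 100]%; per-junction
split/nonsplit read counts at annotated 5′ and 3′ splice sites, where the
unspliced fraction is

```
unspliced_fraction = nonsplit / split        (junctions with < 20 reads excluded)
```

compared between samples with a two-sided Wilcoxon rank-sum test; and
eluate/lysate enrichment with median-of-ratios size factors,

```
log2FC = log2( (eluate/sf_E + c) / (lysate/sf_L + c) ),   c = 0.5
```

rank-correlated (Spearman) against mRNA half-life and transcript length.

**Protein content.** In-silico LysC / Trypsin/P digestion and
intensity-based absolute quantification:

```
iBAQ = sum(peptide intensities) / #(theoretically observable peptides, 7–30 aa)
```

with per-condition replicate means and between-class stoichiometry ratios
(e.g. a Yra1-like export adaptor over THO components).

**Protein proximity.** Classification of BS³ cross-links into monolinks,
intralinks and interlinks (A–B/B–A deduplicated); homo-oligomer self-link
detection (identical lysines or overlapping supporting peptides); per-residue
pLDDT disorder overlay; and circular-map layout geometry.

**RNA annealing.** An in-silico RNase T1 protection assay: exact
antiparallel Watson–Crick duplex finding between a substrate and a probe
built as `flank + reverse-complement(substrate core) + flank`, followed by
digestion of all unpaired regions and a fragment-length "gel lane" readout.

## Worked example

```r
library(mrnpAtlas)
report <- run_pipeline(
  config = list(rna = list(n_transcripts = 150L, n_read_pairs = 50000)),
  outdir = "mrnp-out", seed = 42)
str(report, max.level = 2, digits.d = 3)
#> List of 7
#>  $ metagene_end_bin_contrast : num 47.6
#>  $ junction_wilcoxon_p       : num 4.86e-07
#>  $ enrichment_correlations   :List of 2
#>   ..$ half_life_rho: num -0.616
#>   ..$ length_rho   : num 0.574
#>  $ stoichiometry_ratios      :List of 4
#>   ..$ benzonase_eluate     : num 1.46
#>   ..$ benzonase_flowthrough: num 14.4
#>   ..$ eluate               : num 7.39
#>   ..$ flowthrough          : num 11.2
#>  $ link_category_counts      :List of 3
#>   ..$ mono : int 2
#>   ..$ intra: int 7
#>   ..$ inter: int 5
#>  $ self_link_count           : int 2
#>  $ protected_fragment_lengths:List of 2
#>   ..$ substrate: int 60
#>   ..$ probe    : int 60
```

Reading the report: the eluate's metagene is strongly 5′-biased (first
minus last bin of the 0–100% column summary is ~48 points), because the
simulated eluate is nascent-enriched; its unspliced fractions are shifted
up relative to the lysate (Wilcoxon p ≈ 5×10⁻⁷, retention 0.30 vs 0.05);
enrichment anticorrelates with half-life (ρ ≈ −0.62) and correlates with
length (ρ ≈ +0.57), recovering the signs of the planted coefficients; the
intact-eluate Yra1-like:THO iBAQ ratio ≈ 7.4 recovers the planted 10×
overstoichiometry within two-fold and drops to ≈ 1.5 after in-silico
nuclease treatment; the planted cross-link topology classifies as
7 intra / 5 inter / 2 mono with 2 self-links; and the annealing assay
protects a single 60-nt duplex fragment on both the 315-nt substrate and
the 80-nt probe.

Intermediate outputs (GFF3 annotation, SAM alignments in transcript and
genome coordinates, FASTA sequences, peptide/cross-link/pLDDT TSVs,
metagene CSVs, JSON summaries) are written under `outdir`, together with a
resolved copy of the configuration. A command-line wrapper with
`simulate | rnaseq | proteomics | xlms | anneal | all | validate`
subcommands is installed at `inst/scripts/mrnp-atlas.R`.

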