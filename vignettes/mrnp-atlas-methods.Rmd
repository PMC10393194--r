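---
title: "Models and methods behind mrnpAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrnpAtlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnpAtlas)
```

# Scope

mrnpAtlas characterizes purified nuclear messenger ribonucleoprotein (mRNP)
particles along three axes — RNA content, protein content and protein
proximity — plus an in-silico model of the RNA-annealing / RNase T1
protection assay used to probe RNA-matchmaking activity. Because the
corresponding experimental datasets are large external deposits, every
analysis stage is driven by a synthetic-data generator that emulates the
*statistical structure* of such data; this vignette records the models, the
defaults and the design decisions, and what passing tests do and do not
establish about real data.

# The synthetic transcriptome and read model

`generate_transcriptome()` builds `n_transcripts` transcripts with lengths
drawn as `min + (max - min) * u^shape` (`u ~ U(0,1)`; the default shape of 2
skews toward short transcripts, as in a real mRNA population). A
deterministic `round(fraction * n)` of transcripts carries exactly one
intron (intron length uniform on 80–400 nt, junction placed at 20–80% of
the mature length) and a deterministic fraction is flagged
mitochondrial-encoded. Transcripts are tiled on two synthetic chromosomes
(`chrN`, `chrM`) with 200-nt intergenic gaps, all on the plus strand — a
deliberate simplification: strandedness contributes nothing to coverage
binning or junction counting, which is what the genome-coordinate mode
exists to exercise.

mRNA half-lives are drawn log-uniformly over 3–100 minutes. This range
covers the bulk of published yeast mRNA decay measurements; the analysis
only uses ranks, so the marginal shape matters little.

`simulate_reads()` draws paired 75-nt mates (the library geometry of the
emulated experiment) with a fragment length of 200 ± 20 nt clipped at
molecule ends; only read length is dictated by the emulated protocol, the
insert model is our choice of a typical short-insert library. Per-transcript
read counts are Poisson around the abundance model:

* baseline log-abundance `~ N(0, 1)` per transcript plus `log(length)`
  (longer molecules shed more fragments), shared between samples because it
  is derived from the config seed, not the sample seed;
* the **eluate** adds `beta_halflife * z(log half-life) + beta_length *
  z(log length)` (defaults −0.5 and +0.5) and multiplies mitochondrial
  transcripts by `mito_depletion_factor` (default 0.05). These defaults
  encode the qualitative purification signature being emulated: short-lived
  transcripts over-represented, long transcripts over-represented,
  mitochondrial RNAs depleted.

The nascent-transcription proxy behind 5′-biased coverage is 3′ truncation:
a fraction `nascent_truncation_fraction` of source molecules is cut at a
uniform random 3′ point before fragmentation. The emulated study states the
bias but no generative model; uniform truncation is the simplest mechanism
that yields a monotonically decreasing expected coverage along the
transcript. The pipeline default gives the lysate 0.05 and the eluate 0.30,
so the eluate is nascent-enriched while the lysate is nearly mature.

Junction-spanning reads are emitted *split* (gap exactly matching the
annotated intron) with probability `1 − retention_rate`, else *unspliced*:
a contiguous alignment anchored with equal probability at the 5′ or 3′
splice site, running into the intron. Anchoring at one site per read
reflects that a 75-nt read cannot cross an 80–400-nt intron entirely.
Library depth defaults to 1e6 read pairs per sample; the emulated protocol
does not state depths, so this is configurable, not canonical.

# RNA-content metrics

**Coverage and metagene.** Depth counts aligned (CIGAR M) bases only; N
gaps contribute nothing. The metagene follows the 100-bin contract: each
transcript's binned coverage is min–max scaled to [0, 1], the per-bin
average over transcripts is min–max rescaled to [0, 100]%. A constant
binned profile scales to all zeros — 0/0 is avoided and a flat profile
carries no positional signal. Consequently the column summary attains
exactly 100 at its peak bin and exactly 0 at its minimum on any
non-degenerate cohort. No minimum-coverage floor is applied to cohort
membership by default (whether the emulated analysis used one is unknown);
callers can pre-filter the profile list.

**Junction statistics.** "Overlapping the splice site" is made precise as:
a gapless read covering the junction point with ≥ `min_anchor` = 3 aligned
nt on each side (nonsplit), or a read whose N gap equals the annotated
intron exactly, likewise anchored by ≥ 3 nt on both sides (split). The
anchor requirement is stated only for nonsplit reads in the emulated
analysis; we apply it symmetrically so both categories share the same
minimum evidence. Reads whose gaps disagree with the annotation are
discarded from both counts. The 5′ and 3′ sites of an intron are scored as
separate junction records; junctions with fewer than `min_cov` = 20 counted
reads are excluded, and the unspliced fraction is nonsplit/split, defined
only when split > 0. The two-sample comparison is a two-sided Wilcoxon
rank-sum test; we always use the normal approximation with continuity and
tie correction (ties are pervasive in ratio data at modest depth), and an
all-identical input is reported as degenerate rather than forcing a
p-value.

**Enrichment.** Normalization is median-of-ratios: per-transcript geometric
mean of the two samples as the pseudo-reference (zero-count transcripts
excluded from factor estimation), sample factor = median ratio to the
reference; log2 fold change uses a pseudocount of 0.5 on normalized
counts. A dispersion-shrunken model would be superfluous here: the
downstream statistic is a Spearman rank correlation against half-life or
length, which depends only on ordering. Read pairs count once per
transcript; in the simulator each pair derives from exactly one transcript.

# Protein quantitation (iBAQ)

`digest_protein()` implements LysC (cleaves C-terminal to K) and Trypsin/P
(C-terminal to K or R, including before proline), with 0..m missed
cleavages. `count_observable_peptides()` counts fully cleaved peptides of
7–30 residues — common iBAQ practice; the emulated workflow delegates this
to a search engine whose bounds are not recoverable, so the bounds are
exposed as configuration. A floor of 1 on the denominator protects short or
cleavage-poor proteins. iBAQ per (protein, condition, replicate) is summed
peptide intensity over the observable count; a protein absent from a
replicate contributes intensity 0 (absent, not unmeasured — appropriate for
affinity-captured material where non-detection is informative), keeping
condition means comparable across proteins. Molecular weights use average
residue masses (the MW axis orders a scatter plot; isotopic resolution is
irrelevant), with `X` tolerated and excluded.

The peptide simulator gives each observable peptide a fixed log-normal
detectability (sd 0.5 on the natural-log scale, shared across conditions
and replicates) and multiplies copy-number weight × detectability ×
`exp(N(0, noise_sd))`. The default proteome plants a 10× overstoichiometric
Yra1-like export adaptor over five unit-weight THO-like components, reduced
to 2× after in-silico nuclease treatment — the qualitative stoichiometry
picture the analysis is designed to resolve. Because detectability is a
random per-peptide effect, the recovered iBAQ ratio scatters around the
planted 10:1 within roughly two-fold, which is the tolerance the tests
assert.

# Cross-link networks

Links are partitioned mono / intra / inter; interlinks are canonicalized to
lexicographic protein order and intralinks to ascending residue order
before deduplication, so A–B / B–A duplicates collapse with a multiplicity
count (whether the emulated analysis deduplicated direction is unstated;
unique links are the conservative choice). The homo-oligomer (self-link)
rule flags an intralink when its residues are identical or its supporting
peptide intervals share ≥ 1 residue (closed intervals; the source describes
"overlapping peptides" with no stated minimum). The rule is symmetric by
construction after canonicalization.

Per-residue confidence (pLDDT) profiles are consumed as tables, min–max
scaled per protein for shading (constant profiles scale to 0), and link
endpoints are called structured at pLDDT ≥ 70 — the conventional
interpretation threshold, exposed as configuration. The circular layout
assigns sector widths proportional to protein length with fixed gaps;
residue angle interpolates linearly N→C within the sector, so the layout is
invariant to rescaling all lengths, and angle→residue inversion is exact to
±1 residue (rounding).

# The annealing / protection model

`make_annealing_pair()` reproduces the printed assay geometry: random
substrate, probe = flank + reverse-complement(substrate window) + flank,
with each flank base checked against the substrate at the annealed register
and replaced if it would pair. `anneal()` enumerates all maximal exact
antiparallel Watson–Crick matches ≥ `min_duplex` (default 15 nt, enough to
suppress chance matches in random flanks: a specific ≥15-nt match occurs by
chance with probability ≈ 4^-15 per register) and greedily selects a
non-overlapping set by descending length, ties to the leftmost substrate
coordinate. No thermodynamics and no G·U wobble: the assay is designed
around a perfectly complementary core, and the readout is presence/absence
of the protected band, so the protein's annealing activity is a boolean
switch, not a kinetic model.

RNase T1 digestion has two modes. `idealized` (default) removes every
unpaired nucleotide — matching the assay description in which unpaired
fragments are digested entirely — so protected fragments are exactly the
duplexed intervals and total protected length equals total duplexed length.
`g_specific` reflects the enzyme's actual guanosine specificity: the
molecule is cut 3′ of every unpaired G, and fragments containing at least
one paired position are reported (they may carry non-G single-stranded
overhangs up to the nearest unpaired G); fully unpaired fragments are
treated as degraded.

# Pipeline, determinism and problem sizes

`run_pipeline()` merges a user configuration over
`default_pipeline_config()` (unknown keys rejected), writes a resolved
configuration copy next to the outputs, executes the enabled stages in
dependency order, and emits a JSON report with seven summaries: metagene
end-bin contrast, junction Wilcoxon p, enrichment correlations,
stoichiometry ratios, link-category counts, self-link count and protected
fragment lengths. Every random draw descends from one seed through tagged
sub-streams, so a fixed (config, seed) pair reproduces outputs
byte-for-byte; SAM files are written through a binary connection to keep
line endings platform-independent.

The packaged default for `run_pipeline()` uses 300 transcripts and 2×10^5
read pairs per sample — large enough that every reported sign and contrast
is stable across seeds, while a full run completes in seconds. The test
suite uses 30–500 transcripts and 10^4–6×10^4 read pairs per sample
depending on the property under test; the power-style suites (Wilcoxon
detection across 100 seeded runs, correlation-sign recovery across 40 runs
at n = 500) were sized so that the binomial uncertainty of the reported
success rates is well below the asserted margins.

# What the synthetic data does not show

The generator emulates marginal and first-order structure: abundance
shifts, truncation bias, retention rates, log-normal intensities, planted
link topologies. It does not model sequencing error, mappability,
positional fragmentation bias, isoform complexity (one intron at most),
peptide co-elution or missing-value mechanisms in MS, or chance cross-link
misidentification. Passing tests therefore demonstrate that the estimators
recover planted structure under the stated noise models — not that they are
robust to every artefact of real libraries. The interfaces accept real
GFF3/SAM/FASTA/TSV inputs so the same code paths can be pointed at
experimental data.

# Known limitations

* Junction statistics assume splice-site coordinates are exact; reads with
  near-miss gaps are discarded rather than rescued.
* The enrichment estimator reports ranked log2 fold changes only; no
  dispersion estimation or hypothesis testing per transcript.
* `anneal()` is exact-match only; structured substrates that occlude the
  probe site in reality will still anneal in silico.
* The circular layout emits geometry (sectors, chords); rendering is left
  to the caller.
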