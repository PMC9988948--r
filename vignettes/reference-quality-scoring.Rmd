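---
title: "Scoring reference genomes and gene annotations across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring reference genomes and gene annotations across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reference genomes and their gene annotations differ enormously in quality
across species, yet most contiguity statistics (N50, gap counts) are not
comparable between genomes of different sizes, and there is no widely agreed
single measure of gene-annotation quality at all. `refqual` scores a *cohort*
of species on a common 0–1 scale by combining three families of evidence:

1. **Assembly statistics** — contiguity and gap structure of the assembly
   itself.
2. **Empirical mapping behaviour** — how RNA-seq reads actually align to the
   genome, taken from aligner summary reports.
3. **Empirical quantification behaviour and annotation composition** — how
   mapped reads assign to annotated genes, and how diverse the annotated
   gene biotypes are.

All scoring is *cohort-relative where it must be* (percentiles, min–max
scaling) and *absolute where it can be* (rates), and every indicator is
oriented so that 1 means better.

## The ten indicators

| # | Indicator | Formula | Scaling |
|---|-----------|---------|---------|
| 1 | AdjN50Contig | contig N50 / genome size | cohort percentile |
| 2 | AdjN50Scaffold | scaffold N50 / genome size | cohort percentile |
| 3 | UngapRate | 1 − gaps / max(gaps) | none |
| 4 | UnimapRate | uniquely mapped / total reads | none |
| 5 | MapRate | 1 − unmapped / total reads | none |
| 6 | MultiMapRate | 1 − multi-mapped / total reads | none |
| 7 | TranscriptDiversity | PC1 of biotype proportions | min–max |
| 8 | QuantRate | assigned / mapped reads | none |
| 9 | QuantRateAbs | 1 − no-feature failures / mapped reads | none |
| 10 | QuantRateAmb | 1 − ambiguity failures / mapped reads | none |

Two stage summaries are defined as plain arithmetic means:

$$\mathrm{MQI}_i = \tfrac13(\mathrm{UnimapRate}_i + \mathrm{MapRate}_i +
\mathrm{MultiMapRate}_i), \qquad
\mathrm{QQI}_i = \tfrac13(\mathrm{QuantRate}_i + \mathrm{QuantRate(Abs)}_i +
\mathrm{QuantRate(Amb)}_i)$$

and the overall **NGS applicability index** is the weighted arithmetic mean
of all ten indicators,

$$\mathrm{index}_i = \frac{\sum_{k=1}^{10} w_k\, x_{ik}}{\sum_{k=1}^{10} w_k},$$

with all weights 1 by default, so that with equal weights the index is
algebraically $(3\,\mathrm{MQI} + 3\,\mathrm{QQI} + \text{four remaining
indicators})/10$ — an identity the test suite asserts to $10^{-12}$.

Because full mapping counts partition (`unique + multi + unmapped = total`),
the per-sample identity `UnimapRate = MapRate + MultiMapRate − 1` holds
exactly; the quantification analogue is an inequality,
`QuantRate ≤ QuantRate(Abs) + QuantRate(Amb) − 1`, with equality exactly when
no failure category other than the two named ones is present.

## Numerical and design choices

Several choices are genuinely open in this kind of framework; the ones made
here, all configurable through `cohort_config()`:

* **Percentile convention.** "Percentile" is defined as
  $(\mathrm{rank}-1)/(n-1)$ with average ranks for ties, so the scaled values
  attain 0 and 1 exactly, which matches the stated 0–1 range of the
  indicators. An empirical-CDF convention ($\mathrm{rank}/n$) is available
  (`percentile = "ecdf"`). A single-species cohort has no meaningful
  percentile; it returns 1 with a warning rather than failing the run.
* **UngapRate degenerate case.** If no species has any spanned gap the
  formula is 0/0; the limit along equally gapless cohorts is 1, so an
  all-zero cohort scores 1 everywhere.
* **Species aggregation.** Per-sample rates are averaged unweighted
  (`aggregation = "mean"`) because cohort designs typically use equal-sized
  sample sets per species; pooling raw counts first is available
  (`"pooled"`). Samples whose summary dialect lacks unique/multi-mapped
  counts (samtools-stats) contribute only to the rates they inform; a rate
  with no informative sample is missing, never guessed.
* **Quantification denominator.** "Mapped reads" is the sum of all status
  categories except `unassigned_unmapped` — an unmapped read is a mapping
  failure, not an annotation defect. Unknown status categories stay in the
  denominator under their normalized names.
* **PCA form and sign.** PCA runs on mean-centered biotype *proportions*
  without variance scaling: the columns are commensurate (all proportions),
  so covariance PCA preserves the information that some biotypes vary much
  more than others. Correlation-form PCA is available (`pca =
  "correlation"`). The sign of PC1 is arbitrary; it is fixed so that scores
  correlate non-negatively with biotype richness (ties broken toward a
  non-negative loading on the lexicographically first biotype), making
  "more diverse annotation ⇒ higher score" a stable convention.
* **Shannon equitability.** $H/\ln S$ with $S$ the species' own count of
  positive-proportion biotypes; a single-biotype annotation scores 0 by
  convention. A fixed global $S$ (e.g. the 30-name vocabulary) is available
  (`shannon_s = "fixed"`), which penalizes absent biotypes rather than only
  unevenness.
* **Relative diversity.** Reported as the ratio of min–max-scaled
  diversities against a chosen reference species (default: the cohort's most
  diverse); this is one of several defensible normalizations and is labelled
  as such in the output.
* **Missing data.** The default policy is complete-case: a species missing
  any indicator is excluded from the ranking (and listed), mirroring how
  real cohorts shrink as artifacts are unavailable. Weight renormalization
  over available indicators is available and clearly labelled; the two
  policies answer different questions and are never mixed silently.
* **Biotype vocabulary.** The proportion matrix is built over the union of
  observed biotypes (zero-filled), seeded by a 30-name Ensembl-style
  vocabulary; unknown biotypes are kept verbatim rather than bucketed, so
  cohorts remain comparable without losing information.
* **Coordinates.** GTF intervals are 1-based inclusive; genic and exonic
  fractions use strand-ignored, per-sequence interval merging
  (`GenomicRanges::reduce`). When a GTF has no `gene` lines, gene spans are
  derived as the per-`gene_id` range over all feature lines; both encodings
  of an annotation give identical profiles.

BUSCO completeness and repeat fraction, when supplied as manifest columns,
are carried through as diagnostics only — they are never folded into the
index, since published assemblies are typically already optimized toward
BUSCO and it discriminates poorly between them.

## The synthetic cohort generator

Real inputs for a large cohort are hundreds of gigabytes of downloads;
`simulate_cohort()` instead writes a complete, parseable input set (manifest,
assembly TSVs, HISAT2-style alignment summaries, featureCounts-style
assignment summaries, toy GTFs) governed by two latent gradients on [0, 1]:

* a scalar **quality** latent `q` per species: spanned-gap counts fall
  (log-linearly, Poisson noise) and adjusted N50 rises with `q`; the
  uniquely-mapped share of reads (Dirichlet-multinomial, concentration 300)
  and the assigned share of quantified reads rise with `q`;
* an **annotation** latent `d` (defaulting to `q`, decouplable): the mean
  biotype composition interpolates from a protein-coding-dominated endpoint
  to a 30-biotype vocabulary with a geometric tail, with Dirichlet
  concentration rising in `d` — so richness *and* evenness grow with `d`, as
  they do between poorly and richly curated annotations; the no-feature
  failure share falls and the ambiguity failure share rises with `d`
  (denser annotation assigns more reads but creates more overlap
  ambiguity).

Genome sizes are log-uniform on 5×10⁷–2×10⁹ bp (the upper bound keeps GTF
coordinates within R's integer range), with default cohort sizes of 50
species × 10 samples — large enough for stable rank statistics, small enough
that the full validation pipeline runs in well under a minute.

What the generator does **not** emulate: real sequence content, aligner
version idiosyncrasies, phylogenetic correlation between species,
heteroscedastic library sizes, or any coupling between the toy GTF geometry
and the simulated read counts. Passing the latent-recovery tests therefore
shows that the scoring machinery faithfully recovers orderings *its inputs
encode*; it does not certify behaviour on any particular real cohort.

## Validation strategy

The test suite checks every formula against independent brute-force
arithmetic (1000 random fixtures, agreement to $10^{-12}$), the PCA against a
dense symmetric eigendecomposition (100 random matrices up to 50×30,
$10^{-8}$), interval merging against base-by-base enumeration, Shannon
entropy against `vegan`, and the full pipeline against (a) a shipped
three-species micro cohort whose complete indicator table was hand-computed
and frozen, and (b) the generator's latent gradients (Spearman rank
recovery). `scripts/acceptance.R` re-runs the pipeline computations from
scratch and writes the resulting quantities as JSON.

## Limitations

* Cohort-relative indicators change when the cohort changes: a species'
  AdjN50 percentile or diversity is only meaningful within the scored set.
* The index weights all indicators equally by default; this is a
  transparency choice, not an optimality claim.
* Alignment dialects beyond HISAT2-style paired summaries and
  samtools-stats `SN` reports are rejected explicitly rather than guessed.
* Transcript diversity measures *composition breadth* of an annotation, not
  its biological correctness; a fabricated annotation with many biotypes
  would score high on this one indicator (and be penalized by the
  quantification indicators instead).
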