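---
title: "Decontamination and core inference for low-biomass aerobiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decontamination and core inference for low-biomass aerobiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerocore)
```

## The problem

Air sampled in public transit stations is an extreme low-biomass
environment: a 30-minute filter capture yields nanograms of DNA, and a
large share of the reads in a shotgun library derive not from the air but
from reagents, extraction kits ("kitome") and handling. Before any
ecological statement can be made — diversity, between-city structure, a
"core" community — that exogenous fraction has to be identified and
removed, and every downstream statistic has to be computed in a way that
is robust to the heavy-tailed, sparse species profiles that remain.

`aerocore` implements the post-classification stage of such a study: it
consumes species-level read-count tables (Kraken2 report or Bracken table
dialects) and sample metadata, and carries them through contaminant
identification, abundance filtering, normalization, diversity and
multivariate covariate analysis, and prevalence-based core/sub-core
inference. A synthetic-data generator with planted ground truth makes
every stage testable end to end.

## Contaminant identification and the prevalence gate

Negative controls (field and laboratory blanks) are pooled: their beta
diversity does not support separating them. A taxon is called an
exogenous contaminant when

* it is present (count > 0) in **at least two** negative controls, and
* its **summed raw read count over all negatives exceeds 10,000**.

Both thresholds are evaluated on raw species-level counts, before any
abundance filtering — applying the within-sample abundance filter to the
sparse negatives first would hide exactly the evidence the rule needs.
The 10,000-read total is a sensitivity/specificity trade-off, not a
statistical test: raising it admits more contamination into the "core"
and inflates between-sample homogeneity. Both knobs are exposed as
arguments (`min_negatives`, `min_total_reads`).

Exclusion is deliberately aggressive (exclusion-first): a species that is
both a genuine air resident and a handling contaminant is still removed
from the abundance analyses. The correction happens at the core-inference
stage through the *prevalence gate*: for every taxon a one-sided
two-proportion Z test (pooled variance, no continuity correction,
`alpha = 0.05`, no multiplicity correction — each taxon is an individual
decision)

$$z = \frac{\hat p_{air} - \hat p_{neg}}
  {\sqrt{\hat p (1-\hat p)\left(\tfrac{1}{n_{air}} + \tfrac{1}{n_{neg}}\right)}}$$

asks whether its prevalence among air samples is significantly higher
than among negatives. Species failing the gate can never be core,
whatever their prevalence. Degenerate cases are flagged rather than
silently decided: equal proportions never pass; a taxon absent from all
negatives and present in every air sample passes as "trivially greater".

Candidate cross-contaminated samples (majority of embedding neighbours
from another city) are excluded only when two independent metadata
signals concur: a below-detection DNA concentration *and* a library-plate
position adjacent to the neighbour city. Ordination candidacy alone
always retains.

## Filtering, normalization, transformation

The pipeline order is fixed and enforced through a `transform` tag on the
table container:

1. species-level counts → **0.005% within-sample abundance filter**
   (counts below `5e-5` of the sample total are zeroed; totals are taken
   before zeroing, which makes the filter idempotent; values exactly at
   the cut are kept — the boundary choice is tested explicitly),
2. **contaminant removal**,
3. **normalization to 10,000,000 reads per sample**,
4. **log10(x + 1)** (pseudocount of one read). The log base is
   a presentation choice — no downstream decision is rank-sensitive to
   it — and natural-log Shannon is computed from proportions anyway.

Normalization to a fixed total (rather than rarefying or marker-gene
scaling) is appropriate for a community that is largely uncharacterized;
no genome-size correction is attempted.

## Diversity and covariate analysis

Alpha diversity is the Shannon index (natural log, via `vegan`). Group
differences between cities/years use Tukey's HSD on an ANOVA fit
(Tukey–Kramer for the unequal city sample sizes) with a compact letter
display assigned by the insert-and-absorb procedure; two groups share a
letter exactly when their difference is not significant, and the test
suite checks that equivalence against a from-scratch studentized-range
computation.

Beta diversity is visualised with UMAP (delegated to the reference
umap-learn implementation; `n_neighbors = 15`, `min_dist = 0.1`, fixed
`random_state`). Random initialisation is used because spectral
initialisation is not reproducible when the nearest-neighbour graph is
disconnected — the normal situation for strongly city-clustered
communities. A PCA embedding is available as a fully in-process
alternative.

For covariate significance the top 10 PC scores of the log table are the
dependent variables. Temperature (25&nbsp;°C), relative humidity (65%)
and traveller count (100) are binarised at thresholds chosen to produce
comparably sized groups (boundary values fall in the low class).
Candidate terms — CITY, YEAR, the binarised covariates, GROUNDLEVEL, and
CITY interactions for the environmental terms — enter a forward-stepwise
MANOVA: at each step every remaining candidate is added to the current
model, its partial Pillai trace
$V = \mathrm{tr}\!\left(H (H+E)^{-1}\right)$ is computed from the drop in
residual cross-products, converted to an approximate F, and the candidate
with the largest F enters if `p < 0.001`. Partial (rather than
sequential) tests are used because term order is data-driven; interaction
terms obey marginality (CITY:X is eligible only after CITY and X).
Complete cases are taken once over all candidate covariates, so every
candidate is compared on the same rows — dropping rows per term would
make the step-wise F values incomparable. In the univariate limit the
Pillai trace reduces to the hypothesis R²; the implementation is
cross-checked against `summary.manova` in the tests.

## Core and sub-core inference

A species is *present* in a sample at abundance level $L$ when its
within-sample relative abundance (on the decontaminated, filtered raw
counts — depth-invariant by construction) is $\ge L$; levels 0.005%,
0.3%, 0.5% and 1% are evaluated. Prevalence is the fraction of samples
with presence. Tiers:

* **core**: prevalence strictly > 0.97 *and* the Z-gate passes,
* **sub-core**: prevalence in the closed interval [0.70, 0.97] and gate
  passes (0.97 itself is sub-core, reconciling "> 97%" with "70–97%"),
* **none** otherwise.

Local (per-city) cores recompute prevalence within each city's air
samples; the gate is computed once against the pooled negatives, which
are not city-specific. The whole analysis can be rerun on the subset of
samples with Nonpareil coverage strictly above 50% to probe undersampling
effects. The contaminant inventory itself is tiered the same way (without
the gate, across all samples before removal), yielding a reusable
core/sub-core contaminant table. Mean abundance is averaged over all
samples, zeros included; report rows are ordered by prevalence, then mean
abundance, then taxid.

## The synthetic generator

`generate_synthetic()` emulates the classified count tables downstream of
taxonomic classification — not reads, not sequencing error:

* a shared contaminant profile (lognormal abundances, per-sample
  Dirichlet jitter) makes up ~97% of every negative control, the rest
  being a sparse air-species background (`negative_background_fraction`,
  default 3%, the residue real blanks retain);
* each air sample mixes that contaminant profile at a Beta-distributed
  read fraction (mean 0.627, the study-scale contaminant load) with a
  city profile: a shared species pool plus city-specific species at a
  configurable fold;
* per-city *core* species are planted with a relative-abundance floor
  (default 1%) and occupancy 1, so they satisfy the core definition by
  construction; all other pool species are transient
  (`species_occupancy`, default 0.6), mirroring the dominance of
  low-prevalence taxa in real aerobiomes and keeping the planted core
  the *only* core;
* depths are lognormal (default median 1e6 classified reads; negatives
  10× shallower), counts multinomial; metadata covariates (temperature,
  humidity per city, ground level per locality, plate positions,
  Nonpareil coverage tied to depth) give the covariate analyses signal
  to find; an optional humidity effect multiplies a subset of shared
  species in high-humidity samples;
* a configurable subset of contaminants is also genuinely present in the
  air pool — the hard case the prevalence gate exists for.

Defaults are 6 cities × 3 years × 14 samples (252 air samples) with 22
negatives and 60 contaminant taxa: the study's structure at a size every
analysis completes on in seconds. One RNG stream is seeded from
`config$seed`; the draw order (taxa, profiles, per-sample loops) is fixed
so determinism survives refactoring.

What passing on synthetic data does *not* show: real classified tables
carry database misclassification, strain-level roll-up artefacts,
genome-size bias and correlated (not Dirichlet-independent) contaminant
fluctuations. Recovery results here validate the *logic* of the pipeline
— thresholds, gates, tiering, selection — not classifier accuracy.

## Numerical and degenerate-input choices

* Counts are integers on input; merge conservation is exact integer
  arithmetic. Fractional transforms produce tagged tables so raw and
  normalized values cannot be mixed.
* Zero-total samples stay all-zero under normalization and are flagged;
  prevalence and Shannon refuse them loudly.
* Z tests with pooled proportion 0 or 1 are flagged degenerate, never
  NA-propagated into gates.
* Singular error structure in the MANOVA names the offending term;
  candidates with fewer than two observed levels are skipped and
  reported.
* Species ties in abundance rankings break by ascending taxid;
  letter columns are absorbed deterministically in descending-mean
  order.

## Problem sizes

The test suite and the acceptance script run the generator at 72–288 air
samples with 120–540 taxa — sizes chosen so the planted effects are
comfortably identifiable and the whole suite completes in about a minute
— and the bundled survey reference tables exercise the bookkeeping at
the published scale (750 air samples, 3577 species, 290 contaminants).

## Known limitations

* The Bracken table dialect carries no lineage, so kingdom annotation
  requires a side table (Kraken2 reports are parsed for domain/kingdom
  context).
* No frequency- or correlation-based contamination model is provided;
  the negatives rule plus gate is the method under study.
* BIOM/HDF5 containers, FASTQ handling and rarefaction are out of scope.
* UMAP requires a Python interpreter with umap-learn on the PATH; the
  PCA embedding is the dependency-free fallback surface for the same
  downstream operations.
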