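---
title: "Peptidomic profiling of digestion kinetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptidomic profiling of digestion kinetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdigest)
```

## The problem

Feeding an intact protein and a pre-hydrolysed version of the same protein
produces gastrointestinal digests that differ in peptide size, in which
parent-protein regions survive, and in the speed with which amino acids
reach plasma. `pepdigest` analyses such experiments at the peptidome
level: its inputs are tables of MS/MS-identified peptides (sequence,
intensity, substrate, sampling time, animal) and mature reference protein
sequences; its outputs are positional coverage profiles, size and count
summaries, terminal cleavage logos, multivariate sample discrimination,
and a plasma time-course comparison. Because raw MS data for this kind of
study are often unavailable, the package also contains a first-class
synthetic generator that plants the expected qualitative structure, so
every stage has testable ground truth.

## Coordinates and mapping

All positions are 1-based inclusive coordinates on the **mature** protein
(signal peptide removed). This is the convention in which casein-derived
bioactive peptides are universally reported — β-casomorphin-7 is β-casein
60–66, and mature β-casein has 209 residues so its C-terminal domain is
193–209. The bundled references are the canonical variants of the four
major bovine caseins (one variant each; which genetic variants a given
identification database contained is rarely reported, so the canonical
entries are used and recorded in `source_accession`).

Mapping is **exact substring search**, not scored alignment: search-engine
identifications are exact sequences, and "aligning" them to the parent
only means locating them. All occurrences, including overlapping ones, are
reported in deterministic order (protein order, then ascending start).
Two policies are deliberately exposed because published analyses rarely
state them:

* `equate_ile_leu` (default off): MS cannot distinguish Ile from Leu, but
  search output is already committed to one residue; turning this on
  canonicalises I→L on both sides.
* `multi_match_rule` (default `report_all`): a peptide matching several
  loci (caseins share short motifs) is expanded into one flagged copy per
  locus; `unique_only` drops such peptides instead. The mapping report
  conserves records (`input = unambiguous + ambiguous + unmapped`), so no
  observation is silently lost.

Missing intensities become an occurrence weight of 1 (flagged), which lets
count-only tables flow through the same code paths; non-numeric intensity
text is a row validation failure, not a missing value.

## Profiles, sizes, counts

The residue profile is the core descriptive statistic: for position *p*,
the sum of intensities of all peptides overlapping *p* (intensity mode),
or the number of overlapping peptides (occurrence mode). Animals within a
(substrate, time) sample are pooled by summation — the simplest reading
consistent with "sum of intensities of all overlapping peptides" — and an
optional per-row normalisation is available in `profile_matrix()` because
it is usually unstated whether published area plots were normalised per
sample. The conservation identity
`Σ_p profile[p] = Σ_peptides intensity × length` holds exactly and is
enforced by tests.

Size distributions count **unique sequences** per length bin. The default
bins (2–5, 6–9, 10–14, ≥ 15 residues) bracket the size classes usually
discussed for digests; the exact binning of published figures is rarely
stated, so bins are configurable.

Count summaries reproduce the arithmetic of per-time count tables: per
time point, the number of unique sequences seen in ≥ 1 animal and the
number seen in all `n_animals`; the "Total" row is the **sum over time
points**, not a deduplicated union (the union is available separately as
`dedup_union()`, because both quantities are legitimate but different).

## Terminal logos

The logo matrix gives amino-acid probabilities at peptide positions
N1–N3 and C−3–C−1. Positions are taken as residues 1..3 and L−2..L, so a
length-5 peptide's middle residue contributes to **both** N3 and C−3 —
the stated convention for five-residue peptides in this field, rather than
the more common exclude-short rule. `min_length` defaults to 5 because
ion-trap MS/MS setups typically cannot identify shorter peptides.
Probabilities are plain frequencies: no pseudocounts, no
information-content scaling, and no letter-height rendering — the matrix
is the product.

## Multivariate discrimination

The PCA feature matrix has one row per (substrate, time) sample and one
column per residue of every included protein; each cell is the residue
intensity profile value, so the matrix is exactly the horizontal
concatenation of the per-protein profile matrices. Defaults are column
mean-centering **on** and unit-variance scaling **off**: intensities share
one meaningful scale across residue features, and scaling would inflate
barely-covered positions. Zero-variance columns are dropped (with a
message) only under scaling, where they are undefined. Components come
from a singular value decomposition; a fixed sign convention (each loading
vector's largest-magnitude entry is positive) makes results reproducible
across platforms. With all components retained, the centered matrix is
reconstructed from scores and loadings to 1e-8, and explained ratios equal
the covariance eigenvalue ratios — both checked against a dense
eigendecomposition oracle in the tests.

Clustering operates on the peptide-level matrix, filtered to peptides
present (intensity > 0) in at least `min_presence = 2` time points. The
filter's scope is genuinely ambiguous in published descriptions — within
substrate or across the whole experiment — so both are implemented;
**within-substrate is the default** (a peptide qualifying in either
substrate keeps its column) because the filter's purpose is to remove
one-off identifications, and a peptide reproducibly present in one
substrate is not a one-off. Intensities are log10(1 + x)-transformed by
default: MS intensities span decades, and raw distances would be dominated
by a handful of abundant peptides. Distance and linkage default to
Euclidean/Ward; the desktop tool historically used for such heatmaps does
not document its settings, so these defaults are a robustness choice and a
stated reproduction caveat, with correlation distance and
average/complete/single linkage available. Correlation distance for a
zero-variance row is undefined; such rows are assigned the maximal
distance 2 to every other row rather than erroring. Agglomeration is
delegated to `stats::hclust` and cross-checked against a naive O(n³)
Lance–Williams oracle; merge-height ties are measure-zero for continuous
intensities, so tie-breaking is not load-bearing. The leaf order reported
is `hclust`'s native ordering.

## Plasma ANOVA

Each analyte is analysed separately: a fixed-effects two-way ANOVA
(substrate × time) on a balanced design, followed by per-time substrate
contrasts using t statistics on the pooled error term. The Bonferroni
family is the set of sampled time points of that analyte (9 on the
standard grid −15, 5, 20, 45, 60, 120, 180, 240, 360 min, basal included),
matching the per-analyte star annotations used on such curves; adjusted
p = min(1, raw p × family size), starred at 0.05 and 0.01. Two deliberate
simplifications, both flagged here: the feeding design is a crossover
(each animal receives both substrates) but **animal is not modelled** —
the plain two-way ANOVA is the procedure conventionally reported for these
curves; and unbalanced designs are rejected rather than patched with
Type II/III sums of squares. Empty cells and sub-2 replication are
errors naming the offending cell.

## The synthetic generator

`simulate_digest()` cuts each peptide bond independently with probability
proportional to a per-residue cleavage weight, rescaled so the expected
cut fraction equals `hydrolysis_extent`; fragments between consecutive
cuts are observed if their length falls in `[min_len, max_len]`. What the
defaults emulate, and why:

* **Cleavage weights**: 1.0 after F, L, W, Y, E (the pepsin P1
  preference), 0.01 after proline, 0.2 elsewhere, with a ×0.05 penalty
  when the following residue is proline. The moderate baseline reflects
  that duodenal digests have also seen the broad-specificity pancreatic
  proteases; a single P1-preference vector (no full position-specific
  matrix) keeps the model transparent. Duodenal digestion is represented
  by raising `hydrolysis_extent`, not by a second enzyme pass — the
  downstream analysis consumes peptide tables agnostic to enzyme history.
* **Extents**: 0.15 for the casein-like arm (intact casein reaches the
  duodenum only partly degraded), 0.45 for the hydrolysate-like arm
  (6 h of pre-hydrolysis plus digestion), in `simulate_study()`.
* **Protection**: the casein arm protects β-casein 193–209 by ×0.1,
  planting the well-documented pepsin resistance of that domain; the
  hydrolysate arm does not, planting the contrast that profiling must
  recover.
* **Observability window** `[5, 40]`: identification floors of five
  residues are typical for ion-trap MS/MS.
* **Intensities**: each generating locus draws a base log-intensity once
  (log-normal, meanlog `log(1e6)` arbitrary units, sdlog 0.7) and every
  emission multiplies it by the fragment's production probability under
  the cut model, with within-sample log-noise of 0.3. The per-locus base
  is the key realism ingredient: a peptide's MS response is chiefly a
  property of the peptide (abundance × ionisation efficiency), which is
  what makes intensity profiles reproducible across samples and lets PCA
  and clustering separate substrates, as they do on real data. Coupling
  intensity to production probability makes resistant-region fragments
  dominate profiles the way they do in real digests.
* **Design**: 6 animals, sampling times 5–150 min, per-sample cap of 150
  fragments per animal; the defaults yield 200–500 unique peptides per
  (substrate, time) sample, the magnitude reported for such experiments.

`simulate_plasma()` is additive: substrate-specific mean curve + per-animal
offset + Gaussian noise, truncated at zero. The default curves peak
earlier and higher for the hydrolysate before 200 min and converge by
360 min. With zero noise and offsets the emitted values equal the curves
exactly, which the tests use as the degenerate case.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic/ionisation biases beyond the
static per-locus term, missing identifications and chimeric spectra,
between-animal correlation in cleavage (cut sets are i.i.d. across
animals, so far fewer peptides are "common to all animals" than in real
tables), endogenous-protein background, within-substrate kinetic drift
(real late time points drift away from early ones; simulated samples of a
substrate are exchangeable), and genetic-variant heterogeneity. Recovery
results on simulated data demonstrate algorithmic correctness, not
biological effect sizes.

## Numerical and testing choices

Determinism: every simulation is reproducible from an integer seed; the
two arms of `simulate_study()` use `seed` and `seed + 1`. Per-bond cut
probabilities are capped at 0.995 so production probabilities stay finite.
Profile accumulation uses a difference-array (exact for the additive
identity); logo columns sum to 1 within 1e-9; PCA oracle agreement is
asserted at 1e-8. Test problem sizes are chosen to exercise the
mathematics at desk scale: 1 000 random peptides for the mapping oracle,
20 random matrices for the PCA oracle, n ≤ 12 for the O(n³) clustering
oracle, 100 small simulated peptidomes for the conservation identity, one
full-design simulated study (6 animals × 10 times × 2 substrates) for
planted-structure recovery, and 2 000 null replicates for the ANOVA
type-I calibration (expected rejection rate 0.05 at α = 0.05, asserted
within [0.040, 0.060]).

## Known limitations

* Exact matching only: modified residues, mismatches and mass-based
  rescue are out of scope.
* The count-table "common to all animals" statistic is computed
  correctly, but the simulator's i.i.d. cut model under-produces such
  peptides relative to real digests.
* The ANOVA ignores the crossover structure; a mixed model with animal as
  a random effect would be the stricter analysis.
* The dendrogram reproduces clustering, not the seriation/permutation
  optimisation of dedicated heatmap tools.
* Quantitative size-distribution shares depend on simulator settings;
  only the direction of the casein-vs-hydrolysate contrast is a designed
  (and tested) property.
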