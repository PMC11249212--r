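---
title: "Repertoire metrics and lymphoma classification: models and design choices"
author: "lymphrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire metrics and lymphoma classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphrep)
```

## The problem

B cell lymphomas carry a clonal immunoglobulin heavy-chain (IGH)
rearrangement, and the composition of the IGH repertoire sequenced from
lymphoma-infiltrated tissue differs systematically between entities: chronic
lymphocytic leukemia (CLL) and diffuse large B cell lymphoma (DLBCL)
repertoires are dominated by the malignant clone, nodular lymphocyte
predominant B cell lymphoma (NLPBL) sits on a large background of
non-malignant bystander B cells, and healthy-donor (HD) blood is polyclonal.
`lymphrep` turns per-sample clonotype tables into repertoire metrics and
fixed-length feature vectors, and trains interpretable classifiers (ridge
multinomial logistic regression, random forest) to discriminate these four
groups.

## Ingestion rules

A clonotype is a unique CDR3 nucleotide sequence. Records are read from
AIRR Rearrangement TSVs; non-productive records and records with fewer than
2 reads are discarded **at the record level, before collapsing** — the
threshold could equally be applied to collapsed clonotype counts, but the
record-level reading is the more literal interpretation of a read-count
filter and is what `filterRecords()` implements. Collapsing by CDR3
nucleotide sequence sums read counts, takes V/D/J calls from the
highest-count member (allele suffixes stripped at `*`; `/OR` orphon names
kept verbatim; ambiguous comma-separated calls resolve to the first gene)
and averages V-gene germline identity weighted by read count — the
representative values are dominated by the true clone's reads, which is the
intended behaviour for near-monoclonal samples.

A clonotype is called somatically hypermutated when its V-segment germline
identity is at most 98% — the boundary is inclusive, so 98.0 is
hypermutated and 98.01 is not.

## Repertoire metrics

For a fraction vector $p$ with richness $S$ (number of clonotypes):

* Shannon diversity $H' = -\sum_i p_i \log_2 p_i$ (bits; base 2 throughout,
  forced by the evenness definition below);
* Pielou's evenness $J = H' / \log_2 S$;
* clonality $= 1 - J$, so 1 means a monoclonal sample and 0 a perfectly
  even repertoire;
* SHM fraction = proportion of *clonotypes* (not reads) called
  hypermutated, plus the same proportion over the 10 most frequent
  clonotypes.

For $S = 1$, $\log_2 S = 0$ leaves $J$ undefined; the package adopts the
convention $J = 0$, clonality $= 1$, which is the natural limit (a sample
comprising a single clonotype is maximally clonal). Raw read counts are
used without rarefaction or depth normalisation; the
`metricReadCountCorrelation()` helper exists precisely to verify that the
metrics are not materially driven by depth. Group comparisons use
two-sided Mann–Whitney U tests at $\alpha = 0.05$ without multiple-testing
correction, matching the descriptive use of these comparisons.

## Featurization

Each repertoire maps to `n` clonotype slots in fraction-descending order.
One slot holds: clonotype fraction, CDR3 length, the ten Kidera factors of
the CDR3, and one-hot V/D/J blocks. Four repertoire-level features
(clonality, Shannon, richness, SHM fraction) are appended; total width is
$n(12 + |V| + |D| + |J|) + 4$. Design points that were genuinely open:

* **CDR3 length is amino-acid length**, consistent with the amino-acid
  basis of the Kidera factors (nucleotide length would be ~3x plus
  frame effects and carries the same signal).
* **Kidera aggregation is the arithmetic mean over residues**, the
  standard peptide-level use of these scales.
* **The SHM fraction is part of the repertoire block**: it is one of the
  repertoire-level descriptors the models are meant to see, and it ranks
  among the stronger predictors on synthetic cohorts.
* **Vocabularies are learned from the training split only** and unseen
  genes encode as all-zero one-hot blocks, so the schema cannot leak
  test-set information.
* **Zero padding stays exactly zero under scaling.** Standardisation
  parameters (mean/sd per numeric column; one-hot columns untouched;
  zero-variance columns get scale 1 and therefore map to 0) are fitted on
  training vectors, and padded slots are re-zeroed after scaling. The
  alternative — scaling padded entries like real ones — would turn "absent
  clonotype" into a nonzero pseudo-value that differs between columns.
* Scaling itself is a boolean hyperparameter searched by the grid.

## Training protocol

The cohort is split 80/20 by a stratified rule: total test size
$\lceil 0.2 N \rceil$, per-class seats by proportional floor with
largest-remainder assignment (ties to the larger class, then class-name
order). On class sizes (291, 90, 182, 348) this reproduces test counts
(58, 18, 37, 70) and train counts (233, 72, 145, 278) exactly.

Class imbalance is handled by random oversampling of every class except the
majority class. Oversampling is applied **after** the split and **inside
each cross-validation training fold** — folds are formed on the original
training samples, so a duplicated sample can never appear on both sides of
a fold boundary. Model selection is a grid search under stratified 3-fold
cross-validation scored by support-weighted F1, averaged over folds, ties
broken by grid order; the winning setting is refit on the full
(oversampled) training set and evaluated once on the untouched test set.
Per-class precision/recall/F1 use the zero-division $\to$ 0 convention with
an explicit flag.

Model families and default grids (conventional small grids; the search
space is a free choice of this package): ridge multinomial logistic
regression (`glmnet`, $\lambda \in \{0.01, 0.1, 1, 10, 100\}$, scaling
on/off) and random forest (`ranger`, trees $\in \{100, 300, 500\}$, max
depth $\in \{\text{unlimited}, 10, 30\}$, scaling on/off). The schema
vocabulary is built once on the outer training split rather than per fold;
only scaling statistics are refit per fold. Vocabulary membership is a
much coarser statistic than column means, and refitting it per fold would
change the feature space between folds.

## Interpretation

PCA (internal centering, no scaling) supplies a 2-D embedding with a fixed
sign convention (largest-magnitude loading positive) for reproducibility.
Group means in the embedding are compared by MANOVA using Wilks' lambda —
run on the first two principal-component scores, i.e. on the space actually
visualised, not on the raw features; a singular within-group covariance is
flagged as degenerate rather than raised. Predictors of the logistic model
are ranked by mean absolute coefficient across classes (ties by feature
name), with signed pairwise class contributions
$\beta_a - \beta_b$; for forests, impurity importances are reported and
labelled as such.

## The synthetic cohort generator

The generator exists so the entire pipeline can run and be validated
without patient data. Per class it draws richness $S$ uniformly from a
range, a top-clone fraction from a Beta law, bystander mass from a
symmetric Dirichlet, read counts from a multinomial over the resulting
fractions (clonotypes falling under the 2-read floor are dropped and
fractions renormalised, mirroring the ingestion filter so written cohorts
round-trip exactly), biased V/D/J calls, Gaussian CDR3 lengths clamped to
5–32 aa, uniform-random CDR3 peptides with a fixed-codon back-translation,
and a germline identity from a two-component mixture: hypermutated
clonotypes uniform on [90, 98] (inclusive at 98), unmutated uniform on
[98.5, 100]. The gap (98, 98.5) is deliberately never generated, so the
generative hypermutation label coincides exactly with the ≤ 98% call and
each preset's `shmProbability` is recoverable in expectation through the
full calling path.

Default presets encode the qualitative cohort structure: SHM probabilities
HD 0.192, NLPBL 0.184, DLBCL 0.449, CLL 0.224; mean top-clone fractions
roughly 0.05 / 0.35 / 0.75 / 0.9 and richness ranges 2000–5000 / 500–2000 /
50–500 / 10–200 for HD / NLPBL / DLBCL / CLL; IGHV4-34 up-weighted in
NLPBL and DLBCL and IGHV1-69 (with IGHJ6) in CLL. Dominance and richness
values are calibration stand-ins chosen once to reproduce the qualitative
orderings (clonality CLL > DLBCL > NLPBL > HD, HD most diverse); the true
per-class dominance distributions are not publicly tabulated. Total reads
(200k HD, 100k otherwise) are typical amplicon depths and keep the 2-read
floor from biting on polyclonal samples.

What the generator does **not** emulate: lineage structure or realistic
placement of hypermutations (identity is sampled, not computed from
alignments), shared/convergent clonotypes between samples, primer or
amplification bias, and sequencing error. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly under the
assumed generative structure — not that the classifier will achieve any
particular accuracy on real cohorts.

Seeds: a master cohort seed maps to per-sample seeds through a stable
integer hash of (seed, sample index) (two MINSTD multiplier rounds modulo
$2^{31}-1$), so regeneration is platform- and order-independent; every
stochastic stage (split, folds, oversampling, forest fitting) derives its
own stream the same way.

## Numerical conventions and degenerate inputs

Fraction vectors must sum to 1 within 1e-6 on input and hold within 1e-9
inside `Repertoire` objects; clonality is clamped to [0, 1] against
floating-point residue; ties in clonotype ordering break by read count then
CDR3 byte order (C locale, platform independent); an empty repertoire after
filtering is an error, as is a fold count exceeding the smallest class.

## Problem sizes used in the validation suite

The test suite validates the generator's calibration with 500 repertoires
per class (Monte-Carlo tolerance ±1.5 percentage points on the cohort mean
SHM percentage) and the end-to-end pipeline with 100 samples per class at
n = 3, where the default presets are comfortably separable (test weighted
F1 ≥ 0.9) and an all-identical-preset cohort scores in the chance band
(0.25 ± 0.1 for four balanced classes). Unit tests use smaller, faster
presets with the same dominance contrasts.

## Known limitations

* Identity-based SHM calling inherits the resolution of the upstream
  aligner; the package treats the reported identity as ground truth.
* The feature layout grows linearly in n; at n = 100 with rich training
  vocabularies the design matrix is wide relative to typical cohort sizes,
  and the ridge penalty is doing real work.
* Coefficient-magnitude rankings compare features on heterogeneous scales
  unless scaling was selected by the grid; rankings are most interpretable
  for scaled models.
* `EvaluationReport` confusion matrices are computed on a single held-out
  split; no confidence intervals are attached.
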