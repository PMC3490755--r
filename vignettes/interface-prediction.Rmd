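---
title: "Predicting protein-RNA interface residues: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-RNA interface residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaiface)
```

## The problem

Given a protein chain known (or suspected) to bind RNA, which of its amino
acids form the binding interface? When a complex structure exists the answer
is geometric: a residue is an *interface residue* if any of its atoms lies
within a cutoff distance of any RNA atom. The interesting problem is
prediction from information that is available without the complex — the
sequence, its evolutionary profile, and optionally the unbound structure —
and, just as important, *fair measurement* of how well such predictors work
on heavily imbalanced residue data. This package implements both halves:
the labeling/benchmark machinery and two classical classifier families.

## Interface labeling

`label_interface()` labels a residue 1 when its minimum atom-to-atom
Euclidean distance to the pooled atoms of all RNA chains in the complex is
at most the cutoff (default **5 Å**; 3.5 Å is the other definition in common
use, and the package treats the cutoff as a parameter precisely because the
choice moves every downstream metric). Distances use every atom present in
the coordinate file by default; a heavy-atom-only policy is available for
comparison with methods whose definitions exclude hydrogens — coordinate
files of typical crystallographic resolution rarely contain hydrogens, so
the two policies coincide on most real inputs.

Residues of the full-length sequence that are missing from the solved
coordinates are retained, flagged unsolved, and labeled non-interface —
nothing can be measured for them. This gives the two dataset variants:
*sequence data* (all residues) and *structure data* (solved residues only).
By construction the interface counts of the two variants are identical and
their non-interface counts differ by exactly the number of unsolved
residues; `make_dataset()` enforces and tests this bookkeeping.

Solved residues are mapped onto the full sequence by exact substring match
of their one-letter string when it is unique, otherwise by a global identity
alignment (gap opening 0, extension 1, so gap placement is decided by
matches rather than by gap-merging economies) requiring at least 95%
identity over aligned residues. The numbering in coordinate files is
author-assigned and unreliable, which is why the mapping is sequence-driven.

## Feature encodings

All six encodings share one window parameter W (default **25**, the target
plus 12 residues on each side — wide enough to see a full binding patch,
small enough to train on hundreds of chains) and a dimension law:

* identity channels: 21 indicators per position (20 amino acids plus `X`
  for unknowns and padding) → 21·W features;
* PSSM channels: the 20 logistic-normalized profile values per position →
  20·W features (500 at W = 25);
* an optional auxiliary scalar channel (e.g. externally predicted solvent
  accessibility) appends W more.

Sequence windows pad beyond the termini; spatial windows take the W − 1
residues nearest by centroid distance (centroid = mean of heavy-atom
coordinates), with ties broken by ascending sequence position so encoding is
deterministic. The spatial window counts **W residues in total including the
target**, so all six encodings share one dimension law; the alternative
reading (target plus W nearest neighbors) differs only by one neighbor and
was rejected to keep the identity/PSSM feature lengths equal across the
sequence and spatial variants.

Smoothed PSSMs replace each position's 20 raw scores by the sum over a
window of **w = 3** neighboring positions (w = 5 would sum positions
i−2…i+2), positions beyond the termini contributing zero. Smoothing
operates on **raw scores, before logistic normalization** — summing
log-odds is the natural composition of evidence, and normalizing afterwards
keeps features in (0, 1); the alternative order (normalize, then sum) would
leave the (0, 1) range and is deliberately not used. Padding values are the
neutral choices: logistic(0) = 0.5 for PSSM features (the midpoint of the
squashing function), the `X` indicator for identity features, 0 for the
auxiliary channel and for smoothing sums.

## Classifiers

**Naïve Bayes** assumes feature independence given the class. Binary (0/1)
features get add-one Laplace-smoothed conditionals (k + 1)/(n_c + 2);
continuous features get per-class Gaussians with a variance floor of 1e−9
to survive constant columns. The decision rule is the posterior ratio test
P(C=1|x)/P(C=0|x) ≥ 1 — ties go to the interface class — and the ranking
score is the log posterior ratio, computed entirely in log space. Gaussian
treatment of the continuous PSSM features is itself a modeling choice (a
kernel-density or discretized variant would be defensible); it was chosen
for determinism and because the logistic-squashed features are unimodal in
practice.

**SVM** uses the standard soft-margin formulation with either the
polynomial kernel (x_i·x_j + 1)^p or the RBF kernel exp(−γ‖x_i − x_j‖²),
at fixed defaults **p = 1, γ = 0.01, C = 1.0** — the point of the framework
is comparing encodings under a common, untuned classifier, so there is no
hyperparameter search anywhere. The quadratic program is delegated to
libsvm (a solver contract, not a bespoke optimizer); the stored model keeps
the support vectors, dual coefficients α_i y_i and bias, and scoring
evaluates the dual expansion through the package's own kernel functions, so
serialized models are self-contained. Decision-value orientation is
normalized so that class 1 is always positive (libsvm orients by the class
it happens to see first). Training sets for the SVM are balanced by seeded
undersampling of the non-interface majority; test sets are never balanced.

## Evaluation conventions

Cross-validation is *sequence-based*: whole chains are dealt into k = 5
folds (seeded permutation, round-robin), so no window of a test chain can
appear in training. Two aggregations:

* **residue-based** — confusion counts pooled over all residues of a fold,
  metrics on the pooled counts, then an unweighted mean over folds. ROC/AUC
  are computed on the fold's pooled scores and averaged; a global pooling
  across folds is available behind a flag (the fold-averaged mode is the
  default because the fold is the unit of replication).
* **protein-based** — metrics per protein (with the degenerate conventions
  below), averaged over proteins within a fold, then over folds. This is
  the stringent view: one hard protein drags the average down even when its
  residues are few. Per-protein AUC is undefined for single-class proteins;
  those are excluded from the fold's AUC average and counted in
  `n_auc_excluded`.

Specificity here is TP/(TP+FP) — what most of machine learning calls
precision — and Sensitivity is TP/(TP+FN); both are reported for the
interface class. Degenerate conventions are fixed and tested: a predictor
with zero positive predictions gets Specificity 1, Sensitivity 0 and
F = MCC = 0; any zero denominator in F or MCC yields 0. The AUC is the
Mann–Whitney statistic with half credit for tied scores, which equals the
trapezoidal area under the ROC swept over distinct thresholds (ties
grouped, so results cannot depend on instance order). Methods are compared
across datasets by tie-averaged ranks (rank 1 = best, tied scores share the
mean of their positions); with only a handful of benchmark datasets a
Friedman test would not be sound, so none is offered.

The surface post-filter re-marks predicted interface residues as
non-interface when their relative solvent accessibility is **not strictly
greater than 5%**. RSA comes from NACCESS-style `.rsa` files when supplied;
otherwise a built-in Shrake–Rupley estimator samples each heavy atom's
probe-expanded sphere (probe 1.4 Å, 960 deterministic golden-spiral points
per atom, about 1–2% sampling error against a 10,000-point reference) and
divides residue SASA by fixed theoretical per-residue maxima. Numeric
parity with NACCESS is explicitly not promised; the estimator exists so the
filter works without external software. The chain is evaluated in
isolation (unbound accessibility). Residues with unknown surface status are
left untouched by the filter, since the rule demands positive evidence of
burial.

## The synthetic benchmark

`synthetic_spec()` defaults describe the study conditions used throughout
the tests: 20 chains of 50–70 residues, an 8-residue contiguous interface
patch, RNA placed 4.0 Å from patch residues and 12.0 Å from all others
(bracketing the 5 Å cutoff so labeling recovers the patch exactly), PSSM
noise σ = 1 with a δ = 2 mean shift on 5 fixed columns at interface
positions, and optionally a fraction of non-patch residues omitted from the
coordinates. Chains of 50–70 residues clear the 40-residue inclusion filter
while keeping the full 5-fold CV of all six encodings inside seconds; the
test suite labels, encodes and cross-validates roughly 1,200 residues per
benchmark. Every artifact derives its seed from the master seed by fixed
offsets, so benchmarks are byte-identical across runs.

What the generator emulates: the file formats (fixed-column PDB, FASTA,
PSI-BLAST ASCII PSSM), the geometry that drives distance labeling, unsolved
residues, and a class-conditional profile signal whose strength is a dial
(δ = 0 must give chance-level AUC; δ = 2 must be nearly separable). What it
does not emulate: real protein stereochemistry, sequence homology between
chains, the column structure of real PSSMs (signal sits in arbitrary fixed
columns), or realistic class imbalance dynamics across proteins. Passing
tests therefore demonstrate the correctness of the machinery and the
statistical behavior of the pipeline, not expected accuracy on real
protein-RNA complexes — real-data performance depends on profile quality
and homology structure the generator deliberately omits.

## Numerical and degenerate-input choices

* logistic normalization via `plogis` — monotone, overflow-free for any
  finite score.
* altloc handling: highest occupancy wins, ties to conformer `A`;
  multi-MODEL files use the first model; waters and unrecognized ligands
  are dropped; modified residues map to their parent amino acid (MSE → M
  etc.), unknowns to `X`.
* variance floor 1e−9 in Gaussian Naïve Bayes; Laplace add-one in the
  categorical tables; all likelihoods in log space.
* undersampling and fold assignment draw from a private RNG stream seeded
  per call, so package calls never disturb the caller's RNG state.
* residues with no heavy atoms are excluded from centroids and the spatial
  index, with a warning.

## Limitations

PDB fixed-column input only (no mmCIF, no multi-model NMR averaging);
PSI-BLAST is consumed as files, never run; sequence-identity redundancy
reduction is accepted as a precomputed chain list; no physico-chemical
feature channels; no probability calibration of SVM scores (ROC/PR consume
raw decision values, which is rank-equivalent). These are scope boundaries,
not accidents: each sits behind a module surface where an extension could
be added without touching the evaluation conventions.
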