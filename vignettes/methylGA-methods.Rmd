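---
title: "Nested genetic-algorithm feature selection for DNA methylation: models and design"
author: "methylGA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested genetic-algorithm feature selection for DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

methylGA implements a hybrid system for cancer methylomics: unsupervised
selection of CpG loci by a nested two-layer genetic algorithm, followed
by multilayer-perceptron classification of malignancy and cancer type.

## Beta values and preprocessing

The primary measurement is the per-locus beta value
$\beta_n = \max(M_n,0) / (\max(M_n,0) + \max(U_n,0) + \alpha)$, a
methylation proportion estimate in $[0,1)$; $\alpha > 0$ (default 100)
stabilises the ratio when both intensities are small, so $\beta = 0$
exactly when no methylated signal is detected and $\beta$ never reaches
1. `computeBeta()` clamps negative intensities to zero before forming
the ratio.

Cohort assembly transposes per-sample locus maps into a samples-by-loci
matrix (`assembleBetaSet()`), stored loci-by-samples in a
`SummarizedExperiment`-derived `BetaSet`. Preprocessing has two stages:

* **Rejection** (`filterSamples()`): a sample is dropped when its
  missing fraction strictly exceeds the platform threshold — 10% on 27k
  arrays, 20% on 450k arrays; custom platforms take an explicit
  threshold. The comparison is strict ("more than"), so boundary samples
  are retained, and it is computed on raw missingness before imputation:
  rejection removes a sample from training entirely, which is only
  meaningful pre-imputation.
* **Imputation** (`imputeMissing()`): per-sample linear regression on
  the locus index. Interior gaps reduce to linear interpolation between
  the flanking observed loci; leading/trailing runs are extrapolated
  from a least-squares line through the $k = 4$ nearest observed loci.
  Predictions are clamped to $[0,1]$ to preserve the beta-value
  invariant. Imputation is deliberately within-sample only: it is
  deterministic, order-free of the rest of the cohort, and cannot leak
  label information across samples. Array intensities do covary across
  samples at a locus, so cross-sample imputation could be more accurate;
  it is out of scope here.

## The inner layer: grouping GA with Calinski-Harabasz fitness

A partition chromosome is an ordered arrangement of the sample indices
cut into contiguous logical clusters (`ClusterPartition`). For a
partition of $n$ samples into $k$ clusters, on the currently selected
features only:

$$\alpha_c = \sum_{j=1}^{k} S_j \, D(\bar F_j, \hat F)^2, \qquad
\gamma_c = \sum_{h=1}^{k} \frac{1}{2 S_h} \sum_{F_a \in C_h} \sum_{F_b \in C_h} D(F_a, F_b)^2,$$

the size-weighted between-cluster dispersion and the pairwise form of
the within-cluster sum of squares ($D^2$ = squared Euclidean distance).
The fitness is the Calinski-Harabasz index

$$F_{CH} = \frac{\alpha_c}{\gamma_c} \cdot \frac{n - k}{k - 1},$$

higher is better. The normalization is written in its standard
orientation — samples minus clusters over clusters minus one — which is
the only orientation under which "higher is better" holds; `chFitness()`
is tested against an independent naive implementation. Internally both
terms come from cluster-sum sufficient statistics
($\gamma = \sum_i \lVert x_i \rVert^2 - \sum_j \lVert \sum_{i \in j} x_i \rVert^2 / S_j$),
which the suite verifies against the pairwise definition to $10^{-9}$,
together with the decomposition $\alpha + \gamma = $ total SSD.

Degenerate partitions ($\gamma = 0$: all singletons or duplicated
points) get an infinite sentinel fitness but are flagged, excluded from
elitism and given zero roulette weight — otherwise the objective
collapses to all-singleton partitions, the known fragmentation failure
of variance-ratio criteria. Single-cluster partitions score 0.

### Operators

* **Initialisation**: cluster count uniform on $2..\lceil\sqrt n\rceil$,
  uniform random arrangement, uniform random cut positions.
* **Selection**: roulette wheel on min-shifted fitness
  $w_i = f_i - \min_j f_j$; all-equal populations select uniformly.
* **Crossover (modified MPX, probability 0.30)**: in each parent the
  target is the cluster whose centroid lies nearest the overall centroid
  (the least-separated, most "central" cluster); a uniform within-cluster
  cut-off and uniform size select a substring, which is removed; the
  partner parent's surviving items are appended sequentially in the
  partner's relative order, grouped into one new cluster per contiguous
  run of partner clusters. Both symmetric offspring are evaluated and
  the fitter is kept.
* **Mutation (split/merge)**: gene-level, mirroring the outer layer's
  per-bit operator — every cluster is independently eligible for one
  event at rate $p = p_{max} \cdot \bar f / f_{best}$ on min-shifted
  fitnesses, capped at $p_{max} = 0.10$, so the rate rises as the
  population converges. A split event bisects a cluster of size
  $\ge 2$ at a uniform interior point after canonically reordering its
  members along their elongation (distance from the member farthest from
  the cluster centroid); the within-cluster encoding order carries no
  other semantics, and without this canonicalisation a random cut
  separates an arbitrary subset and almost never improves the Ward
  objective. A merge event fuses a uniformly chosen cluster with its
  nearest-centroid neighbour — "neighbouring" in Ward's data-space
  sense — relocating the absorbed block so clusters stay contiguous.
  These two readings were adopted after the literal encoding-order
  alternatives (chromosome-adjacent merges, unordered splits) left the
  inner GA unable to de-fragment partitions at desk scale: pure but
  fragmented clusters could never become adjacent in the encoding, so
  beneficial merges never fired.
* **Elitism**: the best individual is copied unchanged, making the elite
  fitness trajectory non-decreasing by construction.

The engine is compiled (Rcpp) and uses R's RNG, so runs are reproducible
under the configured seed; the exported R operators implement identical
semantics and the suite cross-checks the engine's returned fitness
against an R-side re-evaluation.

## The outer layer: binary feature-selection GA

A mask chromosome is a bit per platform locus (`FeatureMask`). The
outer GA's fitness is not computed independently: each mask's columns
are passed to a fresh inner-GA run and the converged best $F_{CH}$ is
retrieved as the mask's fitness (`evaluateMask()`), creating the
feedback between cluster separability and feature selectivity.
"Multiplying the features by the mask" is implemented as column
masking — the alternative reading (scaling fitness by the selected-feature
count) would reward selecting more features and contradict the observed
dimensionality reductions.

Operators: roulette selection, single-point crossover (tails swapped at
one uniform cut), adaptive per-bit flip mutation
$p = p_{max} \cdot \bar f / f_{best}$ capped at $p_{max} = 0.05$, and
elitism. Each generation every non-elite chromosome is evaluated by a
fresh inner run under a seed derived from (master seed, generation,
chromosome index) via a multiply-add hash modulo $2^{31}-1$
(`deriveSeed()`), so evaluations are independent and may run
concurrently (`threads > 1`, via forked workers) with results combined
identically to the sequential order. Elites carry their already-computed
record instead of being re-evaluated: re-scoring under a new seed would
make the recorded elite trajectory stochastic and break its
monotonicity.

Per-cancer-type masks are intersected bitwise (`commonFeatures()`); the
classifiers consume the intersection mask.

### Defaults and tunables

| parameter | default | note |
|---|---|---|
| outer generations | 100 | published setting |
| inner generations | 200 | published setting (per outer chromosome) |
| crossover probability (inner) | 0.30 | published setting |
| mutation cap (inner) | 0.10 | published setting |
| mutation cap (outer) | 0.05 | published setting |
| outer/inner population | 20 / 30 | not stated in the source method; desk-scale defaults |
| outer crossover probability | 0.9 | not stated; standard binary-GA value |
| initial mask density | 0.5 per bit | uninformative prior over loci |
| elite count | 1 | one elite per layer |

## Supervised stage

Two dense ReLU multilayer perceptrons with softmax outputs are trained
with mini-batch Adam using the original authors' defaults
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) and bias
correction ($\hat m = m/(1-\beta_1^t)$, $\hat v = v/(1-\beta_2^t)$);
the source equations omit the correction but invoke the optimiser "as
recommended", so the standard form is used. "Unselected features get
zero weights" is implemented as input masking, which is algebraically
equivalent to zeroing first-layer weight rows and directly testable:
outputs are a function of selected features only.

Unstated training details were fixed as: cross-entropy loss, batch size
32 (16 in the small pipeline default), up to 100 epochs with early
stopping on evaluation loss (patience 10) when an evaluation split is
supplied, He-style initialisation, stratified 70/30 train/test split
under a fixed seed. `gridSearch()` enumerates the published grid — three
learning rates (0.1, 0.01, 0.001), four base widths (512, 256, 128, 64),
three depths (1, 2, 4) — with deeper stacks halving the width per layer
(matching the reported two-layer optimum (256, 128)); ties break toward
fewer parameters, then the smaller learning rate.

## Evaluation suite

Confusion matrices (rows = truth), per-class one-vs-rest accuracy,
precision ($0$ with a flag when no positive prediction exists), recall,
F1; MCC in the binary closed form with the zero-denominator $\to 0$
convention, and the generalized $R_K$ coefficient for more than two
classes (it reduces exactly to the binary form at $K = 2$, which the
suite checks on 1,000 random tables). Per-class tables report
one-vs-rest accuracy alongside the overall accuracy because a per-class
"accuracy" is otherwise ambiguous in a two-class model. ROC curves
threshold at distinct score values with deduplicated points and
trapezoidal AUC; macro-AUC averages per-class AUCs (classes lacking both
a positive and a negative are skipped with a flag), micro-AUC pools all
(sample, class) indicator/score pairs into one curve. The AUC oracle in
the tests is the Mann-Whitney $U/(n_+ n_-)$ identity.

## The synthetic-cohort generator

`generateCohort()` emulates the features of array methylation data that
matter to this method: values in $[0,1]$, bimodal distribution across
hypo- and hyper-methylated states, a minority of label-informative loci
against a large uninformative background, and platform-style missing
values. Informative loci draw class modes at $0.5 \pm s/2$ (separation
$s$; every informative locus separates at least two classes), noise loci
share one mode (0.25 or 0.75) across classes; draws are beta-distributed
around the mode with concentration 30 by default (within-class SD
roughly 0.08–0.10, a realistic array-level spread). It does **not**
model probe chemistry, type-I/type-II probe differences, batch effects,
cell-type composition or chromosomal correlation — so passing tests
demonstrate that the algorithms recover planted structure of this kind,
not that they meet any accuracy level on real TCGA cohorts.

## Numerical choices and degenerate inputs

* Alpha/gamma are clamped at 0 against floating-point cancellation;
  degeneracy is declared at $\gamma \le 10^{-12} \cdot$ total SSD.
* Identical-sample datasets short-circuit to a flagged degenerate
  result.
* Masks are repaired to at least two set bits (a 1-bit space has no
  cluster geometry).
* Prediction ties resolve to the lexicographically first class name;
  grid-search ties to fewer parameters, then lower learning rate.
* All randomness flows from integer seeds through `deriveSeed()`'s hash
  chain (master seed to stage to replicate/chromosome), keeping every
  derived seed in R's integer range and making sequential and
  concurrent runs byte-identical.

## Problem sizes in the test suite

The suite runs desk-scale study conditions: synthetic cohorts of 500
loci (50 informative, separation 0.6, three classes of 20 samples) for
selection-recovery checks with the outer GA at 20 generations x
population 20 over an inner GA at 50 generations x population 20 across
five seeds; oracle equivalences on 100 random instances of up to 30
samples; operator conservation sweeps of 1,000 random parent pairs; and
a full pipeline determinism run on a six-cohort, 120-locus cohort. These
sizes exercise every code path while keeping the default `testthat` run
in the low minutes.

## Known limitations

* The inner GA is a stochastic optimiser: its converged $F_{CH}$ for a
  given mask varies across seeds, so outer-layer fitness is a noisy
  signal and selected masks vary between replicates
  (`replicateRuns()` quantifies this with a normalized 95% t-interval
  of the selected-locus counts).
* Feature selection assumes the cohort contains only samples with an
  established cancer history; mixing benign tissue into the clustering
  cohort changes what the cluster structure reflects.
* The multi-host networked convergence of the original software is out
  of scope; concurrency is single-host (forked workers) with a
  sequential-equivalence guarantee.
* Real-data preprocessing beyond the beta-value model (normalisation,
  probe filtering, IDAT parsing) is out of scope.
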