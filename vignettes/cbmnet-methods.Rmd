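---
title: "Network propagation and anti-cancer likeness: methods and design"
author: "cbmNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network propagation and anti-cancer likeness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmNet)
```

## The model

`cbmNet` predicts whether a small molecule behaves like an approved
anti-cancer drug from nothing but its protein targets and a protein–protein
interaction network. The key assumption is that compounds acting on a common
molecular network exert similar downstream effects, even when their direct
target sets barely overlap. Three ingredients implement it.

**Random walk with restarts.** The interactome is an undirected graph whose
scored edges are dichotomized at a confidence threshold; the transition
matrix is the row-normalized adjacency, `W[a, b] = 1/degree(a)`, with
self-loops on dangling nodes so each row sums to one. A compound's targets
define the restart distribution `p0` (uniform mass `1/k` over the `k`
targets that map onto the node list, as the targets enter unweighted). The
walk iterates

$$p_i = p_{i-1} W (1 - c) + c\, p_0$$

until the L1 change between iterates falls below a tolerance. Because each
update is a convex combination of two probability distributions, every
iterate sums to one, and the error contracts geometrically at rate
`1 − c`. The converged vector is the compound's genome-wide profile. The
fixed point also has the closed form `p* = c p0 (I − (1 − c)W)^{-1}`, which
the package solves with one sparse LU factorization; the two routes agree to
below 1e-8 and the iterative walker is checked against the solve in the test
suite. The closed form is used for batch work up to 5000 nodes; above that
its factorization memory is not worth it and the compiled iterative walker
takes over.

**Classifiers.** Propagated profiles of labeled drugs (anti-cancer vs
other, roughly 1:9) train two linear models. The linear SVM uses balanced
class weights (each class weighted by its inverse frequency) so the 1:9
imbalance does not flatten the separator. The Maximum Margin Criterion
projects onto the top eigenvectors of `Sb − Sw`, the difference of
between-class and within-class scatter; unlike Fisher's discriminant it
needs no inversion of `Sw`, which matters when genes outnumber compounds.
Scatter matrices use equal class priors, again to neutralize the imbalance.
Both models emit probabilities through a Platt-style logistic calibration
fit with regularized targets; inside cross-validation the calibration is
fitted on out-of-fold decision values so it never sees its own training
scores.

**Nested cross-validation and the ensemble.** Stratified 10-fold outer
cross-validation estimates each parameter setting's positive-class F score
(the natural criterion under heavy imbalance), while stratified 5-fold
inner cross-validation picks the classifier hyperparameter per outer fold.
When the hyperparameter grid has a single candidate the inner loop is
vacuous and is skipped, with calibration falling back to training decision
values. The final model per setting is refit on all data with the averaged
best hyperparameter — geometric mean for the SVM cost, which lives on a log
scale; rounded median for the MMC dimension. Models passing the selection
rule (F ≥ 0.84 by default, mirroring the operating point where a top-*n*
cut and the F cut coincide at full scale) form the ensemble; a compound's
anti-cancer likeness (ACL) is the arithmetic mean of the members'
calibrated probabilities, each computed in that member's own feature space.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| gene–gene threshold | grid {400, 600, 700, 800, 850, 999} | dichotomization cutoff on 0–999 confidence scores; 999 stands for unscored curated edges, which enter with the maximal score |
| compound–gene threshold | grid {0, 100, 200, 325, 400, 500, 600, 700} | filters target interactions before seeding |
| restart probability `c` | grid of 14 values, 1e-4 to 0.2 | diffusion depth; `c = 1` disables propagation |
| convergence tolerance | 1e-6 (L1), cap 10 000 iterations | unstated in the underlying method description; chosen so the remaining error `(1−c)/c · tol` is negligible for the grid's `c` range, with tighter values used when the walk is compared against the exact solve |
| log transform | on/off in the grid | `log(x + 1e-12)`; damps isolated non-propagating genes that keep a large mass; the epsilon guards exact zeros and its magnitude only shifts the zero bin |
| SVM cost C | inner-CV over {0.1, 1, 10} | log-spaced around 1 |
| MMC dimensions k | 1 | one margin direction suffices for a binary problem; exposed as a hyperparameter |
| ACL threshold | 0.7 (strict `>`) | defines a cancer-beating molecule |

## The synthetic benchmark

Real runs of this method consume millions of scored interactions and
thousands of compounds from curated databases. The package's generator
emulates that structure at desk scale with known ground truth: a
planted-partition interactome (default 500 genes, a 40-gene module wired at
density 0.3 against a 0.01 background, spanning chain added outside the
module so the graph is connected), module edges drawing higher confidence
scores than background edges from overlapping normal distributions (means
800 vs 480) so the threshold grid has a detectable optimum; 100 positive
compounds drawing 70 % of their 20–30 targets from the module and 900
negatives drawing uniformly (the 1:9 imbalance of approved drug labels);
uniform integer target scores in 100–999 so the compound–gene thresholds
bite. A food map assigns mixture compounds (positive-like vs negative-like
samplers) to foods with linearly declining positive-like fraction, planting
a CBM-richness ordering. All randomness flows from a single spec seed
through per-stage substreams, so any stage regenerates identically on its
own.

What passing tests on this benchmark show — and what they do not: the
pipeline recovers a planted, strongly modular signal essentially perfectly
(mean outer F1 near 1, module genes filling the top importance ranks), and
collapses to the analytic random baseline `2pq/(p+q)` when labels are
permuted. Real interactomes are scale-free, noisy and incomplete, real
anti-cancer drugs are far less cleanly module-targeted, and measured
performance there is correspondingly lower; the synthetic results validate
the machinery, not the biological effect size. Bioavailability,
concentration and interaction directionality are likewise outside the
model.

## Numerical and design choices

- **Convergence norm** is L1; the update contracts L1 distance by exactly
  `(1 − c)` per iteration, so successive-difference stopping gives a clean
  a-priori error bound.
- **Thresholds compare with `>=`**, keeping threshold 0 as the keep-all
  case of the printed grids.
- **Dangling nodes** are retained with self-loops rather than dropped:
  probability is conserved and node indexing stays identical across
  thresholds, so models trained at different thresholds share a feature
  space.
- **Node ordering** is lexicographic over gene ids, fixed once per graph —
  matrices are reproducible bit-for-bit.
- **Sequence matching** runs exact, then containment, then fuzzy tiers;
  the fuzzy mismatch fraction is the best ungapped-offset Hamming distance
  over the shorter sequence's length, and 5 % is the default tolerance.
  Earlier-tier matches are excluded from later tiers, so the tiers are
  disjoint and exhaustive.
- **Seeds are unweighted** (targets enter at `1/k` regardless of their
  interaction score); the score's role ends at the filtering threshold.
- **InChIKey-style compound matching** is exact full-string equality.
- **Gene importance** is the Pearson correlation of each gene's profile
  column with the model's predicted probabilities (continuous outcomes by
  default; hard labels available), with zero-variance genes scored 0;
  ensemble importance is the arithmetic mean across members.
- **Model selection ties** are broken by a deterministic settings key, and
  fold assignment is a pure function of the run seed, so identical seeds
  give bitwise-identical result tables.
- **Selection pools SVM and MMC models** into one ranking rather than
  selecting per classifier.
- **Food correlation** uses binary CBM incidence (phi coefficient) by
  default — the food map reflects which CBMs foods share, not how strongly
  each scores — with an ACL-weighted variant behind a flag. The correlation
  cutoff for drawing edges has no canonical value and is exposed as
  configuration.
- **Degenerate inputs**: compounds whose targets all fail to map are
  excluded, counted and reported; foods with zero CBMs are dropped from the
  correlation map with a log entry; a walk hitting the iteration cap
  returns `converged = FALSE` with a warning rather than failing.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at the
default synthetic conditions (500 genes, 1000 labeled compounds) with a
compact grid (one gene–gene threshold, `c = 0.02`, both classifiers, log
transform on and off), a 100-graph propagation-oracle sweep over the full
14-value `c` grid, and a 20-replicate permutation null — a few minutes on
one CPU. The full printed grid (1344 propagation/preprocessing combinations
per classifier) is exposed via `defaultParameterGrid()` for larger runs.

## Known limitations

- Walks are over dichotomized edges; edge weights only gate inclusion.
- No directionality or sign of interactions; activating and inhibiting
  compounds propagate identically.
- The radial-kernel SVM is deliberately omitted: at full scale its best
  operating point does not beat the linear kernel and its optimal kernel
  width degenerates toward linearity.
- Pathway enrichment of ranked genes is out of scope; `writeRnk()` exports
  the ranked list for external preranked tools.
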