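---
title: "Self-training in the significance space of support vectors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-training in the significance space of support vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biomedical event extraction pipelines contain a classification stage — *edge
detection* — that labels candidate trigger–argument connections with a role
class (Theme, Cause, Site, ...) or Negative. Feature vectors for this task
are extreme in two ways: the dimensionality is in the hundreds of thousands
(sparse binary indicators from lexical and dependency-path features), and the
class distribution is severely skewed — the Negative class outnumbers a rare
role class by five or six orders of magnitude. At the same time, unlabeled
biomedical text is abundant. `stss` implements a semi-supervised learning
method for exactly this regime, together with the baselines needed to judge
it: majority-class under-sampling, inverse-frequency class weighting, and
traditional self-training.

## Self-training in significance space

The task model `SVM_1` is a one-vs-rest ensemble of linear soft-margin SVMs
(one binary classifier per class, argmax-of-score decoding). The key
observation is that the training instances that *matter* to `SVM_1` are its
support vectors: instances with functional margin at most 1. One STSS round:

1. **Significance set `S`.** Relabel the training set: support vectors of
   `SVM_1` get significance label 1, everything else 0. For a multi-class
   ensemble, the support set is the union of the per-class SV sets.
2. **Significance model `SVM_2`.** A binary linear SVM trained on `S`. It
   learns *which regions of feature space hold informative examples*.
3. **Query `U`.** Classify a data pool with `SVM_2`; the instances it marks
   significant form the query set `U`.
4. **Label.** In *labeled-pool* mode the pool's true labels are used (the
   pool is held-back labeled data; nothing is self-labeled). In *self-label*
   mode, `SVM_1` predicts labels and a calibrated confidence for each queried
   instance.
5. **Filter to `L_c`.** A selection strategy keeps the confidently labeled
   subset (see below).
6. **Augment and retrain.** `L_c` joins the training set, selected instances
   leave the pool, and `SVM_1` is retrained. Every intermediate model is
   stored in the run history for later evaluation.

The loop (`run_stss()`) stops at `max_iter` rounds, on pool exhaustion, or
when the selection comes back empty — for a deterministic strategy an empty
round provably repeats, so the loop stops immediately; only the random
strategy gets a second draw.

### Selection strategies

`selection_strategy()` implements the four filtering rules: `top_k` (the k
highest-confidence examples), `top_pct` (the top `ceiling(p*n)` — a flexible
threshold whose yield tracks the candidate-set size), `threshold`
(confidence at least `tau`) and `random` (k uniform draws, the control).
Ranking ties break toward the lower pool index so runs are reproducible.
The package default is `top_pct` with `p = 0.10`: the flexible-threshold
strategy is the one the method favors, and since no particular percentage is
canonical, one default is fixed here once. `top_pct` uses a ceiling so a
non-empty candidate set always yields at least one selection.

### The two-phase framework

**Phase I** solves the imbalance problem without ever mislabeling anything.
For each positive class, the initial training set is *all* its positives
plus the same number of randomly chosen majority-class negatives; the rest
of the training data becomes a *labeled* pool. STSS rounds then pull in the
informative negatives — those falling into the significance region — under
their true labels. The result per class is a balanced subset `D_s` whose
imbalance-ratio denominator `floor(n_neg/n_pos)` is far below the original
training set's, plus a one-vs-rest ensemble assembled from the per-class
fits. Each subproblem runs on a seed derived from the master seed, so the
per-class subsets are independent but jointly reproducible.

**Phase II** starts from the Phase-I model and the union of the balanced
subsets (under their original multi-class labels) and runs STSS in
self-label mode against a genuinely unlabeled pool.

One subtlety: the assembled Phase-I model's components were each fitted on
their own balanced subset, so their margins are meaningless on rows they
never saw. The significance of a union row is therefore defined by
*provenance* — a row is significant iff it is a support vector of the
subproblem that actually trained on it. `phase_one()` records this vector
and `phase_two()` uses it for the first round; later rounds rebuild
significance from the retrained (whole-union) model in the ordinary way.

Decoding with the Phase-I ensemble has no binary model for the majority
class. Predictions fall back to the designated majority class (configuration
`majority_class`, default `"Negative"`) whenever no positive-class
calibrated score reaches 0.5, with confidence one minus the best
positive-class score.

## The base classifier

- **Solver.** Each binary problem is solved by libsvm (via `e1071::svm`,
  linear kernel, no feature scaling — the features are sparse indicators).
  The primal weight vector is recovered from the dual coefficients; libsvm
  orders classes by first occurrence in the data, so the sign is normalized
  explicitly.
- **Two-class shortcut.** With exactly two classes, the two one-vs-rest
  problems are exact negations with one shared optimum; the second component
  is derived by negation (its Platt sigmoid is refitted on the negated
  decision values). Phase I, which runs binary subproblems throughout,
  halves its training cost this way.
- **Calibration.** A linear SVM emits decision values, not probabilities;
  the filtering strategies need the latter. Each component carries a Platt
  sigmoid `P(class | d) = 1/(1 + exp(A d + B))` fitted by Newton iteration
  on its own training decision values, with smoothed targets
  `(n_+ + 1)/(n_+ + 2)` and `1/(n_- + 2)` so separable data cannot drive
  `|A|` to infinity. Scores are strictly increasing in `d` and strictly
  inside (0, 1).
- **Support-vector identification.** A primal characterization is used:
  instance `i` is a support vector when `y_i (w.x_i + b) <= 1 +
  sv_tolerance`. At the exact optimum this margin set coincides with the
  nonzero-dual-coefficient set. The default `sv_tolerance = 1e-3` is matched
  to libsvm's default termination tolerance (1e-3): free support vectors sit
  at functional margin `1 + O(solver slack)`, so the band must dominate the
  slack; a much tighter band silently drops free SVs, and a much looser one
  would start absorbing genuinely interior points. The test suite fits tiny
  problems at solver tolerance 1e-7 and compares against an independent
  primal quadratic program (quadprog) at a 1e-4 band. Problems where the
  bias is non-unique (no free SV pins it — the hinge subgradient in `b` is
  flat at the optimum) have an ill-defined margin set and are excluded there;
  they are detected from one-sided subgradient counts.
- **Ties.** Argmax decoding breaks exact score ties toward the smallest
  class code.
- **Degenerate rounds.** If a training set consists entirely (or not at all)
  of support vectors, the significance model is untrainable; the round
  raises a classed error (`stss_degenerate_significance`) and the loop stops
  gracefully, keeping the history so far. Tiny balanced subproblems (a
  handful of instances, all on the margin) hit this path routinely and
  harmlessly.

## The synthetic generator

Real edge-detection feature data cannot ship with the package, so the
generator emulates its *structure*: sparse binary features (background
activation probability `feature_density`), one disjoint informative block
per class whose features activate with probability `feature_density +
separation` for instances of that class, per-class counts following the
edge-detection training distribution scaled by a factor (counts
`max(1, round(scale * count))`, round half up, so ultra-rare classes survive
scaling and the rare-class-removal path stays testable), feature count
`max(100, round(scale * 412753))`, and uniform label-flip noise.
`edge_detection_fixture(scale)` bundles a training set, an unlabeled pool
with hidden ground truth, and the spec; defaults are separation 0.3 and 5%
flip noise.

What the generator does **not** emulate: correlated n-gram features,
multi-label instances, document structure, and — importantly —
*structured* annotation noise. Uniform flips interact with extreme skew in a
way worth stating plainly: at a 400:1 Negative:positive ratio, 5% uniform
flips make most *observed* positives feature-wise negatives. Passing tests
on this fixture show the machinery behaves correctly under heavy, adversarial
label noise; they do not certify performance numbers on real corpora, whose
noise is milder and differently shaped.

## Desk-scale studies

Two documented studies run in the test suite and in
`scripts/acceptance.R`; their problem sizes are fixed here once, as the
package's own choice of a configuration that a laptop-class machine
completes comfortably.

- **Phase-I data-efficiency audit** (`phase_one_audit()`): fixture scale
  0.01, five seeds, Phase I with `max_iter = 3` and `top_k` capped at 500
  added negatives per round. Checks that every balanced-subset row is
  bit-identical to its provenance row in the original data and that every
  per-class ratio denominator strictly decreases.
- **STSS vs traditional self-training**
  (`stss_selftrain_benchmark()`): fixture scale 0.01, five seeds, pool of
  4,000 instances from the same generative process. Phase I (one round,
  `top_k` 100) produces the shared starting model and training set; both
  methods then run one self-label round with the shared default `top_pct
  (p = 0.10)` strategy — self-training filters the whole pool, STSS only the
  significance-queried subset; that is the entire difference. Each stored
  model is evaluated on a noise-free dev set from the same generative
  process (50 per positive class, 500 Negative — proportional sampling would
  leave rare-class F undefined at this scale); a method scores its best dev
  macro F. Each round retrains the full one-vs-rest ensemble — the dominant
  cost at this scale — which is what bounds the study to one round; the
  `max_iter` argument runs longer horizons where time permits.

  One property of the study conditions deserves emphasis. Uniform 5% flip
  noise at a 400:1 skew means roughly three quarters of *observed* positives
  are feature-wise negatives; nearly every training instance then violates
  some component's margin, the significance region swells to most of feature
  space, and STSS's query step filters only weakly. Under these conditions
  the two semi-supervised learners are expected to perform within noise of
  each other — the benchmark checks that exploiting significance space does
  not *hurt*, and the directional comparison rests on paired seeds.

## Limitations

- Single-label decoding only; a per-class threshold mode exists but
  multi-label evaluation is out of scope.
- The solver is exact libsvm rather than a large-scale primal solver, which
  bounds the desk-scale training sizes; the algorithmic layer is
  solver-agnostic.
- Macro-averaged F on the synthetic benchmark is noisy at small scales;
  directional conclusions there rest on paired seeds, not on magnitudes.
- The imbalance-ratio denominator uses the floor convention throughout;
  sub-unit ratios (majority smaller than minority) report 0.
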