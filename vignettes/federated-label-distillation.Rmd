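---
title: "Federated label distillation for QSAR classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated label distillation for QSAR classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidsim)
library(dplyr)
```

## The problem

Pharmaceutical companies hold private assay data on safety-relevant
off-targets (hERG, 5-HT~2B~, muscarinic M~1~, GABA~A~, COX2, ...), but no
single company's data covers enough chemical space for broadly applicable
activity classifiers, and raw structures cannot be shared. Federated
learning by *label distillation* sidesteps structure sharing: each partner
trains a local **teacher** classifier on its private compounds, the
teachers label a large shared pool of unlabeled molecules, the predictions
are consolidated across partners, and a global **student** model is trained
on the distilled pseudo-labels. Only predictions on public molecules ever
leave a partner.

`fluidsim` implements this workflow end to end — featurization, teachers,
consolidation, federated-set construction, student training, and the
evaluation protocol — together with a synthetic multi-partner world
generator so every stage is testable without proprietary data.

## Distillation recipe

Teachers emit, for every pool molecule, a probability of activity
$p \in [0,1]$ and two confidence attributes:

* **Decidability** $d = |2p - 1|$: 0 for an equivocal call ($p = 0.5$),
  1 for a decisive one. Symmetric in $p \leftrightarrow 1-p$.
* **Reliability** $r \in [0,1]$: the mean Tanimoto similarity between the
  query fingerprint and its $k$ (default 5) most similar training
  fingerprints — how close the molecule sits to the chemical space the
  model was trained on.

Neither attribute has a published closed form in the platform this design
follows; $|2p-1|$ and $k$-NN mean Tanimoto are this package's published
definitions, chosen for monotonicity, a $[0,1]$ range, and fidelity to the
verbal descriptions ("confidence in the prediction", "gap in chemical
space"). Both are pluggable via the scoring registry, and reliability uses
the fingerprint block only, because Tanimoto similarity is defined on bit
sets.

Per-molecule member predictions are consolidated by a
decidability-weighted majority vote (the label whose voters carry the
larger summed decidability wins; an exact tie resolves to *inactive*, the
conservative call in safety screening; if every member is fully equivocal
the unweighted majority decides, which also makes single-member
consolidation an identity). Unweighted majority and mean-probability
thresholding are available as alternatives. Consolidated decidability and
reliability are member means; the reliability filter applies to the
consolidated mean, matching the single filter step after consolidation.

The **federated set** is then built by filter → rank → fill:

1. drop consolidated records with reliability below `reliability_min`
   (protocol default 0.005 — whether that scale matches the original
   platform's internal scale is unknowable, so the threshold is a free
   configuration value);
2. split by consensus label, rank each class by decreasing decidability
   (ties broken by higher reliability, then molecule id, so regression
   runs are fully deterministic);
3. take up to `n_per_class` from each class (protocol scale 10,000);
4. fill any shortfall from the other class, continuing down the donor's
   ranking — so 5,085 eligible positives against abundant negatives yield
   a 5,085 / 14,915 set of 20,000;
5. if the donor is also exhausted, return everything eligible and record a
   shortfall warning.

Ranking is per class, the only reading consistent with taking the first
$N$ entries *of each label*. Decidability is not thresholded by default;
an optional `decidability_min` exists for experiments that want it.

## The synthetic world

`generate_world()` emulates the statistical structure of a consortium
study:

* **Chemical space** is a mixture of Gaussian modes ("series") in a latent
  coordinate (default 10 clusters, 6 dimensions) with explicit roles:
  6 partner-owned clusters (assigned round-robin, private by default —
  `partner_cluster_overlap = 0`), 2 clusters that generate the public
  labeled set, and 2 pool-only clusters. The unlabeled pool spans *all*
  clusters, mirroring broad public chemistry that touches each partner's
  series (where that partner's teacher is confident — the source of
  positive pseudo-labels) as well as space no labeled set covers.
  Partner-private series are required for the reliability domain to carry
  information at all: $k$-NN Tanimoto reliability saturates as soon as a
  series has *any* training representation, so a generator in which every
  partner samples every cluster makes the applicability domain vacuous.
  The overlap knob interpolates continuously to identical partner
  mixtures (1).
* **Activity** is a logistic function of a random linear projection of the
  latent coordinate plus per-cluster offsets, emitted as a percent
  response; `label_activity()` applies the ≥ 50 % at 10 µM convention
  (the boundary is active). Cluster-correlated activity mimics
  chemical-series effects and is what makes reliability genuinely
  informative about prediction quality.
* **Imbalance** is controlled per dataset: the activity calibration is set
  from the requested inactive/active ratio (accounting for label noise),
  so realized ratios track requests within binomial fluctuation. Requested
  ratios that imply less than one expected active molecule raise an error
  naming the dataset.
* **Label noise** is a symmetric flip with probability `label_noise`
  (default 0.05), the simplest model of assay variability; a per-partner
  calibration jitter knob (default off) emulates assay-condition
  differences between companies.
* **Temporal structure**: training molecules carry pre-cutoff assay years,
  test molecules post-cutoff years (cutoff 2020), and the test mixture
  drifts half-way toward the global cluster mixture by default
  (`temporal_drift = 0.5`) — newer molecules explore chemistry beyond a
  partner's historical series, which is the premise of temporal
  validation.
* **Features**: molecules always carry abstract feature vectors
  (descriptors = noisy latent coordinates; fingerprints = cluster-prototype
  bits, 256 by default), so no chemistry toolkit is needed for modeling
  studies. `mode = "smiles"` additionally assembles concrete SMILES from a
  small fragment grammar (ring scaffolds with chainable substituents) so
  the chemistry pipeline can be exercised end to end. The grammar makes no
  attempt at realistic medicinal-chemistry series.

Pool ground-truth labels are hidden behind `pool_ground_truth()`, an
explicit oracle used only by tests and evaluation; no federation code path
reads it.

What passing tests on this world do *not* show: real assay noise is not
symmetric or label-independent, real chemical series are not Gaussian
modes, and real descriptor blocks are far more collinear than noisy latent
coordinates. The generator supports relative comparisons between
compositions and protocols, not absolute performance claims.

### Scale

The default world is a deliberate desk-scale analogue of the study design:
3 partners × 2,000 training molecules, 800-molecule test sets, a
1,000-molecule public set, a 20,000-molecule pool, and a 500 + 500
federated target — roughly a 1:20 scale-down of the consortium-scale
numbers (>300,000 pool, 10,000 per class), with test sets kept at the
study's absolute scale (hundreds of molecules) because coverage and
balanced-accuracy comparisons need their resolution. These sizes are also
what the test suite and the reproduction script run.

## Featurization

`standardize_smiles()` removes salts by keeping the largest fragment
(heavy-atom count; ties broken by the lexicographically smallest canonical
SMILES, so the choice is deterministic) and canonicalizes via the
OpenBabel backend; the operation is idempotent. Charge neutralization and
tautomer/stereochemistry normalization are deliberately out of scope.

`featurize()` produces two blocks per molecule:

* a **physicochemical descriptor block** defined by a frozen, named
  configuration artifact (`descriptor_config()`); the count is
  configuration-defined and asserted at load rather than hard-coded,
  because 1D/2D descriptor counts are toolkit- and version-dependent. The
  shipped configuration combines OpenBabel property-engine descriptors
  with heavy-atom-graph counts.
* a **hashed circular (Morgan) fingerprint**, radius 3, folded to 2048
  bits, implemented in-package over the heavy-atom graph: initial atom
  invariants (atomic number, heavy degree, bond-order sum) are iteratively
  hashed with sorted (bond order, neighbour identifier) pairs, and each
  environment — identified by its bond set — is emitted once at the
  smallest radius where it appears. The test suite checks popcounts
  against an independent exhaustive environment enumerator on small
  molecules.

Descriptors are min–max scaled to $[0,1]$; fingerprint bits pass through.
The study protocol scales training and test jointly, and that is the
default; fitting on training only and clipping test values ("strict"
usage: fit the scaler on the training container alone) avoids the mild
leakage of joint scaling at the cost of protocol fidelity — out-of-range
values clip to the boundary either way, and constant descriptors map to 0.

## Teachers and the model zoo

Eleven architectures sit behind one contract (fit on a matrix, emit
probabilities): naive Bayes, a gradient-descent linear classifier, a
decision tree, random forest, extremely randomized trees, $k$-NN, a
multilayer perceptron, AdaBoost, gradient boosting, a support-vector
classifier, and extreme gradient boosting. Established implementations are
used wherever the environment provides them (ranger, rpart, nnet, e1071,
class, xgboost); the steepest-descent logistic classifier and
SAMME-AdaBoost over shallow trees are authored in-package. Support-vector
probabilities come from Platt scaling; $k$-NN tie-breaking is pinned to
the stored seed so predictions are reproducible.

Hyperparameter search (`optimize_hyperparameters()`) is a seeded random
search (budget 25 by default; the search protocol, budget, and seed are
recorded in every result) scored on mean cross-validated balanced
accuracy. The sensitivity refit rule is implemented as a tie-break: among
configurations within $10^{-6}$ of the best balanced accuracy, the one
with the highest sensitivity wins — re-optimizing on sensitivity alone
would collapse to always-positive classifiers. Cross-validation
(`cross_validate()`) supports stratified and random 5-fold schemes with 10
repeats; fold assignment depends only on (seed, n, labels, scheme, k), so
architectures compared under one seed share folds. Minority oversampling
(`oversample_minority()`) replicates whole minority rows to the integer
factor closest to the target ratio; it synthesizes nothing.

Fine-tuning (`train_finetune_path()`, variants RI and RF) continues the
perceptron's optimization from the pretrained weights on the internal set
with a reduced iteration budget (default half the pretraining budget).
Because the optimizer restarts with its own termination tolerance,
refining on data identical to the pretraining set reproduces the
pretrained predictions to ~10^-4^ rather than exactly; the property tests
assert 10^-3^ after confirmed convergence. Non-iterative learners refit on
the union instead, and a refined model's training-space reference is
always the union of pretraining and refinement fingerprints.

## Evaluation protocol

`classification_metrics()` reports sensitivity, specificity, precision,
balanced accuracy (the arithmetic mean of sensitivity and specificity) and
the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with a zero denominator reported as 0 (the standard convention; it keeps
report tables total) and zero-denominator ratios as missing.
`evaluate_model()` optionally restricts scoring to the applicability
domain — the conjunction `reliability >= reliability_min` and
`decidability >= decidability_min` — and reports the in-domain fraction as
`ad_coverage`. Coverage is monotonically non-increasing in both
thresholds by construction.

For the default synthetic world the experiment configuration uses
`reliability_min = 0.4` — between the within-series (~0.6–0.8) and
cross-series (~0.05) Tanimoto modes of the synthetic fingerprints — and
leaves decidability unthresholded (`decidability_min = 0`) in the
AD-coverage trend analysis. The reasoning: the coverage-growth claim is
about chemical-space enlargement, and in the reliability domain the
orderings are structural — a model trained on a superset of data carries a
superset training reference, so every query's k-NN reliability, and hence
coverage, can only rise. Thresholding decidability as well is supported
(any production configuration can set it) but at desk scale it adds
base-learner confidence noise of a few test molecules per comparison,
which swamps the small coverage increments without measuring space.
The qualitative finding — applicability-domain coverage growing as the
training space grows, teacher → hybrid → hybrid-federated and federated →
refined-federated — is reproduced by the acceptance suite on 5 seeds. The recovery checks (teacher balanced
accuracy at the desk-scale training size, student-vs-teacher agreement on
pool-distributed data) run on low-noise worlds without temporal drift,
because recovery relative to the noise-implied Bayes rate is only defined
in-distribution; the drifted default world is reserved for the AD
analysis, which is about shift.

`chemspace_embed()` implements the joint chemical-space analysis: the
named sets are embedded together (2 or 3 dimensions) in one coordinate
system with set tags, plus a nearest-neighbour overlap statistic
(`embedding_overlap()`) that turns "set A covers set B" claims into a
number. The embedding backend is pluggable — PCA by default, classical MDS
as an option — because the analysis contribution is the joint-embedding
protocol and the overlap statistic, not the embedding algorithm; axis
signs are pinned so runs are deterministic.

## Orchestration and reproducibility

`run_experiment()` executes generate → teachers → federate → students →
evaluate from one nested configuration (`default_run_config()`,
YAML-loadable via `read_run_config()`). Every tabular artifact is written
as CSV next to a JSON manifest carrying the configuration, its hash,
per-file MD5 hashes, a stage log, and any warnings (for example
federated-set shortfalls). Every random draw derives a named stream from
the global seed — each dataset, teacher, student, and stage has its own —
so reruns are byte-identical, and removing a federation member changes
only that member's artifacts and downstream federation outputs. The first
configured member plays the internal-member role: students refine on, and
are evaluated against, its data.

```{r example, eval = FALSE}
cfg <- default_run_config(seed = 1)
run <- run_experiment(cfg, out_dir = "runs/demo")
run$metrics
plot_ad_trend(run$trends$composition)
autoplot(run$embedding)
```

## Known limitations

* The consolidation rule, the confidence definitions, and the 0.005
  reliability scale are this package's published choices for an
  underdocumented proprietary pipeline; they are faithful to the verbal
  descriptions but not guaranteed to match the original numerically.
* The hypothesis-network architecture used by one side of the original
  comparison is proprietary and out of scope; the composition path accepts
  any zoo architecture (random forest by default), since the path is
  defined by its data composition.
* Label-space contributions to the applicability domain are mentioned in
  the three-domain literature but unspecified; only reliability and
  decidability are implemented.
* The generator supports qualitative, relative findings; absolute
  performance numbers on proprietary assay data are not reproducible by
  construction.
* Bayesian hyperparameter optimization backends are not part of this
  stack; the seeded random search records its protocol so results are
  comparable, but search efficiency differs.
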