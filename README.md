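# fluidsim

Federated learning by **label distillation** for binary activity (QSAR)
classification in secondary pharmacology, end to end and fully simulatable.

Pharma partners cannot pool the structures and assay labels behind their
safety-panel models (hERG, 5-HT<sub>2B</sub>, AChM<sub>1</sub>R,
GABA<sub>A</sub>, COX2, ...). In the distillation flavour of federated
learning each partner instead trains a local **teacher** classifier on its
private compounds; the teachers label a large shared pool of unlabeled
molecules; the per-molecule predictions are consolidated across partners;
and a global **student** model is trained on the distilled pseudo-labels.
Two confidence attributes steer the distillation:

- **decidability** `|2p − 1|` — how far a predicted probability `p` is from
  the equivocal 0.5;
- **reliability** — mean Tanimoto similarity between a molecule's Morgan
  fingerprint and its *k* nearest training fingerprints, i.e. how close it
  sits to the model's training chemical space.

The **federated set** is built by *filter → rank → fill*: drop consolidated
predictions with reliability below a threshold (0.005 in protocol mode),
rank each class by decreasing decidability, take the top *N* per class
(10,000 at protocol scale), and fill any class shortfall from the other
class, continuing down its ranking. The applicability domain (AD) of a
model is the conjunction of reliability and decidability thresholds, and
the package reproduces the qualitative finding that AD coverage grows as
the training space grows: teacher (T) → +public (HI) → +federated (HF),
and federated (F) → internal-refined federated (RF).

The package ships every stage behind a data-frame-first, pipe-friendly
interface: SMILES standardization and featurization (208-style descriptor
block + 2048-bit radius-3 Morgan fingerprints), a synthetic multi-partner
world generator (cluster-structured chemical space, temporal train/test
split, controlled class imbalance, hidden pool ground truth), an
11-architecture model zoo with seeded hyperparameter search and repeated
stratified/random cross-validation, the federation core, both student
training paths (data-composition and pretrain/fine-tune), confusion-matrix
metrics (balanced accuracy, MCC), AD-restricted evaluation, joint
chemical-space embedding, and a config-driven experiment runner with
byte-reproducible outputs.

## Worked example

The fill rule on a real eligibility profile — 5,085 eligible positives
against abundant negatives, per-class target 10,000:

```r
library(fluidsim)

cons <- synthesize_consolidated(n_pos_eligible = 5085, n_neg_eligible = 30000, seed = 1)
fs   <- build_federated_set(cons, n_per_class = 10000, reliability_min = 0.005)
glance(fs)
#>   n_records n_pos n_neg n_per_class reliability_min shortfall class_ratio
#> 1     20000  5085 14915       10000           0.005         0        2.93
```

All 5,085 positives are taken, negatives fill the shortfall to 14,915, the
set totals 20,000, and the inactive/active ratio lands at 2.93.

A small federation on a synthetic three-partner world, comparing the
internal-only teacher (T) with the hybrid-federated student (HF) under
AD-restricted evaluation:

```r
w  <- generate_world(world_config(n_train_per_partner = 600, n_test_per_partner = 300,
                                  n_public = 400, n_pool = 4000, seed = 1))
pf <- world_features(w, w$pool)
teachers <- lapply(names(w$partner_train), function(p)
  train_teacher(model_dataset(w, w$partner_train[[p]]), member_id = p, seed = 1))
fed <- build_federated_set(consolidate(lapply(teachers, predict_pool, pool_features = pf)),
                           n_per_class = 250, reliability_min = 0.005)

internal <- model_dataset(w, w$partner_train[[1]])
public   <- model_dataset(w, w$public_set)
test     <- model_dataset(w, w$partner_test[[1]])

t_model  <- train_composition_path(internal, variant = "T", seed = 1)
hf_model <- train_composition_path(internal, public, federated_dataset(fed, pf),
                                   variant = "HF", seed = 1)

evaluate_model(t_model,  test, ad_restricted = TRUE, reliability_min = 0.4)
#>   sensitivity specificity balanced_accuracy precision   mcc ad_coverage n_evaluated
#> 1       0.506       0.969             0.738     0.930 0.551        0.59         177
evaluate_model(hf_model, test, ad_restricted = TRUE, reliability_min = 0.4)
#>   sensitivity specificity balanced_accuracy precision   mcc ad_coverage n_evaluated
#> 1       0.578       0.780             0.679     0.578 0.358        0.88         263
```

The teacher can reliably predict 59 % of the temporally newer test set —
the rest falls outside its chemical space. Adding public and federated
data widens the applicability domain to 88 %: half again as many molecules
receive an in-domain call, at the price of some precision on the newly
covered, pseudo-labeled regions — the same coverage-versus-performance
trade the AD trend analysis quantifies.

The full pipeline is one call:

```r
run <- run_experiment(default_run_config(seed = 1), out_dir = "runs/demo")
run$metrics                          # all variants, plain and AD-restricted
plot_ad_trend(run$trends$composition)
autoplot(run$embedding)
```

Every artifact is written as CSV with a JSON manifest (config hash,
per-file MD5s, stage log); rerunning with the same config and seed
reproduces the CSVs byte for byte. A thin command-line wrapper lives at
`inst/cli/fluidsim.R` (`generate`, `run-all`).

## Package layout

- `R/chem_features.R` — standardization, descriptors, Morgan fingerprints, scaling
- `R/synthetic_data.R` — the multi-partner world generator
- `R/zoo.R`, `R/teacher_models.R` — model zoo, CV, hyperparameter search, teachers
- `R/confidence_domain.R` — decidability, reliability, AD membership
- `R/federation.R` — pool prediction, consolidation, federated-set construction
- `R/student_models.R` — variant table, composition and fine-tune paths
- `R/evaluation.R` — metrics, AD trends, ratios, chemical-space embedding
- `R/workflow.R` — config-driven end-to-end runner
- `vignettes/federated-label-distillation.Rmd` — models, assumptions, and design choices
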