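# lungpaste

Unsupervised anomaly detection for chest radiographs via anatomy-aware
self-supervised augmentation — as a tested, self-contained R package.

## The problem

Labeled abnormal radiographs are scarce; normal ones are not. One-class
(unsupervised) anomaly detection trains only on normals and flags images
whose anomaly score exceeds a threshold. The catch is where the training
signal comes from. `lungpaste` synthesizes it: a patch is cut from a normal
radiograph and blended back elsewhere **only inside the lung fields**,
through a blurred-shape opacity mask, so the synthetic "lesions" occur where
real pulmonary disease occurs. A small residual CNN `f` is trained to
distinguish originals (label 0) from augmented images (label 1),

    L = (1/N) Σᵢ { CE(f(Xᵢ), 0) + CE(f(Aug(Xᵢ)), 1) },

and test images are scored by a Gaussian kernel density over the learned
embeddings z against the normal-training bank {zᵢ}:

    A(z) = (1/N) Σᵢ K(z − zᵢ),   K(z) ∝ exp(−‖z‖²/2),

with raw anomaly score −log A(z) (computed by log-sum-exp), min-max
normalization to [0, 1], and a decision threshold chosen to maximize F1 on a
labeled validation split.

The package provides every stage:

* **Phantom generator** — synthetic chest radiographs (dark lung fields,
  bright mediastinum, ribs, pulmonary vessels, vignetting, noise) with
  ground-truth lung masks and injectable lung opacities, so the entire
  pipeline is testable with no external data.
* **Annotation-free lung segmentation** — CLAHE, Otsu (dark foreground),
  morphological opening, border clearing, disc dilation,
  minimum-component-area filtering (8-connectivity).
* **Anatomy-aware paste augmentation** — cut/paste, oval-or-rectangle
  blurred opacity shape (interior value v ~ U[0.59, 1], blur radius
  r ~ U[0, 15] px at 256²), anatomical mask `X_seg ⊙ X_blur`, convex blend;
  ablation modes `no_segmentation` and `no_blur`.
* **Pretext classifier** — residual CNN + 3-layer projection head written in
  RcppArmadillo (no deep-learning framework needed), SGD with momentum,
  weight decay, cosine annealing, checkpointing by validation AUC.
* **KDE anomaly scoring, best-F1 thresholding, ensembling, ROC/AUC metrics**
  and a fully seeded end-to-end pipeline.

## Worked example

```r
library(lungpaste)

# 200 normal 64x64 phantoms for training, labeled validation and test splits
cfg <- pipeline_config(seed = 1)     # tiny preset: 20 epochs, one CPU
res <- run_pipeline(cfg, out_dir = "run1")

res$report$auc        # test AUC separating injected opacities from normals
res$threshold         # best-F1 cut chosen on the validation split
head(res$scores)      # per-image raw and normalized anomaly scores
```

On this machine the run prints (seed 1, ~70 s):

```
res$report$auc
#> [1] 0.79
c(res$report$accuracy, res$report$f1)
#> [1] 0.7300000 0.7096774
res$threshold$threshold
#> [1] 0.01419921
head(res$scores, 3)
#>   image_id label  raw_score normalized_score
#> 1 nrm_0001     0 0.05667193      0.001803688
#> 2 nrm_0002     0 0.07503178      0.005240757
#> 3 nrm_0003     0 0.06409206      0.003192779
```

meaning: a model trained on 200 normal phantoms, never shown an abnormal
image, ranks unseen opacity-bearing phantoms above normals with AUC 0.79 on
this seed (desk-scale runs are seed-noisy: 0.56–0.96 over the three
acceptance seeds, see the vignette); the 0.014 cut (chosen on validation
data only) yields the reported accuracy and F1. `run1/` contains the
manifest, per-image scores CSV, a JSON report, a stage log, and first-epoch
augmented examples — re-running the same config reproduces all of them byte
for byte.

Individual stages are exported too:

```r
s  <- generate_normal_phantom(phantom_spec(256, seed = 7))
m  <- segment_lungs(s$image)                 # binary lung mask
dice(m, s$lung_truth)                        # 0.847 on this phantom
a  <- paste_augment(s$image, m, rng_seed = 1)
all(m[a$image != s$image] == 1)              # TRUE: changes confined to lungs
```

## Command line

A dispatcher with per-stage subcommands ships in `inst/cli/lungpaste`:

```sh
lungpaste synth    --n-normal 200 --n-abnormal 0 --out data/ --seed 1
lungpaste segment  --in data/ --out masks/
lungpaste augment  --in data/ --masks masks/ --out aug/ --mode full --seed 1
lungpaste train    --train data/ --masks masks/ --val val/ \
                   --val-labels val/labels.csv --out model.rds
lungpaste score    --ckpt model.rds --train-bank data/ --in test/ --out scores.csv
lungpaste threshold --scores scores.csv --labels labels.csv --out decision.json
lungpaste evaluate --scores scores.csv --labels labels.csv --threshold 0.28 \
                   --out report.json
lungpaste run      --seed 1 --out run1/
```

## Scope

Desk-scale by design: the full-scale 256-epoch ResNet-18 recipe is
expressible (`model_config("resnet18")`) but all stochastic guarantees are
stated for the `tiny` preset on phantoms. Reproduction of published
benchmark numbers on public chest-radiograph corpora, comparison baselines, and
saliency visualization are out of scope. See the methods vignette
(`vignettes/lungpaste-methods.Rmd`) for the model, parameter rationale, and
known limitations.
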