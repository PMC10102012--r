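# retinaCL

Style-transfer-augmented contrastive pretraining for referable diabetic
retinopathy (DR) screening, with a fully synthetic desk-scale test bed.

## What it does

Screening fundus photographs for **referable DR** (moderate
non-proliferative disease or worse, grade ≥ 2 on the 0–4 severity scale)
with deep classifiers normally demands large labeled datasets. This package
implements a label-efficient alternative:

1. **Contrastive pretraining** (SimCLR-style): two augmented views of each
   unlabeled image are embedded by an encoder and a 128-dim projection
   head, trained with the NT-Xent loss

   `loss(i,j) = -log( exp(sim(z_i, z_j)/τ) / Σ_{k≠i} exp(sim(z_i, z_k)/τ) )`

   (cosine similarity, mean over all ordered positive pairs in the batch)
   under a LARS optimizer.
2. **Neural style transfer as augmentation**: with probability 0.70 a view
   starts from an AdaIN-stylized variant of the image (stylization
   coefficient α = 1.0), which replaces texture/color statistics while
   preserving spatial content — pushing the encoder toward the global shape
   cues (vasculature, lesions) that carry the diagnosis.
3. **Fine-tuning**: the pretrained encoder transfers one-to-one (projection
   head discarded) into a referable-vs-non-referable classifier trained
   with cross-entropy/Adam, including label-fraction experiments down to
   10% of labels.
4. **Evaluation**: ROC curves, AUC via the Mann–Whitney statistic, DeLong
   95% confidence intervals, Youden operating points
   (J = max(sensitivity + specificity − 1)), and paired DeLong tests.

A seeded synthetic generator (`generate_fundus()`, `generate_style()`)
renders fundus-like images — circular aperture, vessel tree, optic disc,
fovea, grade-dependent lesions — in which *shape carries the label* and a
class-independent color/texture field is a deliberate confounder, so the
whole pipeline is testable on a laptop CPU with no downloads. Networks are
small convolutional encoders run by a built-in matrix-based engine; the
full-scale settings (ResNet50, batch 2048, 224 px) remain the documented
configuration defaults.

## Worked example

```r
library(retinaCL)

# a seeded synthetic dataset: 120 images, manifest + ground-truth sidecars
params <- synth_params(image_size = 32)
man <- generate_dataset(120, c(0.5, 0.2, 0.15, 0.1, 0.05), params,
                        out_dir = "demo_data", seed = 1)

# quality screening with the five exclusion criteria
reports <- lapply(man$path, function(p) assess_quality(read_image(p)))
kept <- apply_exclusion(man, reports)

# AdaIN coder + pre-synthesized stylized variants
bank <- generate_style_bank(24, 32, seed = 2)
coder <- train_coder(c(lapply(kept$path[1:64], read_image), bank, bank),
                     desk_coder_config(content_size = 32, style_size = 32),
                     seed = 3)
cache <- precompute_stylized(kept, bank, variants_per_image = 2,
                             alpha = 1.0, coder, "demo_styled", seed = 4)

# contrastive pretraining (desk profile), then transfer + fine-tune
ck <- pretrain(kept, cache, desk_pretrain_config(epochs = 10), seed = 5)
folds <- kfold_split(kept, k = 5, seed = 6)
fit <- finetune(folds[[1]]$train, folds[[1]]$validation,
                transfer_weights(ck, seed = 7),
                desk_finetune_config(), seed = 8)

scores <- predict_referable(fit$model, folds[[1]]$validation)
roc_report(scores, folds[[1]]$validation$referable)
```

The final call prints, for this seeded run:

```
ROC report: AUC 0.937 (95% CI 0.846-1.000, delong)
  Youden threshold 0.321 (J = 0.833): sens 1.000 (1.000-1.000), spec 0.833 (0.611-1.000)
  n: 7 positive / 18 negative
```

i.e. the classifier separates referable from non-referable synthetic images
with AUC 0.94 on this small validation fold; the Youden threshold is the
operating point maximizing sensitivity + specificity − 1, with stratified
bootstrap CIs at that point. (Small-fold CIs are wide by nature.)

`desk_benchmark()` runs the package's headline experiment — with-NST vs
no-NST contrastive pretraining vs random initialization, evaluated at 10%
and 100% of labels on a fixed held-out split — and returns a tidy table of
AUCs per replicate seed and arm.

A thin command-line front end is installed at `inst/cli/retinacl`
(subcommands `synth`, `filter`, `split`, `stylize`, `pretrain`,
`evaluate`).

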