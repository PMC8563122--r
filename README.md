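# mtialm

Multitask interactive attention learning for palm-image classification.

`mtialm` jointly screens a palm photograph for two hand signs used in
traditional Chinese medicine hand diagnosis of myocardial-infarction
risk: **task M**, swelling of the metacarpophalangeal joints (the
knuckle line), and **task P**, hypertrophy of the palmar thenar (the
muscle bulge at the thumb base). It is aimed at researchers studying
multitask attention architectures on region-structured medical images —
everything runs from a seeded synthetic palm generator, so no clinical
data or downloads are needed.

## The model

A shared residual backbone exposes four stage outputs
*f*⁽ⁱ⁾ that feed two task-specific branches of cascaded soft-attention
modules. Each module builds a bounded mask

&nbsp;&nbsp;*f*′⁽ⁱ⁾ = T(G(*f*⁽ⁱ⁾ ⊕ ↓*f*ₘ⁽ⁱ⁻¹⁾)),

with G a 3×3 conv + batch norm + ReLU and T a 1×1 conv + batch norm +
sigmoid, exchanges mask features across branches through an information
interaction module

&nbsp;&nbsp;*f*ᵢᵢₘ⁽ⁱ,ᴹ⁾ = T₁ₓ₁(*f*′⁽ⁱ,ᴹ⁾ ⊕ λ₁ *f*′⁽ⁱ,ᴾ⁾)  (and symmetrically with λ₂),

and gates the fused features through a residual identity

&nbsp;&nbsp;*f*ₘ⁽ⁱ⁾ = (1 + *f*′⁽ⁱ⁾) ⊙ *f*ᵢᵢₘ⁽ⁱ⁾.

Each branch ends in a 1×1 conv to two class maps, global average
pooling and a softmax. The two cross-entropies combine through
learnable observation-noise variances σ² = e^η,

&nbsp;&nbsp;L = ½e^(−η_h)L_h + ½e^(−η_k)L_k + η_h + η_k,

optimized with Adam under a stepped learning-rate schedule. Ablation
variants (backbone-only, attention subsets, no interaction,
single-task), landmark-based palm patch extraction, per-branch
gradient-weighted class-activation maps, and a localization score
against ground-truth masks are all part of the package; the methods
vignette (`vignettes/mtialm-methods.Rmd`) derives and motivates each
piece. The convolutional engine itself — forward passes, batch norm,
reverse-mode gradients, Adam — is implemented in the package with
RcppArmadillo kernels.

## Worked example

Generate a small labelled cohort, train the full two-branch model for a
few epochs, and inspect one branch's activation map:

```r
library(mtialm)
rs <- generate_dataset(generator_config(n_records = 80, seed = 7))
rs
#> <record_set> 80 records (synthetic); task M positives: 40, task P positives: 41
sp <- split_records(rs, 0.8, seed = 7)
size <- dataset_psize_stats(rs)$chosen_global_size   # 80 px at this geometry
train <- prepare_inputs(sp$train, 64, size)
val <- prepare_inputs(sp$val, 64, size, with_masks = TRUE)

model <- build_model(model_config(), seed = 7)
model
#> <mtialm_model> variant=full preset=small input=64px channels=8/16/32/64
#>   attention levels: 1,2,3,4 | lambda1=0.20 lambda2=0.40 | 259,076 parameters

fit <- train_model(model, train, val, schedule_config(), epochs = 10, seed = 7)
unlist(fit$best_val$m[c("accuracy", "sensitivity", "specificity", "f1", "auc")])
#>    accuracy sensitivity specificity          f1         auc
#>   0.9375000   1.0000000   0.8750000   0.9411765   0.9843750
unlist(fit$best_val$p[c("accuracy", "sensitivity", "specificity", "f1", "auc")])
#>    accuracy sensitivity specificity          f1         auc
#>           1           1           1           1           1

k <- which(val$label_p == 1 & fit$best_val$p$prob >= 0.5)[1]
cam <- grad_cam(fit$model, val$x[, , , k], task = "p")
localization_score(cam, val$mask_p[[k]])
#> [1] 0.4720136
```

Ten epochs on 64 training images already separate both planted signals
almost perfectly (task M: one specificity miss among 16 validation
records; task P: perfect). The single-record localization score printed
here is still near chance (0.5 = no localization) — attention maps
sharpen with the full training protocol, where the median over
correctly classified positives reaches about 0.7 per task (see below).

A command-line front end wraps the same functions
(`inst/cli/mtialm`): `generate`, `preprocess`, `train`, `evaluate`,
`ablate`, `cam`, each writing a frozen copy of its resolved
configuration beside its artifacts.

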