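---
title: "Multitask interactive attention for palm-image screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask interactive attention for palm-image screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Traditional Chinese medicine hand diagnosis reads morphological signs of
cardiovascular risk off the palm. Two such signs are swelling of the
metacarpophalangeal joints — the knuckle line where the fingers meet the
palm — and hypertrophy of the thenar eminence, the muscle bulge at the
base of the thumb. `mtialm` implements a convolutional model that scores
both signs simultaneously from a single palm photograph: task M (joint
swelling) and task P (thenar hypertrophy), each a binary classification.

The two tasks look at different regions of the same anatomy, which makes
them a natural fit for hard parameter sharing with task-specific heads:
a shared backbone learns features common to both, and per-task attention
branches specialize on their own region while still exchanging
information.

## Preprocessing: landmark-based palm patches

Raw photographs contain fingers, wrist and background that carry no
signal. Four physician-annotated landmarks bound the palm: column
coordinates $X_1 > X_2$ (thumb side and opposite edge) and row
coordinates $Y_1 > Y_2$ (wrist side and finger side; images are indexed
from the top-left corner). The palm extents are

$$\Delta X = X_1 - X_2, \qquad \Delta Y = Y_1 - Y_2,$$

and the square patch side for one record is
$P_{\text{size}} = \lceil \max(\Delta X, \Delta Y) \rceil$. Rounding is
always up, and the crop box centered on the landmark-box midpoint is
zero-padded where it leaves the image: padding must not invent signal,
and ceiling guarantees coverage. A dataset-level input size is chosen as
the smallest integer covering a configurable quantile of the
$P_{\text{size}}$ distribution (default: all records), optionally capped;
at the clinical acquisition geometry this procedure yields the 460-pixel
input the model defaults to. Patches are resized to the network input
side with bilinear interpolation (half-pixel-center convention); tests
run at 64 pixels.

One subtlety is inherent to the crop: an integer-aligned window of side
$\lceil \Delta \rceil$ cannot always contain an arbitrarily placed
continuous interval of length $\Delta$ — containment can miss by up to
half a pixel of grid rounding, and one extra pixel of side absorbs it.
The tests encode exactly this guarantee.

## The model

A residual backbone (the standard 18-layer configuration at the clinical
scale; a narrow 8/16/32/64-channel single-block variant for desk-scale
work) exposes its four stage outputs $f^{(i)}$, $i = 1,\dots,4$, with
spatial size halving per stage. Each task branch attaches one attention
module per level, cascaded along the backbone.

**Attention module, first stage.** The module forms a bounded mask from
the level's shared features, concatenated with the aligned output of the
branch's previous module when one exists:

$$f'^{(i)} = T\!\left(G\!\left(f^{(i)} \oplus \downarrow f_m^{(i-1)}\right)\right),$$

where $\oplus$ is channel concatenation, $G$ is a $3{\times}3$
convolution + batch norm + ReLU, and $T$ is a $1{\times}1$ convolution +
batch norm + sigmoid, so every entry of $f'^{(i)}$ lies strictly in
$(0, 1)$. The first module of a branch takes $f^{(1)}$ alone.
Alignment $\downarrow$ uses $2{\times}2$ average pooling when the
previous map is exactly twice the current size and bilinear
interpolation otherwise; when an ablation skips levels, a $1{\times}1$
convolution + batch norm additionally matches the channel count.

**Cross-task interaction.** At every level the two branches exchange
information before the mask is applied. Taking one branch as *main* and
the other as *reference*, the reference mask features are scaled by a
weight and fused through a $1{\times}1$ reduction:

$$f_{\text{IIM}}^{(i,M)} = T_{1\times1}\!\left(f'^{(i,M)} \oplus \lambda_1 f'^{(i,P)}\right),
\qquad
f_{\text{IIM}}^{(i,P)} = T_{1\times1}\!\left(f'^{(i,P)} \oplus \lambda_2 f'^{(i,M)}\right),$$

with $T_{1\times1}$ a $1{\times}1$ convolution + batch norm mapping
$2C_i \to C_i$ channels, separate parameters per direction (whether the
two directions share parameters was genuinely open; separate parameters
are the weaker assumption and cost little). Defaults
$\lambda_1 = 0.2$, $\lambda_2 = 0.4$. Setting a $\lambda$ to zero
silences the reference branch exactly — the package tests this as an
algebraic identity against the no-interaction variant.

**Attention module, second stage.** The mask gates the fused features
through a residual identity,

$$f_m^{(i)} = \left(1 + f'^{(i)}\right) \odot f_{\text{IIM}}^{(i)},$$

so that repeated masking across the cascade attenuates rather than
annihilates the signal (a pure product of sigmoid masks would vanish
layer by layer). After the last module, each branch ends in a
$1{\times}1$ convolution to two class maps, global average pooling, and
a softmax.

The wiring of mask, fusion and gate deserves a note: the fusion consumes
the *first-stage* outputs $f'$ of both branches and feeds the *second*
stage. This is the only acyclic arrangement in which the interaction
sees task-specific features of the same level from both branches, and it
is what the package implements.

**Ablation variants.** `model_config(variant = ...)` builds the
backbone-only model (`osn`, heads directly on $f^{(4)}$), attention
subsets (`am_subset`, any non-empty subset of the four levels — 15
combinations, see `am_subset_grid()`), the no-interaction model
(`no_iim`, where each branch's own $f'$ passes through its own
$1{\times}1$ reduction in place of the cross-branch fusion), and
single-task models (one branch, no interaction).

## Loss, uncertainty weighting and schedule

Each task contributes a binary cross-entropy on its positive-class
probability, clamped at $10^{-7}$. The two losses combine through
learnable observation-noise variances $\sigma^2 = e^{\eta}$:

$$L_{\text{total}} = \tfrac{1}{2} e^{-\eta_h} L_h + \tfrac{1}{2} e^{-\eta_k} L_k + \eta_h + \eta_k,$$

with $L_h$ the thenar task's loss and $L_k$ the joint task's. The
log-variance parameterization keeps the variances positive under
unconstrained optimization, and the additive $\eta$ terms stop the
weights from collapsing to zero; for a fixed per-task loss $L$ the
optimum is $\eta^\ast = \log(L/2)$, which the tests verify numerically.
The penalty coefficients are taken as printed in the formulation above
(some related formulations halve the log terms; this one does not).

Optimization is minibatch Adam ($l_0 = 0.01$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, no weight decay, batch size 32, up to 500 epochs)
under a stepped decay indexed by the epoch counter $s$:
$l_0$ on $[0, 100]$, then $0.5\,l_0$, $0.1\,l_0$, $0.01\,l_0$,
$0.001\,l_0$ on $(100,150]$, $(150,250]$, $(250,400]$, $(400,\infty)$.
Indexing the schedule by epochs rather than gradient steps is a design
choice: the breakpoints line up with the epoch budget, not with
iteration counts at batch size 32. After each epoch the model is scored
on the validation split, and the parameters minimizing the *validation*
total loss are kept — selecting on training loss would defeat the
held-out split.

## The synthetic-palm generator

The study's clinical images are private, so the package ships a seeded
generator that emulates their structure: an elliptical palm on a dark
background whose bounding landmarks follow the acquisition statistics
(horizontal extent $423 \pm 16.26$, vertical $439 \pm 27.15$, rescaled
by `image_side / 600` so the palm fills most of the frame), the
four-combination label composition of the clinical cohort
(537 : 530 : 522 : 570 for none/P/M/both, apportioned by largest
remainder), exclusion-flag contaminants at a configurable rate, additive
Gaussian pixel noise, and 8-bit quantization so a written PNG reloads
bit-identically.

Positive labels plant soft-edged darkened discs — bruising-like
discoloration, matching the clinical motivation — in task-specific
regions: the knuckle band (upper quarter of the palm) for task M and the
lower-lateral thenar area for task P, with per-record jitter. The
regions are disjoint by construction (an oversized lesion radius is a
configuration error), each planted disc records its exact binary mask,
and the Gaussian profile width $\sigma = r/1.6$ keeps the disc-mean
contrast above half the peak contrast, which is the separability
invariant the tests assert. Each record draws from an RNG substream
derived from the global seed and the record index, so generation order
never matters.

What the generator deliberately does *not* model: real skin texture and
tone variation, illumination gradients, pose and perspective, finger
anatomy, or lesion morphology beyond a contrast disc. Passing the
recovery tests therefore shows that the implementation trains, couples
its branches, and localizes planted signals correctly — it says nothing
about clinical accuracy on real palms, and the clinical headline numbers
are out of reach without the private data.

Default generator conditions are the desk-scale study conditions: 400
records, lesion contrast 0.5 against pixel noise 0.1.

## Activation-map localization

`grad_cam()` implements gradient-weighted class-activation mapping per
task branch: the class score (post-GAP, pre-softmax) is backpropagated
to a branch feature map, channels are weighted by the spatial mean of
their gradients, and the rectified weighted sum is upsampled and
max-normalized. The canonical target is the deepest feature map of the
branch — the input of the $1{\times}1$ class-map convolution — because
it carries the most task-specific semantics. That choice presumes the
map retains usable spatial extent: at the clinical 460-pixel input the
deepest attention map is $15{\times}15$ and is exactly what the package
targets; at a 64-pixel test input the same map is $2{\times}2$ with
near-global receptive fields, and measurably carries no spatial
attribution. `grad_cam()` therefore targets the deepest attention level
whose map side is at least `min_side` (default 4) pixels, which
coincides with the canonical choice whenever the input is large enough;
`level =` overrides the rule.

Localization quality against a ground-truth mask is scored
threshold-free as mean-contrast:
$\text{mean}_{\text{in}} / (\text{mean}_{\text{in}} + \text{mean}_{\text{out}})$,
0.5 meaning no localization. Activation maps are soft, so an
intersection-over-union at an arbitrary threshold would be noisier.

## Numerical choices

* Batch norm: momentum 0.1, $\varepsilon = 10^{-5}$, identity
  initialization, running statistics frozen in eval mode.
* Convolutions are He-initialized; an optional hook can load external
  backbone weights, but nothing in the package requires a download.
* Bilinear resizing uses the half-pixel-center convention; its adjoint
  (exact transpose) backs the gradient.
* Probabilities are clamped at $10^{-7}$ before logarithms; AUC uses
  midranks, counting ties as one half.
* Metrics with zero denominators (e.g. no positives in a tiny split)
  return 0 with a warning rather than failing, so ablation tables stay
  total.
* A stratum of size one always goes to the training split; stratified
  splitting tops up per-stratum floors by largest remainder so the
  training total equals $\lfloor n \cdot \text{fraction} \rfloor$.

## Desk-scale problem sizes

The test and acceptance runs are sized for a single CPU: parameter
recovery trains the small preset (64-pixel input, channels 8/16/32/64,
one residual block per stage) for 30 epochs on 400 generated records and
expects at least 0.90 validation accuracy on both tasks; the directional
ablation trains `full`, `no_iim` and `osn` for 12 epochs on 200 records
across five seeds and checks that the full model's median validation
accuracy is never below its ablations'. Under these conditions the
planted signal is strong enough that all three variants typically
saturate near perfect accuracy, so the ordering holds largely through
ties — the comparison is a wiring check at this scale, not a power
study. Localization is scored on the recovery model's correctly
classified positive validation records.

## Known limitations

* The numerical engine is a compact tape-based implementation sized for
  the small preset; the clinical-scale preset builds and runs but is not
  tuned for speed, and there is no GPU path.
* JPEG input is not read directly (PNG is the bundled format); convert
  on ingest.
* The generator's anomalies are contrast discs; attention and
  localization results on textured, low-contrast clinical lesions will
  be harder than on synthetic data, and the package makes no clinical
  claim.

## Reproducing the run

```{r, eval = FALSE}
library(mtialm)
rs <- generate_dataset(generator_config(seed = 11))
sp <- split_records(rs, 0.8, seed = 11)
size <- dataset_psize_stats(rs)$chosen_global_size
train <- prepare_inputs(sp$train, 64, size)
val <- prepare_inputs(sp$val, 64, size, with_masks = TRUE)
fit <- train_model(build_model(model_config(), seed = 11),
                   train, val, schedule_config(), epochs = 30, seed = 11)
fit$best_val$m$accuracy
```
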