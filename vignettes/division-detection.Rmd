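---
title: "Detecting yeast division events with masked-autoencoder pretraining and a temporal transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting yeast division events with masked-autoencoder pretraining and a temporal transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In microfluidic aging experiments, single budding-yeast mother cells are held
in traps and imaged every 15 minutes for days, while each newborn daughter is
flushed away. A mother's replicative lifespan (RLS) is the number of daughters
she produces before ceasing to divide, so quantifying RLS means marking the
frame of every bud emergence in a movie of a few hundred frames — classically
a manual task of 20–30 annotations per cell, repeated for hundreds of cells.

`budcall` automates this with a two-stage model that needs only a small
annotated training set:

1. **Self-supervised pretraining.** A masked auto-encoder (MAE) vision
   transformer learns single-frame morphology from *unlabeled* crops: each
   64×64 crop is cut into 8×8-pixel patches, 75% of the patches are hidden,
   and an encoder/decoder pair is trained to reconstruct the hidden pixels
   under an L2 loss. The encoder thereby learns cell shape and texture
   without any division annotations.
2. **Supervised temporal detection.** Every frame of an 11-frame window
   (the frame of interest with five preceding and five subsequent frames)
   is embedded by the frozen pretrained encoder: the classification (CLS)
   token output concatenated with the mean of the patch-token latents
   (configurable; see below). Fixed sinusoidal temporal embeddings encode slot order, a
   lightweight 2-block temporal transformer mixes the sequence, and a
   two-way softmax on the center slot outputs the probability that a budding
   event occurs at the center frame.

Frame probabilities are thresholded (default 0.5) and consecutive positive
frames are merged into single division events; the event count is the RLS and
successive event gaps give cell-cycle-length trajectories.

## Why these design choices

**Two classes, one prediction per window center.** The classifier
distinguishes only budding vs non-budding at the window's center frame. This
keeps annotation cost minimal (one frame index per division) and avoids
multi-state lifecycle schemes.

**Frozen encoder by default.** Stage 2 can either freeze the pretrained
encoder (frame embeddings computed once and cached) or fine-tune it at a
10-fold reduced learning rate (`encoder_mode = "finetune"`). Freezing is the
default: with cached embeddings the temporal stage trains in seconds on a
single CPU, and on the synthetic benchmark it already recovers lifespans
nearly perfectly, so the extra cost of backpropagating through the encoder
for all eleven frames of every window buys nothing at this scale. Both modes
share all other code paths and both are exercised by the test suite.

**Loss on masked patches only.** The reconstruction objective averages the
squared pixel error over *hidden* patches (the canonical masked-autoencoding
objective); `loss_on = "all"` is available as a config switch since scoring
visible patches too is a defensible variant.

**Checkpoint and weight copies.** An exponential-moving-average (EMA) copy of
the MAE weights (decay 0.999) is maintained for stability and logged each
epoch; model selection uses the raw weights at the epoch with the lowest
validation loss, and the detector may be pointed at the `best`, `ema`, or
`final` copy (`encoder_weights`). The temporal detector is selected per epoch by two validation
signals: spurious event count on a small set of event-free validation movies
(fewest wins), then validation F1 at a ±1-frame tolerance. The event-free
control matters because lifespan counting tolerates very few false
positives: per-epoch diagnostics show checkpoints with near-identical F1
differing sharply in their false-positive rate on quiet movies, so F1 alone
cannot resolve the specificity that downstream RLS counting needs.

**Frame readout.** With a fine-tuned encoder the CLS-token output is the
natural frame summary, since supervised gradients teach it what to collect.
With a *frozen* encoder the CLS token is only as good as pretraining happened
to make it: the masked-reconstruction loss never constrains it directly, and
across pretraining runs its informativeness varies from excellent to
near-chance. Mean-pooled patch latents do not have this failure mode — every
patch latent is shaped by the reconstruction loss — so the frozen default
concatenates both (`frame_embedding = "cls_mean"`), keeping the CLS summary
where it helps while anchoring the readout to loss-trained features. Pure
`"cls"` and `"mean"` readouts remain available; the finetune path uses pure
CLS.

**Boundary policy.** The first and last five frames of a movie get
edge-replicated window slots (flagged per slot), so every frame receives a
prediction without fabricating motion. The same padding is applied at
training and inference.

**Positive span.** An annotation marks bud emergence at exactly one frame;
`positive_span` widens the labeled span if a dataset's annotation convention
marks short intervals instead.

**Event representative.** A merged run of positive frames is reported at its
first frame (bud-emergence semantics); a midpoint option exists and shifts
signed-error statistics accordingly. No refractory filter is applied by
default (merging only); `min_gap` provides one when wanted.

**Matching and scores.** Predicted and true events are paired by a Hungarian
assignment maximizing the number of pairs within `max_gap = 5` frames and,
among those, minimizing the total absolute offset; equal-cost ties resolve
deterministically toward lexicographically earlier pairs. Tolerance-window
precision/recall/F1 use the count identities (`F1 = 2tp/(2tp+fp+fn)`, so a
detector that predicts nothing scores 0 rather than "undefined");
exact/±1/±2 and early/late/unmatched fractions are reported over predictions
(unmatched predictions as their own class), with a ground-truth-denominated
switch. Lifespan agreement reports both the OLS R² of predicted on true RLS
and the identity-line variant. Cycle-length trajectories are binned at 2% of
lifespan and smoothed with a Savitzky–Golay filter (window 11, order 2).

## Hyperparameters

| Parameter | Default | Meaning |
|---|---|---|
| `patch_size` | 8 px | token size; 64 tokens per 64×64 crop |
| `mask_ratio` | 0.75 | fraction of patches hidden during pretraining |
| `encoder_dim/depth/heads` | 128/4/4 | ViT encoder ("tiny" desk scale) |
| `decoder_dim/depth` | 64/2 | reconstruction decoder, discarded after stage 1 |
| `base_lr`, `warmup_steps`, `cycle_steps`, `min_lr` | 1.5e-3, 100, 400, 1e-5 | warmup + cosine annealing with restarts |
| `ema_decay` | 0.999 | EMA weight copy |
| `grad_accum_steps` | 2 | micro-batches per optimizer step |
| `weight_decay` | 0.01 | decoupled (AdamW); layer-norm gains and biases exempt |
| `epochs` (MAE) | 30 | desk-scale pretraining budget |
| `epochs` (detector) | 20 | temporal-stage budget; checkpoint chosen by validation |
| `n_val_negatives` | 30 | event-free validation movies steering checkpoint choice |
| `window` | 11 frames | temporal context (center ± 5) |
| `temporal_dim/depth/heads` | 64/2/4 | temporal transformer |
| `threshold` | 0.5 | probability cut for a positive frame |
| `frame_interval_min` | 15 | acquisition cadence |

All numerics run in single precision with hand-derived backward passes
(verified against finite differences in the test suite); training is
deterministic given the seed on a single device.

## The synthetic benchmark

Real mother-machine data is large and annotation-bound, so the package ships
a generator that emulates the geometry of trap imagery: a bright elliptical
mother body in a fixed trap position (Gaussian per-frame center jitter), and
at each scheduled division a bud disk emerging on the channel-facing side,
growing linearly to 5 px radius over 4 frames before being flushed. Pixel
noise is Gaussian (σ = 0.05 on a [0,1] scale) and per-frame multiplicative
illumination shifts are available. Division schedules draw RLS from
N(24, 4²) — matching ~1,000 division events per ~40 training cells and the
20–30 buds per cell typical of wild-type aging — with young cycles of ~6
frames (~90 min) lengthening linearly 2.5-fold across life, emulating
late-life cell-cycle slowdown. Movies are written as 16-bit multi-page TIFFs
with `cell_id,event_frame` annotation CSVs, and round-trip through the same
readers used for real data.

What the generator does *not* emulate: phase-contrast optics (halos, focus
drift), debris and neighboring cells, elongated daughter morphologies
(an aspect-ratio knob exists on the mother only), segmentation/tracking
errors in the centroids, and cell death morphology. Passing the synthetic
benchmark therefore demonstrates that the architecture, training loop, and
post-processing recover known division schedules under noise, jitter, and
class imbalance — not that any fixed accuracy transfers to a particular
microscope; on real data the pretraining corpus and annotated set would be
swapped in through the same interfaces.

## Problem sizes and degenerate inputs

The shipped study conditions — used by the test suite and the acceptance
script — are: 40 training-pool cells (cell-exclusively split 80/20 for
validation), 20 held-out evaluation cells, 2,000 pretraining crops, 30 MAE
epochs, 12 detector epochs, ~250 frames per movie. On these sizes a full
pipeline run takes roughly ten minutes on one CPU core.

Degenerate inputs are handled explicitly: empty timelines are legal
everywhere (RLS 0, empty cycle series); single-frame movies produce one
fully padded window; an all-background movie is a valid negative control;
matching accepts empty prediction or truth sets; zero-denominator scores are
returned as flagged `NA`, never silent `NaN`; `sd = 0` normalization, odd
window lengths, non-even embedding dimensions, and overlapping bud episodes
are rejected with errors (the generator can alternatively truncate
overlapping episodes, which it reports).

## Known limitations

- The CLS embedding is the only information passed between stages; daughter
  morphology is not quantified.
- The synthetic benchmark's difficulty is bounded by its renderer; headline
  synthetic scores should be read as an upper bound on real-data behavior.
- Fine-tuning the encoder is implemented but CPU-expensive; at desk scale it
  is an ablation path rather than the default.
- `smooth_cycle_trajectory` requires at least `window` occupied lifespan
  bins, so it needs a cohort, not a single cell.

## A minimal run

```{r}
library(budcall)

cfg <- run_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "artifacts", verbose = TRUE)

res$report$scores$f1          # detection F1 at +/-1 frame on held-out cells
res$report$lifespan$r_squared # predicted vs true RLS
summary(res$detector)

# score any prediction/truth CSV pair the same way
tls <- read_annotations("artifacts/truth.csv")
```
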