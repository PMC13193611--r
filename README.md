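# budcall

Division-event detection and replicative lifespan (RLS) quantification for
single-cell yeast aging movies.

In microfluidic "mother machine" experiments, trapped *S. cerevisiae* mother
cells are imaged every 15 minutes across their whole lives while daughters
are flushed away. The number of budding events a mother completes is her
replicative lifespan; extracting it from phase-contrast movies normally means
manually marking every bud emergence — tens of thousands of annotations per
dataset. `budcall` automates this with a two-stage transformer framework
designed to need very little labeled data:

1. **Masked auto-encoder (MAE) pretraining** — a vision transformer encoder
   learns single-cell morphology from unlabeled 64×64 crops by
   reconstructing hidden patches: each crop is split into 8×8-px patches, a
   fraction *r* = 0.75 is masked, and encoder + decoder minimize the L2
   reconstruction error on the hidden pixels. Training uses AdamW, gradient
   accumulation, warmup + cosine-annealing-with-restarts, an EMA weight
   copy, and validation-loss checkpointing.
2. **Temporal transformer detection** — each frame *t* of a movie is scored
   by embedding the 11-frame window (*t* − 5, …, *t* + 5) with the
   pretrained encoder's CLS token, adding sinusoidal temporal embeddings,
   and passing the sequence through a small temporal transformer whose
   center-slot output feeds a two-way softmax:
   P(budding at *t*) = softmax(W h_center)₁. Training is cross-entropy on
   class-balanced batches; checkpoints are selected by spurious-event count
   on event-free validation movies, then validation F1 at ±1 frame.

Post-processing merges consecutive positive frames into single division
events (RLS = event count; inter-event gaps give cell-cycle trajectories).
Evaluation pairs predicted and true events one-to-one with the Hungarian
algorithm (max pairs within ±5 frames, then minimal total offset) and
reports tolerance-window precision/recall/F1, exact/±1/±2 fractions,
early/late/unmatched breakdown, mean signed error, and OLS R² of predicted
vs true RLS.

Because real mother-machine data is not shipped, the package includes a
synthetic movie generator with known division schedules (mother body in a
trap, buds emerging and growing over 4 frames before being flushed,
configurable noise/jitter/illumination) so the whole pipeline is trainable
and verifiable at desk scale.

## Worked example

```r
library(budcall)

cfg <- run_config(seed = 1)      # 40 training cells, 20 held-out cells
res <- run_pipeline(cfg, verbose = TRUE)

print(res$detector)
#> Budding-event detector (temporal transformer over MAE embeddings)
#>   window 11, temporal dim 64 depth 2 heads 4, encoder frozen
#>   trained 20 epochs; selected epoch 20 (val F1 +/-1 = 0.984)

res$report$scores$f1             # 0.990  F1 at +/-1 frame, held-out cells
res$report$scores$precision      # 1.000
res$report$scores$recall         # 0.980
res$report$lifespan$r_squared    # 0.971  predicted vs true RLS (n = 20)
res$report$lifespan$error_sd     # 0.69   divisions
res$negative_control$n_event_free  # 10 of 10 event-free movies stay at RLS 0
```

Those numbers say: on 20 held-out synthetic mother cells (492 true division
events), every retained prediction falls within one frame of a true
bud-emergence frame (98% exactly on it), 98% of true divisions are
recovered, and per-cell lifespans match the ground truth to well under one
division. The untrained-detector baseline (`res$baseline_report`) trails by
more than 0.6 F1 — the accuracy comes from learned representations, not from
the architecture or post-processing — and event-free control movies stay
event-free.

Individual stages are exposed as ordinary fitting functions returning classed
objects (`mae_pretrain()` → `"bud_mae"`, `train_detector()` →
`"bud_detector"`, both with `print`/`summary`/`predict`/`plot` methods), and
the building blocks (`patchify()`, `random_masking()`, `collapse_runs()`,
`match_events()`, `detection_scores()`, `lifespan_agreement()`,
`smooth_cycle_trajectory()`, …) are usable on their own. A thin CLI lives at
`inst/cli/budcall.R` (`simulate`, `run`, `predict`, `evaluate`, `config`).

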