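---
title: "m6acnn: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6acnn: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`m6acnn` classifies 51-nt RNA windows as methylated (m6A at/near the
central adenosine) or not, using a small fixed convolutional network over
one-hot encoded sequence. This vignette records what the model assumes,
what every tunable parameter means, and the choices made where the design
was genuinely open. It states no empirical claim that the test suite or
the acceptance script does not itself compute.

## The classification model

**Input.** A window is a string over {A, C, G, U}; DNA-style input is
normalized (upper-cased, T→U). One-hot encoding maps residue *i* to row
*i* of a 51 × 4 binary matrix with the fixed channel order A, C, G, U.
Rows (positions) come first and channels last; the alternative
orientation (4 × 51) appears in some descriptions of this encoding, but
the channels-last layout is the one consistent with the network's
declared input shape (51, 4) and is used throughout. Ambiguity codes
(e.g. N) are rejected by default; a documented permissive mode encodes
them as all-zero rows (and decodes such rows as N). An optional check
requires the central position (26 of 51, 1-based) to be adenosine — a
biological expectation for m6A windows, not a format rule, hence off by
default.

**Architecture.** Two identical blocks of
Conv1D(16 filters, kernel 5, stride 1) → ELU → GroupNorm(4 groups) →
MaxPool1D(pool 4, stride 2), then Flatten → Dropout(0.35) →
Dense(32, ELU) → Dense(1) → sigmoid. The published output-shape trace
(51 → 47 → 22 → 18 → 8 on the sequence axis) forces two arithmetic
conventions which the package adopts: convolutions are **unpadded**
("valid"; 51 → 47 with kernel 5 is impossible under same-padding), and
pooling uses **floor** division (47 → 22 with pool 4 / stride 2).
`infer_shapes()` implements this calculus purely; it is cross-checked in
the tests against a brute-force sliding-window enumerator and against the
dimensions the live network actually produces.

**Regularization.** L2 penalties enter the loss as λ·Σw² per layer
(λ = 0.001 on both weights and bias of each convolution, 0.0001 on the
32-unit dense layer). The final 1-unit layer is stated without a
regularizer and is left unregularized. Dropout (rate 0.35, inverted
scaling) is active in training mode only; two inference passes on the
same input are bit-identical.

**Training.** SGD with momentum 0.95 (v ← μv − η∇; w ← w + v), learning
rate η = 0.003, binary cross-entropy, at most 100 epochs of shuffled
mini-batches of 32. After each epoch the validation fold is scored; the
parameters with the best monitored value are checkpointed and training
stops once `patience = 30` epochs pass without improvement. The sigmoid
is fused with the loss through the logit for numerical stability.

## Open choices and how they were fixed

* **Checkpoint monitor.** The protocol description ties checkpoints to
  the *highest validation accuracy* while hyperparameter selection uses
  *minimum validation loss*. Within a fold the package monitors
  validation accuracy (`monitor = "val_acc"`, the default) and records
  the per-epoch validation loss, whose minimum is what the grid search
  ranks by. `monitor = "val_loss"` (and the CLI flag `--monitor`) switches
  the within-fold criterion for users who prefer one consistent quantity.
* **ELU α = 1** and **GroupNorm ε = 1e-5** (conventional defaults; both
  unstated upstream). GroupNorm partitions the 16 channels into 4
  contiguous groups of 4 and normalizes per sample — it has no batch
  dependence and therefore no train/inference discrepancy.
* **Initialization.** Glorot-uniform weights, zero biases, unit
  group-norm scale, all drawn under the run's seed; every artifact
  records the seeds needed to reproduce it.
* **Classification threshold 0.5** on the sigmoid output (no threshold is
  stated upstream); exposed as `--threshold`.
* **Stratified folds by default.** The protocol only says "shuffle and
  split"; plain shuffling can produce degenerate near-single-class
  validation folds at small n. Stratification deals each class
  round-robin (continuing the rotation across classes so overall fold
  sizes still differ by at most one: 2,614 records → four folds of 262
  and six of 261). `--no-stratify` restores plain shuffling.
* **Pooled ROC.** A single AUC per dataset is reported from the pooled
  out-of-fold scores (each record is scored exactly once, by the
  repetition that held it out); per-fold AUCs and their mean are also
  emitted, since it is unstated which aggregation a single published AUC
  refers to.
* **MCC at zero denominator is 0** (the information-free convention).
* **Grid search scope.** One value per axis is shared across all conv
  blocks of a candidate (the published two-block optimum has identical
  blocks, and per-layer variation would explode the 3,920-point grid).
  Candidates whose shape calculus underflows the 51-nt axis are
  enumerated but marked infeasible and never trained. Search evaluates
  one fixed stratified 90/10 split — not nested cross-validation, which
  is out of desk scale at 3,920 candidates — and a seeded `--budget`
  subsample makes partial searches reproducible. For filter counts not
  divisible by 4 (6, 44 are in the grid), group normalization uses the
  largest of {4, 2, 1} that divides the channel count.
* **Final-layer regularization** none (see above); **conv bias L2**
  equals the weight L2 (0.001 "for both" is the stated convention).

## The synthetic benchmark

Real m6A benchmarks (M6A2614: 1,307 + 1,307 windows; M6A6540:
3,270 + 3,270; both 51 nt, redundancy-reduced upstream with CD-HIT-EST)
must be downloaded, so the package generates structurally matched stand-in
data: balanced sets of 51-nt windows in which positives carry a
DRACH-like consensus motif (default `GGACU`) at a fixed 0-based offset 24
with a configurable insertion probability (default 1), all other
positions i.i.d. uniform over A/C/G/U; negatives are pure background,
re-drawn if the motif arises at the offset by chance (elsewhere it may
occur freely, keeping the signal localized). With offset 24 the motif's
adenosine sits one position right of the window midpoint; the exact
placement is immaterial to the classifier, which only needs a fixed
signal. A permuted-label null generator provides the negative control.

What a green test on this data does establish: the encoder, network,
optimizer, early stopping, fold rotation and metric suite interoperate
correctly, the model can extract a localized sequence signal to
near-perfect accuracy, and it finds nothing in signal-free data (CV
accuracy statistically at 0.5). What it does **not** establish: the
published accuracies on the real benchmarks (≈89% / ≈87%), which depend
on genomic background composition, degenerate motif context and
similarity structure that uniform-background planted-motif data does not
emulate. Reproducing those numbers requires the external FASTA files; the
CLI (`m6acnn cv --pos ... --neg ...`) runs the identical protocol on them.

## Numerical notes

* Valid-convolution/pool length: ⌊(L − k)/s⌋ + 1; an architecture whose
  kernel or pool exceeds the remaining length raises an infeasibility
  error (this is what prunes the deep/aggressive corner of the grid).
* Max-pool ties resolve to the earliest window position, making the
  backward scatter deterministic.
* Group-norm variance is the biased (population) estimator, as is usual
  for normalization layers.
* The engine's analytic gradients are checked against central finite
  differences (relative error < 1e-5 enforced in tests; observed ≈ 1e-8)
  over every parameter tensor of a stack containing all layer types.
* Training is bit-for-bit reproducible given the seed: fold assignment,
  initialization, shuffling and dropout masks all derive from it.
  Checkpoints serialize to JSON at ~15 significant digits, so a
  saved-then-loaded model reproduces predictions to that precision.
* Per-fold training seeds are derived as `seed + 7919·t` (kept below
  2³¹), so repetitions are independent but jointly reproducible.

## Limitations

* Training is CPU-bound single-threaded R + BLAS; a 2,000-record 10-fold
  run takes a few minutes. The engine is meant for this model family
  (small 1-D CNNs), not as a general deep-learning framework.
* Only fixed-length windows are supported (length 51 by default;
  other lengths work if all sequences share them and the architecture
  remains feasible).
* The grid search trains each candidate once on one split; rankings
  between near-tied candidates carry that split's noise.
* The synthetic generator makes no attempt to model genomic background
  composition, transcriptome redundancy, or the degenerate DRACH
  alphabet; see above for what that implies about test evidence.
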