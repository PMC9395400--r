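---
title: "Iterative label-noise screening for two-class image datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative label-noise screening for two-class image datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LabelSweep)
```

## The problem

Binary-class medical image collections — the motivating case is endoscopy
frames labeled *early lesion* versus *not* — are expensive to annotate and
the annotations are imperfect. Two kinds of harmful records accumulate:

* **Label noise**: the image is fine but the label is wrong. Within a
  two-class set this is either an *intra-class* flip (one class labeled as
  the other) or an *extra-class* intrusion (an image from outside both
  classes, e.g. a different organ, relabeled into one of them).
* **Background noise**: the label is right but the content is nearly
  useless — the target is blurred, occluded, remote or tiny — so the
  record hurts training more than it helps.

LabelSweep implements an automatic screen for such records that does
**not** require any verified-clean subset to bootstrap from.

## The screening model and loop

The screen rests on the low-density-boundary assumption from cluster
analysis: the decision boundary of a two-class problem lies in a
low-density region of image space. Within a short training budget a
classifier trained on the noisy set learns each class's *common* features
from the high-density bulk; records that contradict those features —
mislabeled images sitting deep inside the other class's region, and
degraded images carrying no class signal — end up on the wrong side of the
model's boundary.

The loop (`cleanDataset()`) is:

1. Train a freshly initialized classifier on **all** remaining images (the
   set being cleaned is its own training set), for `epochsPerRound` passes.
2. Classify the same images in inference mode; every image whose predicted
   class differs from its observed label is flagged and deleted.
3. Repeat. Stop when the flagged fraction of the current set drops below
   `stopThreshold`, after `maxRounds` rounds, or when one class would be
   exhausted.

The model is re-initialized from scratch every round (seed
`baseSeed + round`), which prevents the accumulated memorization of
residual noise across rounds; deletion is permanent within a run. When a
train/validation/test design exists, the screen is meant for the train and
validation portions only — a verified test set needs no cleaning.

The screening network, `vggNinSpec()`, is a VGG16-with-batch-norm
convolutional trunk whose ~120M-parameter fully connected head is replaced
network-in-network style by two 1×1 convolutions (512→2048, 2048→2048,
each with bias, batch norm and ReLU), global average pooling, and one
2048→2 linear layer: 19,982,402 trainable parameters against 134,277,186
for the VGG16-bn baseline (`vgg16bnSpec()`). The widths of the two 1×1
layers are not dictated by the design pattern alone; 2048/2048 with batch
norm on both is the integer configuration whose analytic budget reproduces
the 19,982,402 total exactly, and it is adopted here as the definition.
Other exact-solution width pairs may exist; the budget, not the width, is
the constraint. The nonlinearity after each added 1×1 layer matches the
trunk's (ReLU), and "pooling" after them is global average pooling, the
network-in-network idiom.

`parameterBudget()` computes the analytic layerwise count (conv:
`in·out·k² + out`; batch norm: `2·channels`; linear: `in·out + out`), and
`buildModel()` allocates real arrays whose entries always sum to exactly
that number — the package's tests verify the identity bit-exactly for
every shipped architecture.

## Evaluation metrics

With `ALL` images of which `ATW` are truly erroneous, and a flagged set of
`MW` images of which `TW` are truly erroneous:

* error rate `E_rate = 100·ATW/ALL`,
* filtering accuracy `F_acc = 100·TW/MW` (precision of the screen),
* filtering recall `F_rec = 100·TW/ATW`.

Internally every value is an exact ratio, so the identity
`F_acc·MW = F_rec·ATW = 100·TW` holds to machine precision; rounding is a
display concern only. Report formatting (`roundPercent()`,
`formatPercent()`) rounds half-away-from-zero at the requested precision,
one decimal by default with an integer option. Published tables of this
kind occasionally truncate instead of round; recomputed values can
therefore disagree with a printed percentage by one unit in the last digit
even when the underlying counts agree exactly, which is why
`evaluateCleaning()` exposes the raw counts alongside the percentages.

Which noise tags count as "true error" is configurable
(`errorTags` in `evaluateCleaning()`), so intra-class, extra-class and
background noise can be scored separately, mirroring how the three noise
types behave very differently under the screen.

## The training engine

No deep-learning framework is assumed: the package carries a compact,
fully deterministic training engine for the layer vocabulary the
architectures need (3×3 and 1×1 convolutions with same padding, batch
norm, ReLU, 2×2 max-pooling, global average pooling, linear layers),
written as vectorized matrix algebra — convolutions are im2col gathers
followed by one BLAS product, with index tables cached per shape. Training
uses softmax cross-entropy and AdamW (β₁ = 0.9, β₂ = 0.999, decoupled
weight decay 0.01 on weights only), batches of 32, no augmentation.

The learning rate is variable: at every `plateauWindow` (default 200)
batch boundary, the mean loss over the latest window is compared with the
mean over the window before it, and the rate is halved when it has not
decreased (floored at `minLearningRate`). Window means are the only
well-defined reading of "does not decrease" for noisy per-batch losses;
the comparison is `recent >= previous`, so an exactly flat loss halves.

Numerical conventions worth knowing: batch norm uses ε = 1e-5 and running
statistics with momentum 0.1 (inference always uses running statistics);
exact logit ties predict class 0 (the class listed first in the manifest),
making flagging deterministic; weight initialization is He-style normal
with zero biases, fixed by the seed. The engine's backward pass is
validated against central finite differences in the test suite.

### The "specified batch" per round

The per-round training budget is deliberately short: the default is **5
epochs** over the current set. The screen depends on this — long enough
for the model to learn the class structure from the clean majority, short
enough that it has not yet memorized individually mislabeled images. Both
halves of that trade-off degrade the screen: with many more epochs a
sufficiently large model starts reproducing wrong labels (flips stop being
flagged); with far fewer it misclassifies clean images (precision drops).

## Desk-scale defaults and the reference network

`smallReferenceSpec()` preserves the screening architecture's topology —
conv trunk, two 1×1 convolutions, global average pooling, linear head — at
11,842 parameters, trainable on one CPU in minutes. The synthetic
benchmark runs at 32×32 pixels; the full-scale default of 224×224 and the
full VGG_NIN remain available for real data (`cleanerConfig()` defaults to
224). The pipeline is size-agnostic: images are resized to the configured
resolution at load time.

Problem sizes used by the shipped checks were chosen to keep a complete
run in minutes on a single core: the headline benchmark uses 2,000 images
(1,000 per class, 40 patient-like groups) with 30 flips per class (a 3%
error rate), screened for up to 10 rounds; the flip-rate sweep uses 600
images at rates 1%, 4% and 12%; unit tests use 16×16 sets of tens of
images.

## What the synthetic generator emulates — and what it does not

`generateSyntheticDataset()` writes two parametric texture families:
oriented sinusoidal stripe fields with a warm red-dominant tint (class 0)
and Gaussian blob fields with a green-dominant tint (class 1), plus
per-image pixel noise (sd 0.04). Each image belongs to a patient-like
group; all images of a group share a color shift and texture-parameter
base, so within-group appearance correlates — the property that makes
group-disjoint splitting (`splitByGroup()`, greedy 70/15/15 allocation of
whole groups) matter. Distractors for extra-class noise
(`injectExtraClassNoise()`) are a third family, blue-tinted diagonal
checkerboards, unlike either class. Background degradation
(`degradeBackground()`) rewrites a record's image with heavy blur plus
contrast collapse, occluding neutral rectangles, or the content shrunk to
about 6% of the frame on a neutral background — all three converge toward
a class-neutral "generic mucosa" appearance, emulating frames whose
diagnostic content is effectively absent. Degradation is applied to
still-clean records (one noise tag per record; degrade before injecting
label noise when staging experiments).

The two classes are separable by first-order color statistics *by
construction* — a nearest-centroid classifier on raw pixels exceeds 95%
accuracy — which is precisely what gives the screen its signal and gives
the tests an independent oracle. Real endoscopy data is far harder: class
evidence is subtle, localized and entangled with acquisition conditions.
Passing the synthetic benchmark therefore demonstrates that the
*mechanism* (train → flag → delete → stop) works when class structure is
learnable; it does not certify any particular recall on clinical data. The
same caveat applies in reverse to precision: on the easy benchmark the
screen's precision saturates near 100%, so the known trend of precision
rising with the flip rate appears here in the weak (non-strict) sense,
whereas published results on real data show it rising through the 50–90%
range.

## Design choices where the design was open

* **Epochs per round** (5) and **stop threshold** (0.5% of the current
  set per round) are defaults, both configurable; 10 rounds maximum
  matches standard practice for this screen.
* **Re-initialize vs. warm-start between rounds**: re-initialize, to keep
  each round's flags driven by the current data rather than by the
  previous round's memorized residue.
* **Unreadable image files are flagged**, not skipped: a file that cannot
  be decoded is by definition a background-noise candidate.
* **No pretrained weights anywhere**: initialization is deterministic
  random, keeping every result reproducible offline from a seed.
* **Degradation targets clean records only**, so each record carries one
  unambiguous noise tag.
* **Greedy group allocation** for splitting: groups in seeded random
  order, largest first, each to the split with the largest remaining
  image deficit (ties favor train, then validation). Ten equal groups at
  70/15/15 land on 7/2/1.

## Known limitations

* Two classes only; the flag rule "predicted ≠ observed" does not
  directly rank multi-class confusions.
* Extra-class noise is screened much less reliably than intra-class flips
  — consistent with how such images sit *between* the two learned
  clusters rather than inside the wrong one.
* The flagged set intentionally includes hard-but-correct images near the
  boundary; on real data a manual review of the flagged set remains
  advisable. The package reports flagged ids rather than deleting files.
* The training engine favors determinism and clarity over speed; it is
  adequate for desk-scale screening and for full-resolution runs with
  patience, not a general-purpose deep-learning stack.
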