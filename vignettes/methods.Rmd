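---
title: "Prompting a frozen mask decoder with category descriptors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompting a frozen mask decoder with category descriptors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Counting and typing cell nuclei in H&E-stained tissue is a routine need in
computational pathology: the balance of lymphocytes, plasma cells,
neutrophils and eosinophils around a tumour carries prognostic information.
The obstacle is the long tail of the class distribution -- in large colon
nuclei atlases roughly 92% of instances belong to three frequent categories
(epithelial, lymphocyte, connective), about 6% are plasma cells, and under
2% are neutrophils or eosinophils combined. Networks trained with ordinary
per-pixel losses drown the rare categories in negative gradients.

`nucleiprompt` implements a prompting approach to this problem. A
promptable segmentation foundation model (a frozen image encoder, prompt
encoder and mask decoder in the style of the Segment Anything family) is
never fine-tuned. Instead, the package learns:

1. **Category descriptors** -- for each of the `C` nuclei categories plus a
   background and a boundary channel, a stack of `K` learnable prompt
   tokens (default `K = 32`). Feeding channel `c`'s stack to the frozen
   decoder elicits that channel's mask. Segmentation and classification
   come "for free" from running the decoder once per channel on a shared
   image embedding.
2. **A domain-alignment adapter** -- `L` inverted-residual layers (default
   `L = 12`, bottleneck width 96) inserted between the patch-embedding
   layer and the frozen transformer blocks. It shifts the *low-level*
   statistics of histopathology crops toward what the frozen high-level
   blocks expect, leaving the high-level representation untouched. Every
   layer's output projection is zero-initialized, so a fresh adapter is
   exactly the identity and training starts from the vanilla frozen-model
   behaviour. This identity-at-init property is asserted bitwise in the
   test suite.

The three-way supervision (per-class foreground, background, boundary) is
the classic three-class trick for instance segmentation: the boundary
channel lets connected-component decoding split touching nuclei.

## The objective

Training minimizes a per-channel binary cross-entropy restricted twice:

* **Federated presence rule.** A nuclei-category channel contributes loss
  only on crops where that category appears. Rare-class descriptors
  therefore never receive spurious negative gradients from the vast
  majority of crops that lack them. The background and boundary channels
  are treated as always present (a design choice: the presence rule as
  stated concerns cell types; background and boundary exist in essentially
  every crop).
* **Multi-class hinge margin.** With margin `gamma = 0.2` (in probability
  units), a pixel contributes on channel `c` only while its probability
  gap -- `p_c - max(other channels)` where the channel is the target,
  `max(target channels) - p_c` where it is not -- is strictly below
  `gamma`. Confident pixels are silenced entirely (a hard mask, not a soft
  weight). Gap ties at exactly `gamma` count as confident; the margin is a
  *minimum required* gap.

Aggregation defaults to `"channel_mean"`: the mean over each active
channel's contributing pixels, averaged over active channels. This keeps
the loss invariant to crop size *and* gives every active channel equal
gradient weight. The alternative global mean (`"mean"`) weights channels
by their pixel count, and under a long-tailed mixture the mid- and
rare-frequency channels then receive so little gradient mass that they
are still far from convergence when the step budget ends -- empirically
the single largest factor in end-to-end detection quality here. A
consequence worth knowing either way: the textbook monotonicity property
("raising a correct pixel's probability never increases the loss") holds
exactly under `aggregation = "sum"`; under the means it can be violated by
the changing normalizer when a low-loss pixel leaves the ambiguous set.
The tests check monotonicity under the sum.

The margin comparison runs over *all* channels, not only nuclei channels;
with per-channel sigmoids there is no softmax coupling, so restricting the
comparison would leave background confidence unchecked.

## Long-tail sampling and augmentation

Scenes containing rare categories are oversampled by repeat factor
sampling: category factor `r(c) = max(1, sqrt(t / f(c)))` with `f(c)` the
fraction of scenes containing `c`, scene factor the maximum over present
categories, threshold `t = 0.3` by default. Fractional factors are
realized per epoch by stochastic rounding (floor plus a Bernoulli draw on
the fractional part), reseeded every epoch.

Crops are augmented by flips, multiples of 90 degrees (so label maps are
never interpolated), and photometric brightness/contrast/saturation jitter
with factors in `1 +/- 0.2`. Channel targets are derived *after* the
spatial augmentation, so supervision always stays aligned; photometric
jitter by construction cannot move a label.

The optimizer is Adam at `1e-3` with a linear warm-up and a step decay to
`1e-4` for the last 2 of 20 epochs.

## Inference

Full images are processed by a sliding window (256-pixel windows, step
128 by default; the surrogate fixtures use 128/64). Each window's channel
maps are decoded to instances: per-pixel argmax over all channels,
8-connected components per nuclei class, components under `min_area = 10`
pixels dropped, and surviving components grown back into adjacent
boundary-argmax pixels by geodesic dilation (ties go to the larger
component, exact area ties to the lower id) so instances recover the rim
the boundary channel carved away. The instance score -- used for AP
ranking and refinement ordering -- is the mean class-channel probability
over the instance's pixels; the decoder's mask-quality scalar is exposed
separately as the per-channel confidence.

Stitching keeps an instance iff its centroid falls in its window's central
region. For regularly spaced windows this is the classic
`[x0 + size/4, x0 + 3 size/4)` box; in general the package places the cut
between neighbouring windows at the midpoint of their spans and extends
border regions to the image edge. The midpoint rule is what makes the
central regions a *partition* even when the trailing window is clamped to
the image edge (with a literal quarter-size box, a clamped window's region
would overlap its neighbour's); it reduces exactly to the quarter-size box
in the regular case.

**Point-prompt refinement.** Interactive foreground/background points join
the channel's token stack through the same Fourier positional code used
for the image grid, and additionally contribute a local additive logit
bias (a Gaussian bump, amplitude 4 logits, sd 6 px, signed by polarity) on
their own channel -- the surrogate decoder's concrete mechanism for the
locality that a trained promptable decoder exhibits. The evaluation-mode
refinement loop emulates an annotator: per round and per category, the
ground-truth instance with the lowest current confidence (undetected
first) receives one centroid point, each instance at most once.

## The surrogate backend

No tensor runtime ships with the package; the backend contract is
implemented by a miniature, fully self-contained surrogate written as
matrix code with hand-derived backward passes (gradient-checked against
finite differences in the test suite): patch embedding (default patch 16,
width 64), two pre-norm transformer blocks, and a one-round
two-way-attention decoder with an IoU-style confidence head. All surrogate
weights are randomly initialized once and permanently frozen -- only the
adapter and the descriptor bank ever receive gradients, and the frozen
parameter checksum is asserted unchanged across training. A real ViT-B
checkpoint satisfies the same contract (`create_backend("vit_b")`) but
requires external weights and a tensor runtime, so it is config-selectable
yet not runnable here.

Emulating a *pretrained* promptable decoder with frozen *random* weights
requires a few deliberate structural choices, each of which a trained
foundation decoder exhibits natively:

* **Descriptor-seeded mask slot.** The decoder's mask-token slot is seeded
  with the mean of the channel's descriptor stack. A trained decoder
  learns to route prompt identity into its mask token; a frozen random one
  cannot, and with a purely shared mask token the per-channel probe
  vectors come out 60--95% correlated -- the channels are then barely
  separable no matter what the adapter does.
* **Mask prior.** Mask logits carry a frozen negative bias (-2), so a
  channel prompted with untrained descriptors predicts *near-zero*
  probability everywhere rather than ~0.5 noise. Without it, channels
  whose class is absent from most training crops (exactly the rare ones
  the federated loss deliberately leaves untouched) retain strong random
  activations and steal pixels from the per-pixel argmax at inference.
* **Sub-pixel mask head.** Each grid cell's logit is expanded to a 2 x 2
  block through four frozen probe projections (the analogue of a learned
  upscaling head), doubling effective mask resolution beyond the patch
  grid. A 4 x 4 expansion was also evaluated and is counterproductive
  here: with 8 channels it asks 128 linear readouts of a 64-dimensional
  feature vector.
* **Shared query/key projections** in the cross-attentions, so inner
  products between positional codes survive the frozen random projection;
  this is what makes point prompts spatially selective through a frozen
  decoder.

The trained fixtures use patch 8 on 128-pixel crops (a 32 x 32 effective
logit grid), which resolves nuclei of radius 4--12 px well enough for
object-level detection, though 1-pixel boundary rims remain at the edge of
what the surrogate can represent -- touching pairs are occasionally
merged. This is a surrogate limitation, not a property of the method with
a full-scale backbone.

A last protocol note: experiments evaluate the *final* model of the
20-epoch schedule, not the best-validation-loss checkpoint (both are
saved). The hinge-masked loss measures only ambiguous pixels and is a
poor proxy for object-level F1; the step decay in the last two epochs is
precisely what settles the final model.

## The synthetic scene generator

The generator is the test substrate standing in for real annotated tissue.
It emulates, at roughly 0.5 um/px: elliptical nuclei with smooth radial
shape noise; per-class size/shape priors (small round lymphocytes,
elongated spindle-shaped connective nuclei, large epithelial nuclei);
hematoxylin-like purple fills with class-specific tints (eosinophils
shifted red, neutrophils slightly blue) and a darker rim standing in for
peripheral chromatin; a pink eosin background; additive Gaussian noise
(sd 8 intensity levels); a configurable fraction (default 0.2) of nuclei
placed in 8-adjacent contact with a neighbour without ever overlapping
(single-label maps); and the long-tailed category mixture 0.45 / 0.28 /
0.194 / 0.059 / 0.0085 / 0.0085 for epithelial / lymphocyte / connective /
plasma / neutrophil / eosinophil, i.e. 92.4% frequent mass, 5.9% plasma
and 1.7% split across the two rarest types. Default scenes are 128 x 128
with 20 nuclei.

What it does *not* emulate: real chromatin texture, stain variability
between labs, out-of-focus blur, overlapping (multi-label) nuclei, or
scanner artifacts. Passing the end-to-end tests therefore demonstrates
that the pipeline's mechanics -- supervision, optimization, decoding,
stitching, evaluation -- work as specified, and that the adapter and
descriptors can exploit colour/size/shape cues; it does not certify
performance on real tissue, where the discriminative cues are far
subtler.

## Numerical and protocol choices

* **Boundary thickness** defaults to 1 pixel at 8-connectivity (the
  erosion-depth definition); the thickness is a config knob since
  three-class practice varies.
* **Background channel** is exactly `instance_map == 0`; boundary pixels
  belong to instances, and class channels exclude them, so the three-way
  supervision is mutually consistent and each pixel carries at least one
  positive target.
* **Matching for F1** uses IoU strictly greater than 0.5, class-aware,
  greedy by descending IoU with ties broken toward the lower ground-truth
  id. Greedy is provably optimal when each prediction overlaps at most one
  ground-truth instance above threshold, which holds for compact nuclei;
  the tests cross-check against exhaustive assignment. Categories with
  neither ground truth nor predictions are excluded from the F1 mean
  rather than awarded a vacuous 1.0.
* **mAP** follows the COCO protocol: thresholds 0.50 to 0.95 in steps of
  0.05, score-ranked per-image matching at IoU >= threshold, 101-point
  interpolated AP, categories without ground truth excluded.
* **Wilcoxon comparisons** use the standard signed-rank test, one-sided,
  zero differences discarded, mid-ranks for ties.
* **Decoding** applies pure argmax with no probability threshold; a
  threshold would add a parameter without changing the argmax winner on
  confident pixels, and the background channel already absorbs uncertain
  regions.
* **Descriptor initialization** is small-scale Gaussian (sd 0.1); layer
  normalization inside the decoder makes the scale uncritical.
* **One decoder call per channel**, with the channel's full token stack as
  sparse prompts on a shared embedding: channels stay independent (adding
  a point to one channel provably changes only that channel) at the cost
  of `C + 2` decoder invocations, which the shared embedding keeps cheap.

## Problem sizes used by the tests and the acceptance script

The shipped experiments train the surrogate (patch 8, width 64, 2 blocks)
with `K = 32` descriptors per channel and a 12-layer adapter on 40
generated 128-pixel scenes for up to 1000 Adam steps, evaluate object F1
and mAP on 10 held-out scenes, repeat the run without the adapter as the
ablation control, and run 4 rounds of point-prompt refinement on a held-out
subset chosen (deterministically) to contain every category. Simulator
statistics use 200 scenes. These sizes were chosen so a single CPU core
completes the whole battery comfortably while every check still exercises
the full pipeline end to end.

## Known limitations

* The surrogate's patch-grid mask resolution blurs 1-pixel boundaries;
  touching-pair splitting is exercised mainly through the ground-truth
  channel-map path in the geometry tests.
* The federated rule follows the literal presence formulation; the
  frequency-weighted negative-sampling variant of its cited lineage is not
  implemented.
* The Lizard `.mat` annotation format has no reader here; data enter
  through PNG/TIFF/CSV scenes or the generator.
* COCO-JSON is exported (uncompressed RLE) but not imported.
* Whole-slide streaming, test-time augmentation and multi-GPU training are
  out of scope.
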