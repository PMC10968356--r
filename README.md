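# nucleiprompt

Prompt-based nuclei segmentation and classification for H&E histopathology
tiles, built around three ideas:

* **Category descriptors.** For each nuclei category (neutrophil,
  eosinophil, plasma, connective, lymphocyte, epithelial by default) plus a
  background and a boundary channel, a stack of `K` learnable prompt tokens
  is fed to a *frozen* promptable mask decoder. One decoder call per
  channel on a shared image embedding yields per-channel probability maps
  `p_c(x)`; segmentation and classification fall out of combining them.
* **Low-level domain alignment.** `L` inverted-residual layers (MobileNetV2
  style, zero-initialized output projections, hence exactly the identity at
  initialization) sit between the frozen patch embedding and the frozen
  transformer blocks, shifting low-level histopathology features toward the
  distribution the frozen high-level blocks expect. Only the adapter and
  the descriptor bank are ever trained.
* **A federated multi-class hinge objective.** Per-channel binary
  cross-entropy where (a) a nuclei-class channel only receives gradients on
  images containing that class — protecting rare classes from spurious
  negatives — and (b) a pixel contributes only while its probability gap

  `gap_c(x) = p_c(x) - max_{c' != c} p_{c'}(x)` (target channel)

  stays below the margin `gamma = 0.2`; confident pixels are silenced.
  Long-tailed data are additionally rebalanced by repeat factor sampling,
  `r(c) = max(1, sqrt(t / f(c)))` with `t = 0.3`.

Inference runs a 256/128 sliding window, per-pixel argmax over the channel
maps, 8-connected components per class with boundary-channel splitting and
rim reabsorption, and centroid-in-central-region stitching that keeps each
nucleus exactly once. Evaluation implements the object-level detection F1,

    F1 = TP / (TP + (FP + FN) / 2),

with greedy one-to-one IoU matching, and COCO-style mAP
(`mAP = (1/N) * sum_k AP_k`, 101-point interpolation, IoU thresholds
0.50–0.95), plus a one-sided paired Wilcoxon signed-rank test for method
comparisons. Interactive point prompts can refine predictions after
training without any retraining.

Because no tensor runtime is assumed, the package ships a miniature,
fully self-contained **surrogate backend** (patch embedding, frozen
transformer blocks, a two-way-attention mask decoder with a sub-pixel mask
head, all hand-written matrix code with gradient-checked backprop). A real
ViT-B checkpoint satisfies the same backend contract
(`create_backend("vit_b")`) but needs external weights. A synthetic H&E
scene generator with a long-tailed class mixture, touching nuclei and full
ground truth serves as the test substrate; see `vignettes/methods.Rmd` for
what it does and does not emulate.

## Worked example

Train the adapter and descriptors on synthetic scenes and evaluate on
held-out scenes:

```r
library(nucleiprompt)

cats <- category_set()
simc <- sim_config()                          # 128x128 H&E-like scenes
train <- lapply(1:40, function(i) generate_scene(simc, seed = 1000 + i))
heldout <- lapply(1:10, function(i) generate_scene(simc, seed = 9000 + i))

backend <- surrogate_backend(patch_size = 8, embed_dim = 64, n_blocks = 2)
model <- prompt_model(
  backend,
  init_descriptor_bank(cats, K = 32, D = 64, seed = 2),
  alignment_adapter(L = 12, embed_dim = 64, inner_channels = 96, seed = 3),
  cats)

fit <- train_model(train, model,
                   train_config(crop_size = 128, epochs = 20,
                                max_steps = 1000, seed = 1))

preds <- lapply(heldout, function(s)
  predict_scene(s$image, fit$model, window = 128))
eval_report(preds, heldout, cats)
```

```
<eval_report>
  mean object F1: 0.5059
  mAP: 0.2216  mAP50: 0.4501
  per-category F1: neutrophil=0.286 eosinophil=0.222 plasma=0.308
    connective=0.714 lymphocyte=0.735 epithelial=0.77
```

The mean object F1 says that roughly half of the held-out nuclei are
detected at IoU > 0.5 *and* assigned the correct category (other training
seeds land between ~0.4 and ~0.7 on this 10-scene evaluation — the
rare-category scores ride on a handful of instances). Training the same
configuration without the adapter collapses the mean F1 to about 0.07,
mirroring the role of low-level domain alignment. Point-prompt refinement
(`refine_with_points`) then lifts the mean F1 round by round — in the
shipped acceptance run from 0.43 at round 0 to 0.77 after four rounds,
fastest for the rarest categories.

A command-line wrapper for `simulate` / `train` / `infer` / `eval` /
`refine` is installed at `inst/cli/nucleiprompt.R`:

```sh
Rscript inst/cli/nucleiprompt.R simulate --config cfg.yaml --out data/ --seed 4
```

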