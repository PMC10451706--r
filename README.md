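# dduda

Boundary-enhanced dual-discriminator unsupervised domain adaptation
(DD-UDA) for 2D liver segmentation from CT slices, in R.

## The problem

Multi-phase CT images the same anatomy under different contrast
enhancement (non-contrast, arterial, portal venous phases), and different
centers scan with different protocols. A segmentation network trained on
annotated slices from one phase or center degrades on another, and
annotating every phase is prohibitively expensive. This package trains a
liver segmentation network from **annotated source slices plus
unannotated target slices**, aligning the two domains adversarially at two
levels, with an auxiliary boundary decoder that sharpens the liver
boundary in poor-contrast images.

## The model

The generator is a U-Net-style network with one encoder and two decoders:

* decoder-1 produces the per-pixel foreground probability ("heat map")
  `h`;
* decoder-2 is trained to reproduce the Sobel edge map of the ground
  truth: its output's gradient magnitude `b = Sobel(G_dec2(G_enc(u)))` is
  regressed onto the boundary label `z = Sobel(v)`. Decoder-2 is dropped
  at inference, so the deployed model is no bigger than a plain U-Net.

Two fully convolutional discriminators (channels {64, 128, 256, 512, 1},
4×4 stride-2 kernels) score per-location "came from the source domain"
probabilities — `D_e` on the encoder bottleneck `f`, `D_d` on `h`. The
generator minimizes

```
L = L_seg + 0.2 · L_b + 5e-4 · L_adv_e + 3e-3 · L_adv_d
```

(soft dice + boundary MSE + the two adversarial terms with flipped domain
labels, computed on target maps only), while each discriminator minimizes
its own domain-classification cross-entropy. Training alternates five
steps per iteration: segmentation, boundary, adversarial alignment, then
one classification update per discriminator. Evaluation reports dice,
IoU, sensitivity and precision per slice.

Because the clinical datasets such a model targets cannot be shipped, the
package includes a seeded two-domain phantom generator (smooth blob
organs with masks; the target domain applies a contrast-compression /
gamma / noise / blur remapping) so the full pipeline — preprocessing,
five-step adversarial training, inference, metrics — runs end to end
from code. The convolution machinery itself (conv / transpose-conv /
pooling / batchnorm forward and backward, Adam) is implemented in
compiled RcppArmadillo code on the system BLAS.

## Worked example

```r
library(dduda)

# two-domain phantom data: annotated source, unannotated shifted target
ds <- generate_dataset(n_source = 64, n_target = 64, seed = 1)

# dual-discriminator adaptation at desk scale (base width 8, 20 epochs)
cfg <- synthetic_benchmark_config(mode = "dd_uda", seed = 1)
model <- train(cfg, ds$source, ds$target)

# inference uses encoder + decoder-1 only
test_items <- Map(function(i, m) list(image = i, mask = m),
                  ds$target$images, ds$target_eval$masks)
evaluate_dataset(model$gen, test_items)
```

On seed 1 this prints (the same seed reproduces it exactly):

```
metrics over 64 items: DC 0.9742 | IoU 0.9501 | TRP 0.9787 | PPV 0.9710
```

i.e. the adapted model segments the shifted, never-annotated target
domain at ~0.95 IoU. Training the same seed without adaptation
(`mode = "supervised"`) drops the target IoU to 0.89 while scoring 0.97
dice on its own source domain: the phantom task is easy enough that the
supervised baseline transfers fairly well, so adaptation gains sit close
to that ceiling (see the vignette for what the phantoms do and do not
emulate).

A real CT volume enters the same pipeline through
`load_volume()` → `window_and_normalize()` (clamp to [−20, 200] HU,
per-slice min–max) → `make_boundary_label()` on its masks. Thin
command-line wrappers for each stage live in `inst/cli/`
(`synth.R`, `preprocess.R`, `train.R`, `eval.R`).

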