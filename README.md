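# kneecgan

Conditional-GAN and U-Net segmentation of multi-tissue knee MRI slices, as
a tested R library with a command-line interface.

## What problem this solves, and for whom

Research on knee osteoarthritis needs segmentations of many joint tissues —
femur, tibia and patella, their articular cartilages, selected muscles and
the cruciate ligaments — from sagittal MR stacks, and manual segmentation
costs tens of minutes per subject volume. `kneecgan` implements the
image-to-image-translation approach to this problem for people who want to
study its *mechanics* (objectives, architectures, receptive fields,
transfer protocols, evaluation metrics) reproducibly on one CPU: every
component runs end-to-end on built-in synthetic knee phantoms, with no
external data or GPU.

## The model

A generator `G` (a U-Net: `n_down` stride-2 4×4 convolutions down, a
mirror-symmetric stack of transposed convolutions up, skip connections
between layers of equal size) maps a grayscale slice `x` to a colour-coded
label image `G(x)`: bones in the blue channel (femur 50, tibia 100, patella
150), cartilages in green (50/100/150), muscles in red (100/200), ACL/PCL
at 200 in blue/green. Boolean tissue masks are decoded by keeping values
within ±20 colour units of each code.

A conditional patch discriminator `D` (PatchGAN) scores `(x, label)` pairs
patch-wise; its receptive field is computed analytically by the backward
recurrence `r ← r·s + (k − s)` over the layer stack (variants: 1 — PixelGAN
— 34, 70 and 286 px). Training minimises

```
G* = arg min_G max_D  L_cGAN(G, D) + λ · L_pixel(G)
```

with `L_cGAN` the binary-cross-entropy adversarial value function,
`L_pixel ∈ {L1, L2, SmoothL1}` on the `[-1, 1]` label scale and
`λ ∈ {0, 0.01, 1, 100, 10000}`; plain U-Net mode drops the adversarial
term. Adam (lr 0.0002, β₁ 0.5, β₂ 0.999, batch size 1), jitter augmentation
(bicubic upscale + shared random crop; nearest-neighbour for labels), an
optional mid-training pixel-loss switch (e.g. L2→L1 at epoch 50 of 100) and
a 20+80-epoch pretrain/fine-tune transfer protocol complete the training
recipe. Evaluation reports per-tissue DSC, VOE and average surface distance
(exact anisotropic distance transform, voxel-centre surfaces) on 3D volumes
stacked from 2D predictions, aggregated as mean ± (population) SD across
subjects.

## Worked example

```r
library(kneecgan)
print(build_discriminator("patch_70"))
#> PatchGAN discriminator 'patch_70' (conditional, 4 input channels), receptive field 70 px
#>  layer kernel stride in_channels out_channels pad  norm activation
#>      1      4      2           4           64   1 FALSE leaky_relu
#>      2      4      2          64          128   1  TRUE leaky_relu
#>      3      4      2         128          256   1  TRUE leaky_relu
#>      4      4      1         256          512   1  TRUE leaky_relu
#>      5      4      1         512            1   1 FALSE    sigmoid

# ten phantom subjects; train a U-Net on 8, evaluate on the 2 held out
cfg <- phantom_config(n_subjects = 10)
seeds <- subject_seeds(cfg)
pairs <- lapply(1:10, function(i) {
  sl <- generate_subject(cfg, seeds[i], sprintf("subj%02d", i))
  lapply(sl, function(p) c(p, list(subject = sprintf("subj%02d", i))))
})
ck <- train_model(
  do.call(c, pairs[1:8]),
  generator_spec(n_down = 5, min_channels = 16, input_size = 64),
  objective = objective_config("L1", 1, adversarial = FALSE),
  tcfg = train_config(epochs = 10, crop_size = 64, seed = 7, mode = "unet"))
res <- evaluate_model(ck, do.call(c, pairs[9:10]), which = c("dsc", "voe"))
print(res$aggregate, digits = 3)
#>                  tissue dsc_mean  dsc_sd voe_mean voe_sd
#> 1                 femur    0.846 0.00970    0.267 0.0146
#> 2                 tibia    0.889 0.00241    0.201 0.0039
#> 3               patella    0.561 0.04670    0.609 0.0451
#> 4                   acl    0.000 0.00000    1.000 0.0000
#> 5     femoral_cartilage    0.000 0.00000    1.000 0.0000
#> 6      tibial_cartilage    0.000 0.00000    1.000 0.0000
#> 7    patellar_cartilage    0.000 0.00000    1.000 0.0000
#> 8                   pcl    0.000 0.00000    1.000 0.0000
#> 9       vastus_medialis    0.000 0.00000    1.000 0.0000
#> 10 medial_gastrocnemius    0.000 0.00000    1.000 0.0000
```

The run takes under a minute on one CPU. Reading the numbers: after only
ten epochs the large bones are segmented well (DSC 0.85–0.89, i.e. the
predicted and true femur/tibia volumes overlap at ~90%), the small patellar
disc is learned but still soft at the boundary (0.56), and thin structures
(cartilage shells, ligaments, muscles) have not yet emerged from an
L1-trained U-Net at this budget — mirroring the qualitative behaviour of
the full-scale method, where small and rare structures need longer training
or loss switching. `voe_mean` and `dsc_mean` are linked by
`VOE = 1 − DSC/(2 − DSC)`.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/kneecgan.R synth --size 64 --subjects 10 --slices 10 --out phantom
Rscript inst/cli/kneecgan.R train --config run.yaml --data phantom --out ck.rds
Rscript inst/cli/kneecgan.R evaluate --checkpoint ck.rds --data phantom --split test
Rscript inst/cli/kneecgan.R arch --discriminator patch_286
```

where `run.yaml` is a flat `key: value` file selecting the experiment axes
(`mode`, `pixel_loss`, `lambda`, `switch_epoch`, `n_down`, `min_channels`,
`discriminator`, `epochs`, …).

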