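# guvstack

Automated analysis of confocal fluorescence z-stacks of giant unilamellar
vesicles (GUVs) and phase-separated protein droplets, for membrane
biophysicists who need population-scale statistics — how much protein is
bound to the membranes, or what fraction of vesicles shows coexisting
lipid phase domains — without vesicle-by-vesicle manual inspection.

A GUV appears in each optical section as a bright circular rim of radius
`rho(z) = sqrt(R^2 - (z - z0)^2)`. The pipeline:

1. **Segmentation** — triangle-method thresholding of each section into a
   binary mask, then a two-stage circular Hough transform: edge pixels
   vote for centers along their intensity-gradient directions at every
   admissible radius (default 20–120 px), and each candidate's radius is
   read off its radial intensity-profile peak.
2. **Assembly and selection** — circles are linked across sections by
   center proximity into 3-D vesicle entities; circles failing the
   edge/interior contrast test (e.g. multilamellar vesicles), entities
   with fewer than 3 sections, and entities touching the image border are
   rejected.
3. **Quantification** — background-corrected (`I_net = I_raw -
   I_background`) membrane-band intensity in a second channel (binding
   analysis), interior-disc intensity (protein droplets), or the
   phase-state statistic: the rim is split into N angular segments, the
   20%-rank high/low segment intensities define a mid level, and
   discontinuities are counted as hysteresis crossings of the ±p% band
   around it — at least two discontinuities marks a section
   phase-separated, and a vesicle is phase-separated when at least 40% of
   its sections are.
4. **CNN variants** — program 2 replaces the selection filter with a
   4-class convolutional network (valid / multilamellar / overlapping /
   hazy); program 3 also replaces the per-section phase decision with a
   2-class network trained purely on virtually simulated confocal images
   from the built-in ground-truth simulator. Both networks are small
   (3 conv blocks, 2 max-pools, softmax; 50×50 zero-centered inputs)
   and train with SGDM (lr 0.01, ≤4 epochs, validation every 30
   iterations) in seconds to minutes on a CPU.

The simulator renders spherical shells (anti-aliased 1-px rims), phase
domains as spherical caps, Gaussian PSF blur and detector noise, with
full ground-truth annotations — so every stage is testable against known
truth, and the phase-state classifier needs no experimental training
data.

## Worked example

Simulate a four-vesicle stack (two vesicles carry a phase domain), run
the fully computational program 1 in phase mode, and read the per-vesicle
decisions:

```r
library(guvstack)

p <- scene_params(n_vesicles = c(4, 4), radius_um = c(24, 40),
                  domain_prob = 0.5, field_of_view = 420, pixel_size = 1,
                  z_spacing = 4, z_center_um = c(-2, 2))
scene <- sample_scene(p, seed = 42)
sim   <- render_zstack(scene, seed = 43)
rep   <- run_program1(list(A = sim$stack),
                      analysis_config(radius_range_px = c(20, 55)),
                      mode = "phase")
tidy(rep)
#>   vesicle_id n_sections n_separated fraction_separated vesicle_state high  low
#> 1          1         16           0                  0       uniform 3636 3479
#> 2          2         16           0                  0       uniform 1611 1513
#> 3          3          7           7                  1     separated 2715  755
```

Entity 3 sits at the position of a simulated domain-carrying vesicle and
is called `separated` with every section showing ≥2 contour
discontinuities; its `high`/`low` levels (2715 vs 755 counts) are the two
domains' rim intensities, usable downstream for a partition coefficient.
Entities 1–2 are uniform vesicles, correctly called `uniform` with
fraction 0. The fourth simulated vesicle carries a bright interior and is
rejected by the edge-contrast selection filter — the intended behavior
for multilamellar-like objects (`rep$entities` lists every entity with
its status and rejection reason). `sim$annotations` holds the per-section
ground truth for comparison.

Training and applying the CNNs:

```r
tr  <- generate_training_set("state-2class", 1000, seed = 1)
va  <- generate_training_set("state-2class", 200, seed = 2)
fit <- train_cnn(build_cnn("state"), tr, va, train_config(), seed = 3)
glance(fit)        # one-row summary with final validation accuracy
autoplot(fit)      # training curves
```

A thin command-line front end over the same functions is installed at
`inst/cli/guvstack.R` (subcommands `simulate`, `train`, `program1`,
`program2`, `program3`; TIFF in, CSV + PNG overlays + YAML run manifest
out).

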