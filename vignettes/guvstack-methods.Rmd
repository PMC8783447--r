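---
title: "Methods: automated GUV z-stack analysis with guvstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated GUV z-stack analysis with guvstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvstack)
```

## The analysis problem

Giant unilamellar vesicles (GUVs) are micrometer-scale lipid bilayer
spheres. In a confocal z-stack a GUV appears, section by section, as a
bright circular rim whose radius follows the spherical cross-section
`rho(z) = sqrt(R^2 - (z - z0)^2)`. Statistical statements about a vesicle
population — how much of a fluorescent protein is bound to the membranes,
or what fraction of vesicles shows coexisting lipid phase domains —
require identifying many vesicles across whole stacks, rejecting the ones
that cannot be analyzed (multilamellar interiors, touching neighbors,
out-of-focus smears, vesicles cut by the image border), and then
quantifying each survivor consistently. `guvstack` automates that chain
three ways, differing in how much of the decision making is learned:

* **Program 1** is purely computational: triangle-threshold masking,
  circular Hough segmentation, an edge-contrast selection filter, 3-D
  grouping, and either membrane/droplet intensity quantification or a
  contour-discontinuity phase-state statistic.
* **Program 2** replaces the per-circle selection filter with a 4-class
  convolutional network (valid / multilamellar / overlapping / hazy).
* **Program 3** additionally replaces the per-section phase-state decision
  with a 2-class network trained entirely on virtually simulated vesicle
  images.

All pixel coordinates in the package are 0-based with `x` the column, `y`
the row and pixel centers at integer positions; angles run
counterclockwise from the +x axis in the (x, y) frame.

## Segmentation

Each section is first reduced to a binary mask: a triangle-method
threshold on a 256-bin histogram of the (lightly smoothed) image. The
triangle geometry is computed on normalized axes — peak height and
peak-to-tail span both scaled to one — because fluorescence histograms are
dominated by a background spike and the unnormalized construction would
place the threshold immediately next to it. Masking makes the subsequent
segmentation robust at low signal-to-noise ratio; two cleanup steps keep
the mask honest: connected components smaller than `min_component`
(default 50 px) are treated as noise speckle and removed, and background
holes smaller than `min_hole` (default 200 px) are filled, because an
interior hovering at the threshold otherwise leaves a swiss-cheese mask
whose internal edges flood the Hough vote space. Both defaults sit far
below the geometry of a real vesicle at the supported radii (a 20 px rim
band holds >250 px; a 20 px lumen holds >800 px).

Circles are then detected with a two-stage circular Hough transform
(CHT). Edge pixels are the strong intensity-gradient pixels inside the
(dilated) mask; each votes along both directions of its local intensity
gradient at every radius in the configured range (default 20–120 px, the
radius band that covers typical GUV sizes at 100x confocal
magnification). The gradient of the *intensity* image supplies the vote
direction — the gradient of the binary mask is quantized to a handful of
angles and would smear votes by several pixels at large radii — and the
vote weight is the gradient magnitude, so pixels on the steep rim slopes
dominate while pixels whose local gradient is noise contribute little.
Candidate centers are peaks of the smoothed accumulator; for each
candidate the radius is read off the peak of the radial mean-intensity
profile (the unbiased rim estimate for a fluorescent shell — the edge map
of a thresholded band carries the band's two borders, not its crest), and
the circle is scored by angular coverage: the fraction of 48 sectors
containing an edge pixel within 2.5 px of a mode of the radial
edge-distance histogram. A circle is kept when its score reaches
`1 - sensitivity` (default sensitivity 0.5: half the circumference must
be edge-supported), so raising the sensitivity only admits more circles.
Overlapping candidates are resolved by non-maximum suppression on center
distance.

## Vesicle assembly and selection

Sections are linked into 3-D vesicle entities by center proximity:
walking up the stack, a circle joins the entity whose most recent center
is nearest and within `center_tolerance_px` (default 10 px — well below
the minimum radius, so neighboring vesicles cannot merge); otherwise it
seeds a new entity. Matching against the most recent rather than the
first section lets the grouping track small drifts. Within one section
assignments are made greedily by distance, which makes the result
independent of detection order.

Two selection stages mirror the two failure classes. Per circle, the
edge-contrast filter compares the mean intensity in the rim band (annulus
`r - band_px < d <= r`) with the interior disc and rejects circles whose
ratio falls below `min_edge_ratio` (default 1.5) — too little rim signal,
or too much interior fluorescence, as in multilamellar vesicles. Per
entity, reconstructions with fewer than `min_sections` sections (default
3: one- and two-section groups) are rejected as not enough information
for an intact 3-D vesicle, and entities whose bounding square exits the
image at any section are rejected as edge-touching.

## Intensity quantification

All intensities are background-corrected: `I_net = I_raw -
I_background`, with the per-pixel background estimated per section as the
mean of the pixels at or below the triangle threshold (the "dark part" of
the image). Negative nets are reported as-is; clipping would bias
condition means. For membrane binding, geometry detected in channel A
(the lipid reporter) is applied to channel B (the binding species): the
band of pixels `inward_px` inward from the rim is summed, and the
per-vesicle mean per pixel weights sections by their pixel counts so the
value represents the whole spherical shell rather than an average of
per-section averages. For globular protein droplets the entire interior
disc is averaged instead. Conditions are summarized as the mean of
per-stack means with the standard deviation *between stacks* (n − 1) as
the error estimate — stacks, not vesicles, are the independent unit.

## Contour phase-state statistic

The rim of each accepted section circle is divided into `N` angular
segments (default 36) sampled over the annulus `r - delta_r < d <= r`
(default 3 px), giving net mean intensities per segment. Sorting them
descending, the value at rank `ceiling(percentile/100 * N)` from the top
is the high level, the same rank from the bottom the low level (default
percentile 20 — small enough to resist single-segment outliers, large
enough to find the minority domain), and their average is the
mid-intensity. Discontinuities are counted by a cyclic two-state
hysteresis traversal: the state flips only when the trace crosses the
full `±p%` band around the mid-intensity (default p = 20; match it to the
reporter's partition coefficient). Hysteresis operationalizes a swing
"spanning" the band: single-threshold crossing counting would
double-count noise wiggles, and a profile that never leaves the dead band
has zero discontinuities. A section with at least two discontinuities
(one domain has two boundaries) is phase-separated; for profiles with 2k
alternating arcs the count is 2k, so the number of domains can be read
off. A vesicle is phase-separated when at least `decision_fraction` of
its sections are (default 0.40, boundary inclusive).

## The virtual confocal simulator

The simulator is the package's ground-truth engine: scenes are sampled
from declared parameter ranges, labels derive from the scene alone, and
rendering is a separate, deterministic step (same seed, same scene).

A scene holds spherical vesicles (center, radius, membrane level,
interior level) and optional phase domains. Domains are parameterized as
spherical caps — a direction on the vesicle plus a half-angle `alpha` —
stored as the equivalent intersecting sphere centered on the shell with
radius `2 R sin(alpha/2)`; a cap of half-angle `alpha` subtends an arc of
`2 alpha` on an equatorial section, which makes rendered arc lengths easy
to control. Rendering a section draws the 1-px spherical-shell
cross-section ring at the membrane level (domain-crossing arc pixels at
the domain level, default 25% of the membrane level — a dim domain, as
for a reporter partitioning away from it), the interior disc at the
interior level, convolves with an in-plane Gaussian PSF (default sigma
2 px) and adds Gaussian noise. Three numerical choices in that chain
matter and were each adopted for a measurable fidelity reason:

* **Anti-aliased rim deposition.** The ring is deposited with a tent
  weight `1 - |d - rho|` (unit integral across the rim) rather than a
  binary `|d - rho| <= 0.5` mask. A binary ring aliases with 90-degree
  periodicity — diagonal arcs collect ~40% more pixels per arc length —
  which after blur appears as a spurious, noiseless ±30% contour
  modulation indistinguishable from phase domains.
* **Noise scaled to observed brightness.** The noise sigma is declared
  as a fraction of the membrane level (default 5%) and interpreted
  against the membrane's *observed* brightness: blurring the 1-px shell
  attenuates its peak by about `1/(sqrt(2*pi)*sigma_psf)`, and the
  rendered noise is scaled by the same factor, so the rim
  signal-to-noise ratio is the declared one (20 at the default)
  regardless of PSF width.
* **Detector offset above the noise floor.** The background level is
  floored at 2.5x the rendered noise sigma, as an operator configures
  the offset: a zero-clipped noise floor puts a delta spike into the
  intensity histogram that defeats histogram-based thresholding — for
  virtual and real images alike.

Geometric defaults copy the target acquisition: 1,024 px spanning
127.3 um and 1 um z-spacing.

The simulator emulates: spherical geometry and its z-dependence, rim
brightness variation, dim phase-domain arcs with geometrically correct
section crossings, multilamellar-style interiors, overlapping neighbors,
out-of-focus pole sections, background offset, PSF blur, and
detector-style Gaussian (optionally Poisson) noise. It deliberately does
not model: 3-D (axial) PSF blur, polarization-dependent excitation around
the shell, photobleaching, membrane deformation away from sphericity, or
tubular protrusions. Tests passing on simulated data therefore validate
the decision logic and the geometry handling, not robustness to deformed
or photophysically complex real samples.

## Training data and the two networks

Both classifiers consume 50x50 single-channel patches cropped at
`2 * margin * r` around a detection (margin default 1.2) and resampled
bilinearly. The 4-class selection set renders typical unilamellar
vesicles (C1), vesicles with internal membrane structure (C2),
overlapping pairs (C3), and hazy near-pole, strongly defocused, low-SNR
sections (C4). The 2-class phase-state set renders homogeneous versus
domain-crossing sections; these patches are background-thresholded with
sub-threshold pixels set to zero (not binarized), which removes the
irrelevant background variation and markedly improves the state
classifier, and the same preprocessing is applied at inference. Two
generator details matter for label quality: patches are rendered into a
120-px field, thresholded there and then cropped — the pipeline
thresholds whole, background-dominated sections, and thresholding a bare
50x50 crop would cut into the rim signal itself — and domain caps are
aimed so the cap boundary crosses the rendered ring, because a section
lying entirely inside a domain is visually identical to a uniform one and
would carry an uninformative label.

The two architectures share one topology: three 3x3 'same' convolutions
(16/32/64 filters for selection, 8/16/32 for state), each followed by
batch normalization and ReLU, 2x2 stride-2 max pooling after the first
and second blocks (spatial path 50 → 25 → 12), a fully connected layer of
size 4 or 2, and softmax. Inputs are zero-centered by subtracting the
training-set mean image; the same mean is stored with the classifier and
applied at inference. Training is SGDM with initial learning rate 0.01,
at most 4 epochs, and validation every 30 iterations plus a final
evaluation. After the SGD loop the batch-norm statistics are finalized
by one pass over the training set with the trained weights (mean of
per-chunk means and variances); the running statistics accumulated
during SGD lag the late-training weights, which otherwise makes held-out
accuracy oscillate by more than a percentage point between checkpoints.
Where the recipe leaves choices open we use momentum 0.9,
batch size 128, L2 decay 1e-4, Glorot-uniform initialization, and pool
placement after blocks 1 and 2 (the arrangement that reduces 50x50 to the
12x12 grid the FC layer consumes); cross-entropy on the softmax outputs
is the default loss, with an MSE-on-softmax option. The engine is
implemented in RcppArmadillo, runs single-threaded, and is bit-for-bit
reproducible for a fixed seed (initialization and epoch shuffling draw
from R's RNG). Training-set augmentation by image scaling and position
shifting is available (`augment()`); both ranges must contain the
identity.

## Sub-pixel geometry and the contour statistic

The contour statistic samples a 3-px annulus on a rim whose blurred
radial profile is steep; a sub-pixel center or radius error therefore
converts that profile into a smooth spurious modulation along the
contour (a ~1 px center error produces a ~25% swing — larger than the
discontinuity band). Before contour sampling, `phase_analysis()`
therefore refines each detected circle against the rim ridge: the
radial intensity peak is located along 72 rays and a least-squares
circle is fitted to the peak positions (dropping the worst 20% of
residuals once). Only peak *positions* enter the fit, so a dim phase
domain pulls neither the center nor the radius.

## Numerical choices and degenerate inputs

* Constant images have no definable threshold (error); background
  estimation on a constant image returns the constant.
* Empty contour wedges raise an error advising smaller `N` or larger
  `delta_r`; a mid-intensity of zero (no dynamic range) is an error for
  discontinuity counting and is treated as "uniform" at the
  section-state level.
* An interior mean of exactly zero with positive rim signal passes the
  edge-contrast filter (infinite contrast).
* Duplicate detections (center < 2 px and radius < 2 px apart) are
  suppressed, keeping the higher score; candidate ties in the accumulator
  break lexicographically, so results are deterministic.
* The minimum-section boundary and the 40% fraction rule are inclusive.
* 16-bit TIFF I/O clips to [0, 65535]; intensities are otherwise carried
  as doubles throughout.

## Problem sizes used by the test-suite and acceptance runs

The shipped tests run the full chain at reduced, fixed-seed scales chosen
to exercise every decision path: single sections up to ~400 px across,
stacks of 3–8 vesicles, 200 simulated vesicles for the phase-state
accuracy checks, and the 2-class network trained on 5,000 generated
patches per class (the reference experiment used ~47k/34k). At that
reduced scale the held-out accuracy of the virtually trained phase-state
network is the package's headline reproduction target; the acceptance
script (`scripts/acceptance.R`) regenerates the patches, retrains the
network with the stated recipe, and reports the measured accuracy.

## Known limitations

Elliptical or strongly deformed vesicles are not fitted (circles only);
tubular protrusions are ignored by the circular geometry; merged entities
from touching vesicles are rejected rather than split; no bleed-through
or crosstalk correction between channels; no absolute calibration to
fluorophore numbers; and the partition coefficient is not computed — the
high/low domain levels are exported so users can form it themselves. A
classifier trained on one optical configuration should be retrained for
data acquired under a different one; the simulator's parameter ranges are
the handle for that.
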