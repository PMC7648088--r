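---
title: "Quantifying collective fibroblast migration: models, parameters and design choices"
author: "fibroswarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective fibroblast migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroswarm)
```

Scar-forming fascia fibroblasts heal skin wounds by swarming: they adhere to
one another, align their movement and migrate collectively towards the wound
centre.  Fibroblasts of non-scarring tissues migrate stochastically and more
slowly.  This vignette explains the statistics the package computes to
separate those regimes, the agent-based generator used to validate them, and
the design decisions taken where the underlying procedures are
underspecified.

## The movement-similarity score

For each pair of consecutive time points, every cell has a 3D movement
vector $v_i = p_i(t+1) - p_i(t)$.  Cells are neighbours when they share an
edge of the Delaunay triangulation of the positions at the interval's
*start* frame; the triangulation is recomputed at every frame because the
point cloud deforms.  The score of cell $i$ is the mean angle (degrees)
between $v_i$ and each neighbour's vector, and the global score is the
unweighted mean over all (cell, frame) scores — the simplest reading of
"average all angles"; pooling raw angles instead of per-cell means changes
the result only through weighting and is not exposed.

Two exact anchors calibrate the scale:

* **Uniform migration** — identical vectors give angle 0 for every pair, so
  the global score is exactly 0.  Angles are computed as
  $\mathrm{atan2}(\lVert v_i \times v_j\rVert,\ v_i \cdot v_j)$, which is
  exact at 0 and 180 degrees and well-conditioned near them (the arccosine
  form is not).
* **Isotropic random migration** — for independent isotropic 3D directions
  $\cos\theta \sim \mathrm{Uniform}(-1, 1)$, so $E[\theta] = 90^\circ$.
  With 500 cells over 10 frames the Monte-Carlo error of the global score is
  well under one degree.

Angles are kept on $[0, 180]$; the 0–90 range used in display colour maps is
a clamp for visualisation, not a property of the statistic (a mean of 90 for
random motion requires unfolded angles).  Zero-length movement vectors
cannot define an angle, so such pairs are skipped, and a cell with no usable
pair contributes no score that frame.  Degenerate 3D clouds (coplanar point
sets, fewer than 5 cells) fall back to a 2D triangulation on the two
highest-variance axes with a logged notice; fewer than 5 co-occurring cells
skips the frame.

The triangulation itself is an incremental Bowyer–Watson construction (2D
and 3D) in compiled code, with circumcentres solved in extended precision
and a far super-simplex so that hull edges are recovered; the test suite
checks it edge-for-edge against an independent computational-geometry
reference on random, clustered and degenerate clouds.

## The migration simulator

The generator is a minimal Vicsek-type model with centripetal attraction.
Cell $i$ carries a unit heading $h_i$; at each step

$$h_i' \propto a\,\hat u_{\text{centre}} + b\,\langle h_j\rangle_{\lVert p_j - p_i\rVert < r} + c\,\eta,$$

with $\eta$ an isotropic unit vector, and the position advances by exactly
`speed` pixels along $\hat h_i'$.  The neighbour average includes the cell
itself, as in the classic alignment models.  Cells reflect at the arena
boundary, so no cell is lost (losses would bias the similarity statistic).

Defaults encode the experimental contrast rather than a biological
calibration, because no step-length or density measurements are published
for these cells: 200 cells in a 150 px arena, 97 frames at `dt` = 15 min (a
24-h recording at the acquisition interval), speed 2 px/frame, attraction
and alignment weights 1, noise weight 0.5, interaction radius 30 px.
`mode = "random"` forces attraction and alignment to zero, giving a pure
isotropic random walk whose step length is `speed` *by construction* —
hence mean-velocity ratios between speeds are exact, and the mean squared
displacement grows as $\mathrm{MSD}(L) = L\,s^2$ while reflections are
negligible (the diffusive checks therefore use a large arena so the path
stays far from the boundary).  `mode = "chimera"` seeds one lineage in an
outer annulus and the other in an inner disc of half the radius, mirroring
the two-tissue explant-chimera geometry, and carries the lineage label into
the track table.

What the generator deliberately does not emulate: proliferation and death
(dispensable for early swarming), mechanical deformation of the underlying
tissue, cell shape, and any molecular detail of adhesion — the
attraction/alignment coupling is an abstraction of adhesion-dependent
collectivity.  Passing tests on these tracks therefore validate the
*statistics*, not any biological model of real fibroblasts.

The renderer draws each cell as an isotropic Gaussian spot (default
$\sigma$ = 2 px) in its lineage's channel, then applies the standard
fluorescence noise model: Poisson shot noise on `signal * photon_scale`
followed by Gaussian read noise; both default to off so that geometric tests
are exact.

## Particle image velocimetry

`run_piv()` implements the iterative cross-correlation scheme used for
collective cell migration: interrogation windows of 64, 32 and 16 px, each
pass correlating zero-mean windows by FFT (zero-padded, so linear rather
than circular correlation), peak refinement by a 3-point Gaussian fit per
axis (parabolic fallback when a neighbour is non-positive), and window
offsetting by the rounded, bilinearly interpolated previous field.  After
every pass the normalized median test (noise 0.2, threshold 5) flags
vectors whose residual against the component-wise median of their eight
neighbours, normalised by the median neighbour residual plus the noise
floor, exceeds the threshold.

Choices the published scheme leaves open, all exposed in `piv_config()`:

* **Overlap** — 50 % per pass, the common default for this plugin lineage.
* **Flagged vectors** — replaced by the neighbourhood median during
  intermediate passes (the predictor must stay smooth); on the final pass
  replacement is optional (`replace_invalid`, default on) and the `valid`
  flags are preserved either way.
* **Border windows** — windows lie fully inside the frame, and when the
  offset predictor would push a window across the border it is clamped and
  the vector flagged invalid: matched texture has left the frame, so the
  measurement there is biased (loss of pairs).  On a 512² pure-translation
  pair all remaining valid vectors are exact to machine precision.
* **Peak quality** — the first-to-second peak ratio is reported as a
  diagnostic only; the median test is the validation filter.

## Fractal dimension and lacunarity

Collagen architecture is summarised by box counting on the binarised image
(threshold 0.40 of the channel maximum, a fractional cut so the value is
bit-depth independent).  For box sizes $\varepsilon$ (powers of 2) and
`n_grids = 4` offset grid origins, $N(\varepsilon)$ is the number of
occupied boxes *minimised over the offsets* — the most-efficient-cover
reading of the box-counting definition.  The minimum matters: counting with
a single anchored grid systematically inflates $N$ at coarse scales
(partial-box ceiling effects) and biases the fitted dimension low by
~0.05 on reference sets; with the minimum cover and scales capped at a
sixteenth of the image side the filled square, the line and the depth-5
Sierpinski carpet are recovered within 0.03 of their analytic dimensions
(2, 1 and $\log 8/\log 3 \approx 1.8928$).  The scale cap relaxes towards a
quarter of the side only when needed to reach the minimum of four scales.

Lacunarity is the mean over scales and grids of $(\sigma/\mu)^2$ of the
per-box foreground mass, the standard porosity reading.  Only boxes lying
fully inside the foreground bounding box enter the mass statistics, which
keeps the all-ones image at exactly zero lacunarity for every dividing
scale; box *counts* still include partial boxes so the dimension estimate
is not truncated.  On constructed fixtures the dense pattern scores a
higher dimension and lower lacunarity than the porous one — the direction
expected between scar and intact tissue.

## Trichrome quantification

Nuclei counting follows the classical ImageJ chain on the CMYK black
channel, in order: rolling-ball background subtraction (radius 50 px,
implemented as grey-scale opening with a non-flat ball element on a
shrunken copy, the classic algorithm), contrast stretching with 0.1 %
saturated pixels, unsharp masking ($r$ = 2, weight 0.6), median filtering
(radius 1), Minimum auto-thresholding, distance-transform watershed
splitting, and a 30–200 px² particle gate.  The Minimum method smooths the
256-bin histogram with a 3-bin mean until exactly two local maxima remain
and thresholds at the valley; a histogram that never becomes bimodal falls
back to Otsu with a logged notice, and a single-level histogram yields an
empty foreground.  The chain presumes stained tissue: on a featureless
noise field the auto-threshold is undefined and counts are meaningless —
a limitation, not a failure mode the gate is tuned to hide.  Collagen
(scar) area applies the same thresholding family to the cyan channel.
`rgb_to_cmyk()` is the naive device-independent conversion
($K = 1 - \max(R,G,B)$, $C = (1-R-K)/(1-K)$, …), which is what the original
toolchain uses.

The enrichment index is $\mathrm{MFI}_G / (\mathrm{MFI}_G +
\mathrm{MFI}_R)$ over a region of interest.  It is invariant to a gain
applied to both channels but *not* to per-channel gain — acquisition
settings must be constant across the channels being compared.

## Orientation fields and front trajectories

Local tissue orientation comes from the smoothed structure tensor
(Gaussian-derivative gradients at $\sigma$ = 1 px, tensor smoothing at
4 px): the dominant orientation is
$\tfrac12\,\mathrm{atan2}(2J_{xy},\,J_{xx}-J_{yy}) + 90^\circ$ on
$[0,180)$, and coherence $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
flags unreliable (flat or isotropic) regions.  Vectors are sampled on a
grid (default pitch 150 px) with unit-length display scaling.

Front trajectories formalise "gradient lines perpendicular to the contour
lines": each frame is smoothed and the leading front extracted as an
iso-intensity contour (level 0.5 of the global smoothed maximum); a
front-passage surface assigns every pixel the time the front crosses it
(first coverage for an advancing front, last coverage for a receding one,
with never/always-covered pixels clamped to the ends); trajectories are
integral curves of its smoothed gradient seeded on the earliest front.
Because iso-lines of the passage surface are the fronts themselves, the
curves are orthogonal to every contour by construction; on a planar
advancing-front fixture they are straight within 3 degrees, and a static
front yields zero-length trajectories because the gradient vanishes.  The
original plugin's "smoothing 130" has no public definition, so the
smoothing scale is an explicit parameter (default 8 px) calibrated on the
planar-front fixture.

## Input/output and reproducibility

Tracks interchange as plain CSV (`track_id,frame,t_min,x,y,z[,lineage]`),
with invariants enforced on read and 6-significant-digit output, so a
second write–read round trip is the identity.  Movies are multi-page TIFF
(T-major, then channel, then z) with a JSON sidecar carrying axis sizes,
frame interval, pixel size and the power-of-two intensity scale; the
32-bit quantisation is aligned with the reader's grid so a second round
trip is bit-exact.  `run_pipeline()` checks stage dependencies before
computing anything, seeds every stage from one seed, writes a provenance
sidecar (tool version, canonical config hash stable under key reordering,
input hashes, seed, timestamp) next to every artefact, and produces
byte-identical CSVs when re-run with the same configuration.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to keep Monte-Carlo error
comfortably inside the stated tolerances: similarity endpoints on 50
uniform-motion cells and 500 random-motion cells over 10 frames (3 seeds);
PIV on 512² speckle pairs (translation) and 256² (rotation, where the 2°
rigid rotation stays below half the smallest window across the frame);
fractal oracles at 729² (and 243² for invariance checks); histology
fixtures at 512² with 12 planted nuclei of 80 px² and a 10,000 px² collagen
region.  The swarm-versus-random behavioural contrast uses 150–200 cells
over 8–49 frames and five seeds for ordering checks.

## Known limitations

* The simulator's parameters are set for statistical contrast, not fitted
  to measured fibroblast kinematics; absolute speeds and densities are
  arbitrary.
* PIV uses window offsetting only (no window deformation), so strong
  rotation or shear within a single window degrades accuracy; ensemble and
  volumetric (3D) PIV are out of scope.
* The tracker is a greedy mutual-nearest-neighbour linker without gap
  closing or merge/split handling; it is meant for validating kinematics on
  well-separated nuclei, not for dense tissue tracking.
* Whether the published similarity score averaged per cell before pooling,
  and whether neighbour distance was capped in addition to Delaunay
  adjacency, is not documented; the package uses the unweighted per-cell
  mean and pure adjacency.
* CMYK conversion is a colour-space transform, not stain unmixing; strongly
  overlapping stains would need true colour deconvolution.
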