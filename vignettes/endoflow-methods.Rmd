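---
title: "Models and measurement choices in endoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement choices in endoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoflow)
```

endoflow couples two things that belong together in an endothelium-on-chip
experiment: the physics that sets the mechanical stimulus on the monolayer
(wall shear stress and hydrostatic pressure in a rectangular microchannel),
and the image analysis that reads out the monolayer's response (VE-cadherin
junction morphometry). This vignette explains the models, the tunable
parameters, and the design decisions that were genuinely open.

## The channel flow model

The channel is a rectangular duct of width $2W$, height $2H$ and length $L$,
with coordinates centred on the cross-section ($x \in [-W, W]$,
$y \in [-H, H]$; the cell-covered bottom wall is $y = -H$). For fully
developed laminar flow the axial velocity is the classical separable series

$$u(x,y) = \frac{-16 c_1 W^2}{\pi^3} \sum_{n=0}^{\infty}
  \frac{(-1)^n}{(2n+1)^3}
  \left[1 - \frac{\cosh\!\big(\tfrac{(2n+1)\pi y}{2W}\big)}
                 {\cosh\!\big(\tfrac{(2n+1)\pi H}{2W}\big)}\right]
  \cos\!\Big(\frac{(2n+1)\pi x}{2W}\Big),$$

with $c_1$ fixed by the mean velocity $u_m = Q/(4WH)$:

$$c_1 = \frac{-3 u_m / W^2}
  {1 - \frac{192}{\pi^5}\frac{W}{H}\sum_{n}
   \frac{\tanh((2n+1)\pi H / 2W)}{(2n+1)^5}}.$$

The bottom-wall shear stress is the termwise $y$-derivative at $y=-H$,
$\tau(x) = \mu\,\partial u/\partial y|_{y=-H}$, reported as a magnitude; it
peaks at the centreline and vanishes at the side-wall corners. The axial
pressure gradient uses the hydraulic-diameter friction-factor correlation
$dp/dz = \lambda \rho u_m^2 / (2 D_h)$ with
$\lambda = \tfrac{96}{Re}(1 - 1.3553\alpha^{-1} + \dots - 0.2537\alpha^{-5})$,
$\alpha = W/H \ge 1$, $Re = \rho u_m D_h/\mu$ and $D_h = 4A/P$. Raising the
outlet tube by $h$ adds a hydrostatic gauge pressure $\rho g h$ at the exit;
the outlet-tubing friction term $\mu Q L_t\,32/(\pi D^4)$ is computed and
reported separately because it is sub-pascal at these flow rates. The axial
gauge-pressure profile is affine: $p(z) = P_{out} + (L-z)\,dp/dz$.

Numerical choices: series terms are accumulated up to `n_terms` (default
500) or until the last term contributes less than `convergence_tol`
(default $10^{-12}$) in relative magnitude; $\cosh$ ratios switch to an
exponential-difference form beyond argument 30 to avoid overflow. $Q = 0$
short-circuits every flow quantity to zero rather than evaluating the
$1/Re$ path. The $c_1$ bracket tends to zero for channels that are very wide
relative to their height in the series orientation; the constructor raises
an ill-conditioned-geometry error below a $10^{-6}$ floor rather than
returning a huge, meaningless $c_1$.

### The viscosity discrepancy

For the default chip (1 mm x 100 um x 17 mm; 1.3 and 13 uL/min; 40 cm head)
the widely quoted condition table — peak WSS 0.014/0.14 Pa, channel
$\Delta P$ 4.71/47.1 Pa, inlet gauge pressures 3928.7/3971.1 Pa — is
internally consistent only at $\mu = 1.0\times10^{-3}$ Pa s. Culture medium
at 37 C is usually quoted as $\mu = 7.2\times10^{-4}$ Pa s, which (both WSS
and $\Delta P$ being linear in $\mu$) yields values about 28% lower. The
package default is the physically stated $7.2\times10^{-4}$; the shipped
condition fixture (`inst/extdata/table1_conditions.yaml`) and the acceptance
script pin $1.0\times10^{-3}$ to reproduce the table, and say so in a
comment. Both paths are computed by the same code; nothing else depends on
the choice.

### Validation

The series solution is checked three ways in the test suite: a
finite-difference solution of the duct Poisson problem on a 401 x 41 grid
(velocity agreement < 1%, centreline wall shear < 2%), a 200 x 200 midpoint
quadrature of the velocity field that must return the imposed flow rate to
0.5%, and a force balance ($\Delta P \cdot 4WH$ against the integrated wall
drag times $L$, to 5% — loose because the friction-factor correlation is
itself approximate). The FD solver lives with the tests, not in the package
API: it is an oracle, not a second solver.

## The morphometry pipeline

The measurement chain mirrors standard CellProfiler practice on
DAPI/phalloidin/VE-cadherin stacks:

1. **Primary objects (nuclei):** minimum cross-entropy (Li) threshold,
   hole filling, 8-connected labelling, minimum-area filter (default 50 px).
   An optional distance-transform watershed declump exists but is off by
   default — confluent monolayer nuclei rarely touch, and the option changes
   object counts in ways a default should not.
2. **Secondary objects (cells):** the actin foreground (Li threshold, holes
   filled) is partitioned among nuclei by regularised seeded propagation.
   The landscape is the actin image smoothed with a 1-px Gaussian;
   `lambda = 1e-3` balances image-guided and spatial growth. With this
   landscape the inter-cell split settles on the cortical-actin crest
   between cells. A pure distance-to-seed watershed (`lambda` large) was
   considered and rejected: nuclei sit at cell centroids, not at junction
   bisectors, and the distance split lands several pixels off the true
   junction, which a 3-px membrane ring amplifies into junctional-ratio
   errors of 10-20%. The smoothing sigma matters because thin stress fibres
   otherwise deflect the split; 1 px damps a 2-3 px fibre without moving a
   3 px cortical rim. Hole filling treats the field edge as closed
   (`fill_border_holes = TRUE`), so cells cut by the border keep their
   interiors; this assumes a confluent monolayer, which is the package's
   stated scope, and border-touching cells are excluded from records
   regardless.
3. **Tertiary objects and membrane ring:** cytoplasm is cell minus nucleus;
   the membrane is the cell minus its copy shrunk by 3 iterations of
   per-object 3 x 3 erosion (a 9 x 9 square leaves the exact 72-px ring).
   Cells eroded to extinction keep their whole footprint as the ring and are
   flagged.
4. **Measures:** area (pixel and physical), eccentricity from second
   central moments (with the 1/12 pixel-variance term so a 1-px line stays
   strictly below 1), perimeter as the outer-contour chain length,
   circularity $4\pi A/P^2$, and mean/integrated intensity of every channel
   over every compartment. The junctional ratio is membrane mean over
   whole-cell mean on the VE-cadherin channel — mean-based, so it is
   invariant to cell size and to global intensity scaling; the
   integrated-intensity variant is also emitted for comparison.

Junction-level metrics work on the label interfaces: the VE-cadherin band is
the thresholded foreground within a Chebyshev distance (default 5 px) of any
boundary pixel, assigned per edge; stain width is twice the
distance-transform value along the band's medial axis minus one (a band
drawn $w$ px wide measures $w$); fingers and filopodial protrusions are
skeleton branches extending beyond half a baseline width from the boundary,
with length measured as geodesic arc from base to tip plus the base's
boundary distance and the tip's inscribed radius. The quantities the
original assay measured by hand (finger length, stain width) have no
published algorithm; these are reproducible algorithmic surrogates,
validated only against the synthetic generator's ground truth and never
against published figure values. Line profiles across junctions use
bilinear interpolation at unit spacing with perpendicular averaging, and
colocalization along a profile is summarised as Pearson's r (the original
assay overlays the curves without quantifying them; r is the obvious
scalar).

## The synthetic monolayer generator

Everything above is testable without microscope data because the generator
draws a confluent monolayer with known truth: seed points by
minimum-distance rejection sampling, one Lloyd relaxation step, and a
pixel-grid Voronoi tessellation (anisotropically scaled by `aspect` to
emulate flow-aligned elongation); elliptical nuclei (~15% of cell area);
actin as a 3-px cortical rim plus 3-8 stress-fibre chords per cell over a
dim cytoplasmic level; and VE-cadherin as a band along every shared edge,
with three phenotypes — continuous, fingers (perpendicular spikes, Poisson
positions, truncated-normal lengths, drawn in both VE-cadherin and actin),
and disrupted (band attenuated by $\delta$, plus cytoplasmic puncta). Noise
is Poisson photon resampling followed by additive Gaussian, clipped at
zero; all randomness flows from one seed and the caller's RNG state is
restored.

Two rendering choices matter for validation. First, bands and rims are
drawn symmetric about the *true* inter-cell bisector using the sub-pixel
distance $(d_2 - d_1)/2$ to the two nearest seeds, so the drawn geometry
and the ground-truth label map agree at the half-pixel level; centring the
band on a one-sided pixel centreline instead biases every ring measurement
by half a pixel, which is fatal to a 5% recovery target. Second, stress
fibres default to intensity 0.4 against a cortical rim of 0.5 — in
quiescent confluent endothelium the junctional cortical bundle is the
brightest actin structure — which keeps the rim the dominant barrier for
the propagation split.

Default render: 1024 x 1024 px at 0.16 um/px with ~90 cells, matching a
40-63x confocal field; the band default of 5 px (0.8 um) sits in the
typical 0.5-2 um range of junctional VE-cadherin stains. The test and
acceptance suites render smaller fields (192-384 px, 10-40 cells, seeds
fixed in the test code) so the full suite stays desk-scale; the properties
checked are size-invariant.

What the generator does not emulate — optics (no PSF), 3-D structure,
z-stacks, cell motility, staining heterogeneity within a compartment —
bounds what passing tests mean: they show the pipeline recovers known
geometry and intensity structure from images with realistic layout and
noise, not that it matches manual measurements on real confocal data.

## Orchestration

`run_pipeline()` chains simulate, measure and junction stages (or runs the
hemodynamics summary) from a YAML config with a rejected-unknown-keys
schema; every output directory gets a provenance sidecar (config, config
hash, seed, package version, no timestamps) so identical config + seed
reproduces byte-identical artifacts. Group summaries flag conditions with
fewer than 50 cells, the conventional minimum per repeat in this assay.
Statistical comparison between conditions (ANOVA, post-hoc tests) is out of
scope; standard R routines do that directly on the per-cell CSV.

## Known limitations

- The secondary-object split assumes a visible cortical actin rim; on
  images where junctions are actin-dark the propagation falls back to
  near-distance behaviour and ring-sensitive measures lose accuracy.
- Stain width is biased low by ~0.2 px for even drawn widths (the medial
  axis falls between pixels); odd widths rasterize exactly.
- Protrusion detection reports skeleton branches; two fingers closer than
  the skeleton connectivity scale merge into one record.
- The hemodynamic model is steady, rigid-walled and Newtonian; pulsatile
  flow, compliance and non-Newtonian rheology are out of scope.
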