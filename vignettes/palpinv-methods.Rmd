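---
title: "Estimating tissue-inclusion parameters from tactile data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tissue-inclusion parameters from tactile data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`palpinv` implements a full artificial-palpation estimation pipeline: a
finite-element forward model that maps the parameters of a stiff spherical
inclusion buried in soft tissue to the deformation a square elastic sensing
probe experiences when pressed onto the tissue surface; a synthetic
tactile-camera model producing the corresponding 8-bit image; a linear
calibration tying image features to simulation features; and a small neural
network, trained by Levenberg-Marquardt (LMA) or scaled conjugate gradient
(SCGA), that inverts the three tactile features back to inclusion size,
depth, and Young's modulus.  This vignette records the model, the numerical
choices, and the reasoning behind every default, in the order the pipeline
runs.

## The idealized mechanical model

Breast tissue in the region probed is approximated as a flat, laterally
extended slab of linear isotropic elastic material resting on a rigid base
(the chest wall): a 120 mm x 120 mm cross-section, 20 mm thick, Young's
modulus 5 kPa, Poisson ratio 0.49 (nearly incompressible).  The tumor
surrogate is a sphere of diameter $d$ (mm) and Young's modulus $E$ (kPa),
stiffer than the background, centered on the probe axis with its **top**
a depth $h$ (mm) below the tissue surface.  The depth convention matters:
$h$ is surface-to-top, so the sphere center sits at $h + d/2$ and the
feasibility constraint is $h + d \le 20$ mm.  The sensing probe is a
25 mm x 25 mm block, modeled as a single homogeneous elastic layer
(default 10 mm tall, 100 kPa) standing in for the layered silicone
waveguide of the physical instrument, whose layer modulit are not needed
once only the probe-bottom displacement field is observed.

Three unknowns $(d, h, E)$ are estimated; everything else is fixed
geometry.  `inclusion_scenario()` carries all of it and enforces the
invariants ($d > 0$, $h \ge 0$, $h + d \le$ thickness, $E > E_{bg} > 0$,
$0 < \nu < 0.5$).

## Scenario generation

The inversion study needs a population of scenarios.  `sample_scenarios()`
draws $(d, h, E)$ independently and uniformly from closed intervals,
rejecting and redrawing any triple violating the depth constraint, and is
a pure function of `(n, ranges, seed)`.  The default ranges --
$d \in [2, 14]$ mm, $h \in [3, 12]$ mm, $E \in [20, 120]$ kPa -- bracket
the concrete phantom inclusions used throughout: 2/8/14 mm sizes, a 5 mm
reference depth in the 20 mm slab, and the 120 kPa modulus typical of
fibrous tissue against a 5 kPa background.  A uniform distribution is an
assumption; nothing in the pipeline depends on the distribution family.

`calibration_scenarios()` generates the nine calibration inclusions as
three three-point one-parameter grids (sizes {2, 8, 14} mm at $h=5$,
$E=120$; depths {3, 6, 9} mm at $d=8$, $E=120$; moduli {40, 80, 120} kPa
at $d=8$, $h=5$).  `study_scenarios(n = 134)` composes the full set the
estimation study trains on -- 125 random triples plus the calibration
nine -- so the calibration phantoms are a subset of the study set by
construction.

## The finite-element forward model

`build_model()` meshes tissue and probe with trilinear 8-node hexahedra on
a structured tensor grid: a uniform fine window covering the probe
footprint plus one cell of margin (2.5 mm lateral cells and 2 mm vertical
layers at the default `resolution = 1`, i.e. about 3,600 elements), graded
into three coarse cells per side towards the slab boundary.  Choices worth
recording:

* **Near-incompressibility.** At $\nu = 0.49$ fully integrated linear
  hexahedra lock volumetrically.  The element stiffness integrates the
  deviatoric part with the full 2x2x2 Gauss rule and the volumetric part
  with a single central point (selective reduced integration), the
  standard remedy.  The element matrix for a unit modulus is cached per
  box geometry and scaled per element, since modulus enters linearly.
* **Inclusion representation.** Elements straddling the sphere boundary
  receive a partial-volume modulus: the inclusion volume fraction is
  estimated from a 4x4x4 sub-sample and the element modulus is the
  **harmonic** (Reuss) mixture of background and inclusion.  The harmonic
  bound matches the series-compliance load path of a stiff obstacle in a
  soft column; empirically it is also what makes the forward map
  mesh-converge (the peak inclusion signal changes by under 5% between
  `resolution = 1` and `2`, versus roughly 40% for an arithmetic
  mixture).  A strict centroid-tagging mode (`partial_volume = FALSE`)
  is available and then demands at least two cells per sphere diameter.
* **Contact.** The frictionless probe-tissue contact is approximated by
  node-tied *vertical* coupling: coincident probe-bottom and tissue-top
  nodes share their vertical degree of freedom and keep independent
  lateral ones (free slip).  For monotone indentation without lift-off
  this keeps the system linear and symmetric positive definite.
* **Boundary conditions.** The slab base is fully fixed (bone), the probe
  top is driven down by `indent_mm` and held laterally, the slab sides are
  traction-free by default.  A `"roller"` side condition (zero normal
  displacement) exists solely for verification: a full-width probe on a
  homogeneous slab with roller sides is exactly the confined-compression
  problem with uniform strain per layer, and the solver reproduces that
  closed form to machine precision -- the test suite checks the
  interface displacement of the probe-tissue series stack and the
  linear-in-depth displacement profile.
* **Solver.** One sparse supernodal Cholesky factorization per scenario.
  In the batch driver `fem_features()` the mesh topology is
  scenario-independent, so the assembly index structure, a
  triplet-to-slot map (making reassembly a sparse matrix-vector
  product in the element moduli), and the symbolic factorization are
  all reused; only the numeric factorization and the solve are redone.
  The 134-scenario study runs in well under a minute this way.

### The deformation field and the three features

`solve_indentation()` returns the probe-bottom *relative* vertical
displacement: nodal displacement minus the rigid translation transmitted
through the probe, signed so that a stiffer obstruction yields larger
positive values.  Pressing any probe into a soft slab deforms its whole
face, so this raw field contains a large smooth "bowl" that every scenario
shares.  The feature extraction therefore works on the
**inclusion-induced field** (`inclusion_field()`): the scenario field
minus the homogeneous-slab baseline computed once on the same mesh
(`fem_config(baseline = "subtract")`, the default).  A homogeneous
scenario then yields exactly (0, 0, 0) -- no inclusion signal above
baseline -- and the blob-like signal mirrors what the tactile camera
actually visualizes.  The raw-field mode remains available
(`baseline = "none"`).

The features mirror the instrument's readout on the floored field:

* maximum deformation (mm): the largest grid displacement;
* total deformation (mm): the sum of grid displacements;
* deformation area (mm^2): grid points above the area threshold, times
  the per-point cell area.

Two thresholds shape them, both chosen from measured sweep behavior and
both configurable:

* `floor_eps_mm = 0.002` (2 um): a detectability floor below which the
  optical readout registers nothing.  Without it the total feature is
  *non-monotone in depth*: a deep inclusion spreads a very wide, sub-micron
  halo whose summed mass grows with depth even as the peak falls.
* `area_eps_mm = 0.01` (10 um): the level at which area is counted, the
  simulation-side analogue of the image threshold `k`.  At much lower
  levels the thresholded area first grows with depth (the same halo
  effect) before falling; at 10 um, and with the default 4 mm
  indentation, all three features are monotone along all three parameter
  axes -- nondecreasing in size and modulus, nonincreasing in depth --
  which is the qualitative physics the pipeline must respect and the test
  suite asserts end-to-end.

The operating point `indent_mm = 4` (20% of the slab thickness,
within the small-strain bound of 25% enforced by the solver) keeps most
of the parameter space above the floor; the smallest, deepest inclusions
still fall below it, which is a real sensitivity limit of the instrument
this model emulates, not an artifact to be tuned away.

## The synthetic tactile camera

`render_tactile_image()` is a deliberately simple monotone proxy for the
waveguide optics, not a ray tracer: bilinear resampling of the
inclusion-induced field onto the 1024 x 768 raster (the 25 mm probe
footprint spans the image width; the shorter height crops it vertically,
centered), an affine gain (pixel value per mm), a Gaussian point-spread
blur, seeded additive Gaussian noise, clipping and 8-bit quantization.
Defaults: `gain = 250` px/mm, `blur_sigma = 10` px, `noise_sd = 0.5` px.
The gain places the image threshold `k = 5` at the 0.02 mm deformation
level -- comfortably above the depth-halo crossing, so the image-side
area trend stays monotone where the finer simulation grid would mask the
effect with ties.  The pixel features are the centroid-value / total /
above-`k` count triple of `quantify_image()`; the first feature reads the
pixel at the intensity-weighted centroid of the thresholded blob (with
plain-maximum fallback and a `mode = "max"` switch), which is the printed
definition of the instrument's "maximum pixel value".

What the renderer does **not** emulate: total-internal-reflection optics,
vignetting, geometric distortion, spatially correlated noise, contact
nonuniformity.  Tests passing through this renderer show the pipeline is
self-consistent under a monotone affine optical map; they do not validate
any real camera.

## Calibration

`fit_calibration()` regresses, per feature channel, the FEM-unit feature
on the TSIS (pixel) feature by ordinary least squares on the nine paired
calibration inclusions.  The direction (pixels to simulation units)
follows deployment: the inverter is trained in simulation units and
incoming data are images.  With only nine points, plain OLS is the honest
choice; on the synthetic chain the per-channel coefficients of
determination exceed 0.9 by a wide margin.  `apply_calibration()` is the
per-channel affine map, with the area channel floored at zero.

## The inversion network and its trainers

The network is the literal three-weighted-layer reading of the published
architecture: 3 sigmoid units, 4 sigmoid units, 3 linear outputs
(43 parameters), with per-channel min-max scalers mapping features and
targets to $[0,1]$; both layer sizes and activations are configurable.
Initialization draws weights uniformly within $\pm 1/\sqrt{\text{fan-in}}$
with zero biases, seeded.  The objective is the summed squared residual in
scaled space.

**Levenberg-Marquardt** iterates
$\Delta x = (J^\top J + \mu I)^{-1} J^\top e$ with the Jacobian of the
per-record, per-output residuals computed by backpropagation (verified
against central finite differences at 1e-6 relative).  The damping
$\mu$ is divided by $\beta$ after an accepted step and multiplied by
$\beta$ after a rejected one (rejected trials restore the previous
weights); defaults $\mu_0 = 10^{-3}$, $\beta = 10$.  Large $\mu$ turns
the step into steepest descent, small $\mu$ into Gauss-Newton, and on a
single linear layer one barely-damped step lands exactly on the
least-squares optimum -- all three properties are tested.

**Scaled conjugate gradient** needs only the error and gradient closures
and O(N) memory.  Each iteration probes the curvature along the search
direction $p_k$ with a finite difference of gradients at offset
$\sigma_k = \sigma/|p_k|$, scales it by $\lambda_k$, repairs
non-positive curvature (raising $\lambda$), takes the step
$\alpha_k = p_k^\top r_k / \delta_k$ if the comparison parameter
$\Delta_k$ (actual over predicted decrease) is nonnegative, halves
$\lambda$ when $\Delta_k \ge 0.75$, quadruples it when
$\Delta_k < 0.25$, and restarts the direction to steepest descent every
$N$ = 43 iterations.  A zero curvature after repair is treated as an
unsuccessful step with $\lambda$ escalation.  Defaults
$\sigma = 10^{-4}$, $\lambda_1 = 10^{-6}$.  On a 5-variable convex
quadratic the finite-difference curvature is exact and the optimizer
reaches the minimum in essentially $n$ iterations (tested to 1e-8).
Published step summaries of this algorithm vary in the positive-definite
repair; the update used here is the internally consistent one that
guarantees $\delta_k > 0$ after repair.

Both trainers run a fixed 100-iteration budget by default
(`train_config()`), matching the published training protocol, and their
accepted-step error histories are nonincreasing by construction.

## Validation and error metrics

`holdout_validate()` trains on everything except a named test subset (the
nine calibration inclusions, in the study design) and
`loocv_validate()` runs exactly $n$ folds, each testing the single
held-out record; both refit the scalers on the training portion of every
fold so no test information leaks into normalization, and both average
over repeated weight initializations (seeds `base + 0, 1, ...`; default
10 repeats).

Two error metrics are reported per output.  The headline is
`rms_relative`: the root-mean-square of $(T - Y)/T$ in physical units,
times 100.  The second, `as_printed`, is the plain average of signed
scaled residuals times 100 -- the literal form of the published error
formula.  Signed residuals cancel: an unbiased but inaccurate predictor
scores near zero, so `as_printed` cannot rank models and is included for
comparability only.  This metric discrepancy is the single biggest
caveat when comparing numbers with the published table.

## Problem sizes, determinism, budgets

The package's own study runs 134 scenarios at `resolution = 1`
(about 13,600 degrees of freedom per solve), LOOCV over all 134 folds,
100 SCGA iterations, 10 repeats; the test suite uses a 34-scenario subset
for the recovery check and a half-resolution mesh for most solver tests.
Every stochastic step (sampling, initialization, rendering noise) is
seeded and bit-reproducible; noise-free rendering is deterministic
bit-for-bit.

## Known limitations

* The inverse problem is poorly conditioned in this proxy: the three
  summary features of a single centered blob are strongly collinear, and
  for $E \gg E_{bg}$ the mechanical response saturates in the inclusion
  modulus (a nearly rigid sphere looks the same at 95 and 120 kPa).
  Recovery of depth and especially modulus by the small network is
  accordingly far worse than the published phantom-hardware figures,
  which also used the cancellation-prone signed-average metric.  The
  package reports what its own honest metric measures.
* Scenarios in the small-and-deep corner of the parameter space fall
  below the detectability floor and carry no feature information; their
  LOOCV errors are dominated by the prior spread.
* Linear elasticity, tied contact, and the affine optical proxy are all
  small-perturbation idealizations; none of the hardware-specific optics
  or layered-probe mechanics is modeled.
* Absolute feature magnitudes depend on the unpublished probe modulus
  and indentation depth; only trends and the inversion machinery are
  transferable.
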