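---
title: "Modeling positioning-error sensitivity in single-field BNCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling positioning-error sensitivity in single-field BNCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Boron neutron capture therapy (BNCT) irradiates a boron-loaded tumor with an
epithermal neutron beam. Because most clinical BNCT is delivered at research
reactors, patient positioning relies on comparatively simple fixation, and
setup errors or intra-fraction motion of a centimeter or more are plausible.
`bnctsens` quantifies how such rigid positioning deviations — lateral shifts
parallel to the beam exit, outward shifts that open an air gap, rotations
about the beam axis, and sagittal tilts — change the biologically weighted
dose delivered to a brain tumor and to the surrounding normal structures,
for tumors at two depths (2.5 cm and 6.5 cm from the posterior scalp).

The package is a desk-scale analysis pipeline: synthetic voxel phantoms, a
calibrated parametric dose engine, Gray-equivalent weighting, prescription
normalization, rigid-transform resampling, and DVH/statistical reporting.
Everything is deterministic for a fixed configuration.

## Dose model

### Four physical components

The in-phantom radiation field is decomposed, as is standard for epithermal
beams, into four physical dose-rate components per voxel: the thermal-neutron
channel (dominated by nitrogen capture), the fast-neutron channel, the photon
channel, and the boron channel expressed per ppm of ^10^B. The biologically
weighted (Gray-equivalent) rate is

$$
\dot D_{\mathrm{GyEq}}
 = f_{t}\,\mathrm{RBE}_{hi}\,\dot D_{t}
 + f_{f}\,\mathrm{RBE}_{hi}\,\dot D_{f}
 + f_{p}\,\mathrm{RBE}_{p}\,\dot D_{p}
 + f_{B}\,\mathrm{CBE}(v)\,C(v)\,\dot D_{B},
$$

with dose-rate scaling factors (DRSF) $f_t{=}0.64$, $f_f{=}1.39$,
$f_p{=}0.96$, $f_B{=}0.65$ aligning each computed component with measured
depth-dose-rate data; $\mathrm{RBE}_{hi}{=}3.2$ for the high-LET channels;
$\mathrm{RBE}_p{=}0.5$ for photons (kept exactly as adopted for this beam,
although 1.0 is the more common convention — `weighting_config()` exposes an
override); and BPA compound factors $\mathrm{CBE}{=}3.8$ in tumor and 1.3 in
normal tissue. The boron concentration is $C = 3.5 \times 25$ ppm in tumor
(T/N ratio 3.5) and 25 ppm elsewhere. The absolute normal-tissue
concentration only scales the overall dose rate, which the prescription
normalization divides away; 25 ppm is a representative clinical BPA value.
DRSF and RBE/CBE multiplications commute, so their order is irrelevant to
the result.

A direct consequence used as a sanity anchor: at equal per-ppm boron dose,
the tumor-to-normal boron Gy-Eq ratio is exactly
$3.5 \times 3.8 / 1.3 \approx 10.23$.

### The parametric kernel (transport stand-in)

Monte Carlo neutron/photon transport is out of scope; the engine is an
explicit parametric stand-in whose *constants, normalization logic and
relative quantities* are the claim — absolute Gy-Eq values are not. Each
channel dose rate at a voxel factorizes as

$$
\dot D_c = A_c \cdot g(\mathrm{gap}) \cdot P(r, d, \mathrm{gap}) \cdot
S_c(d),
$$

where $d$ is the tissue path length along the beam direction from the entry
surface of that voxel's ray (air contributes no depth), $r$ the off-axis
radius, and gap the air gap between the aperture plane and the ray's entry
point.

**Depth shapes.** The thermal and boron channels share a buildup-difference
curve $S(d) = e^{-d/\lambda_1} - e^{-d/\lambda_2}$ with
$\lambda_1 > \lambda_2$: zero at the surface, peaking at
$d^\* = \frac{\lambda_1\lambda_2}{\lambda_1-\lambda_2}
\ln(\lambda_1/\lambda_2)$ (about 2 cm with the defaults), then decaying —
the qualitative shape of thermal flux generated by moderating epithermal
neutrons. The fast channel decays exponentially
($\lambda_{\mathrm{fast}} = 1.6$ cm); the photon channel is an attenuated
exponential with a buildup fraction. Amplitudes are Gy/min at the reference
reactor power (1.2 MW), chosen so the boron channel dominates the tumor
dose and the fast channel is a small surface contaminant, as measured for
clinical epithermal beams.

**Calibration.** The one free depth constant, $\lambda_1$, is solved by
bisection so that the *advantage depth* — the depth at which the
central-axis tumor Gy-Eq rate (T/N 3.5) falls to the maximum normal-tissue
Gy-Eq rate — equals 8.5 cm, the characterizing figure of the modeled beam
(hard target, ±0.2 cm). The air-gap scale $z_0$ in the inverse-square-like
factor $g(\mathrm{gap}) = (1 + \mathrm{gap}/z_0)^{-2}$ is solved in closed
form so a 3 cm gap costs 13.5 % of the beam intensity, the midpoint of the
10–17 % deep-tumor loss band reported for 3 cm outward shifts.
`calibrate_engine()` is deterministic (no stochastic search) and attaches a
report listing each target, the achieved value, and the solved parameters.

**Off-axis profile.** The radial shape is the product of an aperture-edge
sigmoid and a super-Gaussian core:

$$
P(r, d, \mathrm{gap}) \propto
\frac{1}{1 + e^{(r - R_a)/w}} \cdot e^{-(r/\rho(d))^{p(d)}},
$$

normalized to 1 on the axis. The sigmoid sits at the aperture radius
($R_a = 7$ cm) with penumbra width $w$ growing with depth and gap at a rate
proportional to $1 - \mathrm{(current/flux)}$, so the forward-peaked beam
modeled here (ratio 0.8) keeps a tight penumbra. The core encodes the
in-tissue redistribution of thermal flux: its radius shrinks
($\rho(d) = 9.5 - 0.45\,d$ cm) while its exponent grows
($p(d) = 1.5 + 0.2\,d$) with depth. This shape was a genuine design choice
and deserves its rationale: for translations perpendicular to the beam, the
tissue depth along every ray is invariant, so in a separable kernel the
lateral-shift dose loss is governed *entirely* by the radial profile. The
benchmark data require two things at once — the profile near the axis must
be *flatter* at 6.5 cm than at 2.5 cm (the measured normalized profiles),
while the *mean tumor dose* must drop *more* at 6.5 cm under the same
lateral shift (the measured dose tables). A single sigmoid that merely
widens with depth cannot do both. The flattening-core/steepening-shoulder
form can: at depth the plateau is more uniform (the shallow profile
"pre-pays" part of its loss at baseline through its central slope), while
the sharper shoulder bites harder once a shift pushes tumor volume into it.
This mirrors the field's usual explanation via steeper isodose gradients at
depth. The constants above were fixed once, by matching the ~1 %/5 %/11 %
(deep) and ~1 %/4 %/9 % (shallow) lateral-loss ladder of the benchmark, and
are recorded in `kernel_params()`.

### What the engine does not model

No energy-resolved transport, no scatter coupling between neighboring rays
(the kernel is separable), no material-specific KERMA beyond the density
threshold that separates tissue from air, and no claim on absolute dose
rates. Consequently, passing tests demonstrate the *analysis layer* —
normalization, weighting arithmetic, geometry, metrics, statistics and the
qualitative sensitivity structure — not transport fidelity on real
patients.

## Phantoms

Two families, both generated by code (no external data):

* **Cylinder**: a homogeneous PMMA cylinder, 16 cm diameter and 25 cm long,
  axis along the beam, flat entry face at the aperture plane. This is the
  uniform-target control.
* **Head**: an ellipsoidal head (semi-axes 9.5 × 12 × 8 cm AP × SI × LR —
  an adult-head scale; the benchmark gives no dimensions) with a 0.7 cm
  soft-tissue scalp/skull shell around a brain interior, posterior surface
  facing the beam. Nine ROIs are placed at anatomically plausible
  positions: tumor, normal brain (brain minus tumor), brainstem, circle of
  Willis, and left/right eyes, lenses and optic nerves, the latter group
  anterior — on the far side from the entry surface.

The virtual tumor is a cylinder of 3 cm diameter and 5 cm length whose axis
runs superior–inferior, centered on the beam axis with the axis at 2.5 or
6.5 cm tissue depth; the deep tumor thus reaches 8 cm, just inside the
8.5 cm advantage depth. Voxel membership of every primitive is decided by
the voxel-center inequality, which makes the brute-force oracle tests
trivial to state.

Phantoms round-trip through 8-bit grayscale TIFF stacks (one file per
axial slice, masks as per-ROI stacks, a plain-text manifest holding the
label-to-gray map), and can be downsampled to the historical
21 × 21 × 25 / ≤ 56-material planning representation by block-averaged
density quantization with a volume-corrected overlap vote for the masks.

## Perturbations and resampling

The phantom moves; the beam stays fixed. Left/right shifts translate along
±x, superior/inferior along ±z, outward along +y (opening an air gap that
engages the gap factor automatically). Rotation is about the beam central
axis; tilt is about the left–right axis through the *plan isocenter* (the
tumor centroid). The isocentric tilt pivot is a deliberate design decision:
angular setup errors in radiotherapy are conventionally expressed about the
isocenter, and a pivot placed far from the target (for example the phantom
centroid, 7–10 cm from the tumor) would turn a 15° tilt into an effective
~2.6 cm translation — contradicting the benchmark's observation that tilts
up to 15° leave the tumor dose essentially unchanged.

Resampling is inverse-mapping nearest-neighbor on the same grid, so labels
stay integers and masks stay boolean; voxels pulled from outside the domain
become air. Dose is always computed *after* the transform, never
interpolated. The default working resolution is 0.5 cm, chosen so that the
battery's 1/2/3 cm translations are exact multiples of the voxel pitch:
translations then reduce to index rolls, left/right mirror symmetry is
exact, and nearest-neighbor tie-breaking cannot bias direction averages.

### Where the dose grid lives

The default pipeline evaluates the analytic kernel at the working
resolution. A `dose_grid = "planning"` mode instead runs the kernel on the
coarse 21 × 21 × 25 phantom and samples the piecewise-constant result back
onto the working-resolution masks (equivalent to fractional-volume
weighting of the coarse dose). The working-resolution default is another
deliberate deviation from mimicking the historical coarse grid end-to-end:
at ~1.2 cm voxels the tumor is only ~20 voxels, and re-rasterizing its mask
under a shift changes the included voxel set enough to inject 2–4 % jumps
into D~mean~ — larger than the 1–3 % physical effects the study measures.
With an analytic kernel there is no transport cost to paying for the finer
grid.

## Planning layer

The prescription is 20 Gy-Eq to 80 % of the tumor volume. The beam-on time
is fixed from the *unperturbed* plan,
$t = D_{\mathrm{presc}} / \dot D_{80\%}$, and reused for every perturbed
case — exactly the clinical situation in which a plan is normalized once
and the patient then moves. Because dose is linear in time, the baseline
tumor D~80%~ equals the prescription to floating-point precision.

Cumulative DVHs use 512 uniform bins from 0 to the maximum ROI dose; D~q~
is read off with linear interpolation between bin edges, which keeps the
interpolation error below the 0.01 Gy-Eq reporting precision on these
grids (the bin count is configurable). ROI metrics are D~mean~, D~max~ and
D~80%~; an empty ROI reports absent metrics rather than zeros.

## Statistics and reporting

At each shift magnitude the four lateral directions form one aggregate row
(mean ± sample SD, n = 4); rotations and tilts aggregate the clockwise and
counterclockwise senses (n = 2). Because the baseline is a single
deterministic plan value rather than a sample, perturbed metrics are tested
with a two-sided one-sample t-test against it,
$t = (\bar x - x_0)/(s/\sqrt n)$ with $n-1$ degrees of freedom; a zero
sample SD flags the p-value as undefined instead of reporting 0.
Percent changes are $100\,(x_0 - \bar x)/x_0$, reported
half-away-from-zero to two decimals, the convention of the benchmark
tables. Two cells of the published percent-change table are internally
inconsistent with the published dose tables they derive from (printed 5.52
vs recomputed 5.40, and printed 4.72 vs recomputed 8.72); the packaged
benchmark flags them and they are excluded from validation.

`export_report()` writes the five CSV tables (cylinder doses, head doses,
rotation/tilt, percent changes, normal-tissue doses), tumor DVHs, off-axis
profiles, the full per-case metric archive, the configuration, and a
manifest with an md5 configuration hash — every percent-change cell is
recomputable from the dose tables in the same report.

## Problem sizes and runtime

The default study runs 2 families × 2 depths × (baseline + 12 lateral + 3
outward + 12 angular) = 112 cases on ~150,000-voxel working grids and
completes in well under a minute on one CPU; the full test suite, including
an end-to-end battery, runs in a similar time. These sizes were chosen as
the smallest at which discretization artifacts (mask rasterization,
nearest-neighbor ties) are comfortably below the effects being measured.

## Known limitations

* The kernel is separable; real neutron fields couple neighboring rays
  through scatter, so edge effects (e.g., dose loss when part of the
  illuminated volume leaves the field) are only mimicked, not modeled.
* The head is an ellipsoid with stylized ROIs; no CT heterogeneity,
  no skull-specific attenuation.
* Absolute Gy-Eq values and beam-on times are not claims; only
  normalized/relative quantities are meaningful.
* The t-test treats direction-averaged values as a sample of independent
  measurements, which inherits the benchmark's own statistical convention
  rather than defending it.
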