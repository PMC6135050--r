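---
title: "Current source density analysis of multi-position EAGs: model and methods"
author: "antennaCSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current source density analysis of multi-position EAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antennaCSD)
```

## The physical model and its assumptions

The electroantennogram (EAG) is a field potential: odor-activated olfactory
receptor neurons (ORNs) draw cations into their dendrites, creating an
extracellular current sink on the antennal surface and a negative potential
that decays with distance from the sink. `antennaCSD` inverts this
relationship for insects with bulbous antennae, mapping an EAG distribution
recorded at N proximo-distal positions onto the current source density (CSD)
that generated it.

The model makes four assumptions worth keeping in mind when interpreting a
map:

1. **Surface conduction.** The current flows only along the funiculus
   surface (the EAG collapses when an electrode pierces the cuticle, so the
   interior is treated as non-conductive). The surface is virtually
   unfolded into a plane; no periodic wrap in the circumferential direction
   is applied.
2. **Point-source electrostatics.** A source element contributes
   $\phi = I/(4\pi\sigma r)$, the three-dimensional kernel, evaluated on
   the unfolded plane.
3. **Compartmental uniformity.** The CSD is constant on each of N
   rectangular compartments, one per electrode. This is what makes the
   inverse unique — and it is the sole source of the biases quantified by
   the simulation tools (see below).
4. **One-dimensional organization.** ORN classes are assumed to vary along
   the proximo-distal axis only; classes confined to one side of the
   funiculus violate this and can produce spurious structure.

With the electrode at proximo-distal position $x_i$ (lateral offset 0), the
transfer coefficient from compartment $j$ is

$$F_{ij} = \frac{1}{4\pi\sigma}\int_{-Y_j}^{Y_j}\!\!\int_{lo_j}^{hi_j}
  \frac{dx\,dy}{\sqrt{(x - x_i)^2 + y^2}}$$

The integrand's singularity when the electrode lies inside its own source
rectangle is integrable; the package evaluates the whole integral with the
exact antiderivative $G(a,b) = a\,\mathrm{asinh}(b/a) + b\,\mathrm{asinh}(a/b)$
combined over signed corner rectangles, so self-terms are handled without
quadrature error (a semi-analytic adaptive quadrature route is available in
`transferCoefficient(..., method = "quadrature")` as a cross-check). The
estimate is then the exact linear inverse $C = F^{-1}\phi$ per time point:
no information is lost, the CSD is the EAG distribution seen through a
change of coordinates.

## Parameters and conventions

* **Compartment windows.** Interior boundaries sit at electrode-gap
  midpoints. When the outer electrodes are at the extremities this yields
  the half-width edge windows $[x_1, x_1 + h/2]$ and $[x_N - h/2, x_N]$
  (no sensilla beyond the arista base or the tip); when a subset of
  positions is analysed, the outer windows are extended to 0 and to the
  full length so the modeled antenna keeps its physical size.
* **Circumference q** (mm): Ramanujan's approximation for the elliptical
  cross-section with semi-axes width/2 and thickness/2, evaluated at the
  compartment midpoint for cones. Exact for circles, within 0.05 % of the
  true perimeter for antennal aspect ratios.
* **Lateral bounds** (`lateralExtentMode`): the source rectangle spans
  $y \in [-q, q]$ in mode `"printed"` — the bounds exactly as the source
  formula prints them — or $y \in [-q/2, q/2]$ in mode `"half"`. The two
  conventions are internally inconsistent in the literature this model
  derives from: $q$ is *described* as the full cross-section circumference,
  which under an exact unfolding of the surface spans $\pm q/2$, while the
  printed integral bounds are $\pm q$ (covering the surface twice). Both
  are implemented; they differ only by a smooth rescaling of the
  coefficient profiles, not by any sign or ordering change. The package
  default is `"printed"` for fidelity to the printed formula; quantitative
  benchmark work in this package states its mode explicitly and uses
  `"half"`, the physically consistent unfolding, which also reproduces the
  published case-9 bias ratios more closely (see below).
* **Conductivity σ** (default 10, the published median across individuals,
  in the literature's mΩ/mm units): a pure multiplicative prefactor.
  Doubling σ halves every forward coefficient and doubles every estimated
  CSD; the spatial profile is unchanged. The printed unit is dimensionally
  a resistance density; the package treats σ as an opaque positive scalar,
  which is all the linear algebra requires.
* **Species presets.** Eight geometries ship with the package. The moth
  preset (`Csac`) uses the published measurements (length 13 mm, width
  0.125 mm). The seven fly presets are *representative* values placed
  inside the published ranges (funiculus length 0.15–1.1 mm, width/length
  0.2–0.6, the larger antennae tending to be the more elongated); exact
  per-species dimensions were never published as numbers. They are meant
  to be replaced by one's own microscope measurements; quantitative work
  should always state its geometry. `Zcuc` (length 1.0 mm, width 0.30 mm)
  is the package-wide default. Thickness defaults to width (near-circular
  cross-sections).
* **Smoothing width.** "Gaussian convolution of 20 ms width" is read as
  kernel standard deviation 20 ms (`widthMode = "sd"`); an FWHM reading is
  available since the convention differs between laboratories. Convolution
  uses reflect padding so baselines near the record edges are not dragged
  toward zero.
* **Metric windows** are half-open: the onset sample belongs to the
  baseline, the first sample strictly after onset to the response.
* **Center of mass** uses positive responses only; negative responses are
  clamped to zero (an `"exclude"` option gives the identical result). When
  no response is positive the center is undefined and returned as `NA`,
  never as 0.
* **Inversion.** Direct solve, no regularization: N ≤ 7 antennal models
  are well-conditioned (condition numbers of order 10–100). A
  condition-number diagnostic is attached to every inverse and an error is
  raised above 1e6; a ridge option exists for pathological irregular
  arrays but is off by default. These thresholds are engineering choices —
  the inversion itself is exact.

## What the simulation tools establish

`makeTestCSD()` encodes ten artificial source distributions.  Cases 1–7 are
0/1 profiles on a 10-compartment fine model whose bins are aligned so that
bins 1–2 equal the proximal compartment and bins 3–5 the second compartment
of the 4-electrode model; `runRoundtrip()` forward-projects them at fine
resolution and inverts at coarse resolution.  The reproducible patterns:

* a source coinciding with a model compartment is recovered exactly;
* a source *larger* than a compartment is detected, with its sign, in every
  compartment it overlaps;
* a source *smaller* than a compartment is detected in that compartment and
  flanked by spurious reverse-polarity estimates in neighboring
  compartments — indistinguishable, at N positions, from genuine lateral
  inhibition.

The exact bin layouts of the published panels are not tabulated anywhere,
so the package pins plausible layouts and the tests assert the sign
patterns, not bin identities. One layout was constrained by the physics:
a sub-compartment strip *abutting* a compartment boundary produces a
positive leak into the neighbor rather than a reverse-polarity artifact,
so the depicted artifact cases are pinned to strips in compartment
interiors.

Cases 8–10 quantify the bias for equal total current placed differently
within the proximal compartment: density 1 on the whole compartment (8),
density 2 on its proximal half along the axis (9), density 2 on a strip of
half the diameter (10; the halved diameter applies to the forward test
model only, not to the inverse). `caseRatioReport()` returns the six
case-9/case-10 ratios in percent of case 8. "Increased by 127 %" phrasing
is read uniformly as "the new value is 127 % of the old" — the companion
"decreased to 89 %" fixes that convention, and a 2.27-fold jump from moving
half a compartment of current would be physically implausible under the
surface integral. Under the package's benchmark configuration (Zcuc
preset, `"half"` bounds) the computed ratios are 125.0 / 89.3 / 135.4 for
case 9 — within ~2 points of the published 127 / 89 / 136 — and
151.5 / 121.9 / 160.7 for case 10 against published values of
149 / 200 / 136. The case-10 proximal-EAG ratio agrees; the remaining two
published case-10 values cannot be produced by this model under *any*
geometry in the plausible range: the model enforces
proximal-ratio > second-electrode-ratio for lateral concentration, while
the published pair (149 < 200) violates it, and inverting case 10 with a
*matched* halved-diameter model returns exactly 200.0. The package
therefore reports its computed values and documents the discrepancy rather
than reproducing those two numbers.

`randomActivationExperiment()` draws one activation level per basiconic
sensilla class ("per class" rather than per individual sensillum: the
~10–40 sensilla per class average out to nearly the same curve), builds
the response-density curve, treats it as a current source profile on a
100-compartment model, samples 4 electrode potentials and inverts with a
4-compartment model. Activation levels are i.i.d. uniform on [0, 1] by
default (the original description says only "a random level"; an
exponential option verifies the conclusions are distribution-robust).
Pooled over simulations, the estimated CSD tracks the local response
density tightly (r² ≈ 0.99 at the default settings) while the EAG —
blurred by distance — tracks it loosely (r² ≈ 0.55), with a slightly
negative CSD intercept at zero density (compensatory reverse polarity
around sub-compartment structure) and a positive EAG intercept (distant
sources contribute additively). These relations, not the third digit of
any r², are the meaningful result; the acceptance suite asserts them as
r²(CSD) ≥ 0.90, r²(EAG) in [0.35, 0.70] and the sign/ordering checks.

`geometrySweep()` re-estimates one EAG distribution under different
modeled geometries. The peak compartment is invariant across all presets
and across cylinder vs 3:1 cone variants of equal mean diameter; the
amplitudes are not, and in the compartments actually carrying the response
the CSD level anticorrelates with the modeled compartment surface (remote
compartments carry only small geometry-dependent artifacts of either
sign — a relation the data cannot constrain).

## The funcmap module

One-dimensional cellular maps of the female *D. melanogaster* antenna are
built from three published ingredients: per-class sensilla counts
(fractional counts are averages over individuals; they total 329.075
sensilla), logit-normal spatial distributions on the normalized [0, 1]
axis, and user-supplied per-ORN response levels (e.g. from the DoOR
consensus database, which the package deliberately does not ship). Class
centers and spreads are given in *position* units; the latent Gaussian
parameters are obtained by the delta method (latent mean logit(m), latent
sd s/(m(1−m))), so the local spread near the center is approximately s. A
`"latent"` mode that takes s directly on the logit scale is also provided;
results in this package state their mode. The delta mapping is wide near
the boundaries — the ab3 class (center 0.05) has its mode shifted ~0.02
proximally of its nominal center, which is physically sensible for a class
crowded against the arista. Trichoid center assignment follows the
published listing order (at1, at3, at2, at4 at 0.65–0.80); a numeric-order
assignment cannot be excluded from the text and would only permute three
nearby curves of the same family.

## The synthetic-recording generator

`synthesizeRecording()` forward-projects a space-time CSD profile and adds
i.i.d. Gaussian noise — the fixture generator used throughout the tests
(the original raw recordings are unpublished). It emulates the linear
physics exactly and the noise floor crudely; it does *not* emulate
adaptation, drift, correlated (1/f) noise, electrode-contact variability,
or inter-individual variability in sensilla placement. Passing tests on
these fixtures therefore validates the estimator's algebra and its bias
structure, not its robustness to everything real recordings contain.
Gaussian noise propagates through the inverse exactly
(sd(C_i) = s·‖F⁻¹ row i‖, verified by Monte Carlo), which is also the
practical rule for how many trials to average.

## Problem sizes and numerical choices

The test and acceptance computations use 4–10 electrode models (100
compartments for the random-activation experiment, 1,000 simulations,
1,000-point density grids) — the sizes the original analyses used, and
small enough that the full suite runs in a few minutes on one CPU. Matrix
inverses are validated to 1e−10, roundtrips to 1e−9, text-format
roundtrips to 1e−12. Degenerate inputs fail loudly: zero-area windows,
non-increasing positions, missing metadata keys, truncated metric windows
and near-singular matrices all raise errors naming the offending quantity.

## Known limitations

* Geometry presets for flies are representative, not measured; all
  quantitative output should state its geometry.
* The two lateral-bound conventions differ by a smooth rescaling; absolute
  CSD amplitudes (not spatial patterns) depend on the choice, on σ, and on
  the measured circumference, so cross-species amplitude comparisons need
  matched conventions throughout.
* The 1-D compartmental assumption cannot separate a small source from
  lateral inhibition of its neighbors, and circumferentially confined ORN
  classes are invisible to it.
* The GC-EAD mode integrates CSD within user- or FID-derived retention
  windows; FID/EAG transfer-line delay is a user-set constant, not
  estimated.
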