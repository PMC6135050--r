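# antennaCSD

Current source density (CSD) analysis of multi-position electroantennogram
(EAG) recordings from insects with bulbous antennae.

## The problem

An odor puff activates olfactory receptor neurons (ORNs) whose dendritic
receptor currents create extracellular current *sinks* on the antennal
surface; these sinks generate the negative field potentials an EAG electrode
records. Because each responsive ORN class occupies a restricted region of
the fly funiculus, a single-electrode EAG under- or over-reports compounds
depending on where the electrode happens to sit. Recording the EAG at N
proximo-distal positions and inverting an electrostatic model of the antenna
turns the potential distribution into a spatial map of the underlying
current sources — i.e., a map of where the activated ORNs are.

This package is for insect electrophysiologists and chemical ecologists who
record multi-position EAGs (including GC-EAD rigs) and want quantitative,
geometry-aware activation maps rather than raw potentials.

## The model

The funiculus surface is unfolded into a plane and split into one
rectangular compartment per electrode, each carrying a uniform current
source density C_j. A point source in a homogeneous conductor produces
φ = I/(4πσr), so the potential at electrode i from compartment j is

    F_ij = 1/(4πσ) ∬_rect_j dx dy / sqrt((x − x_i)² + y²)

integrated over the compartment's proximo-distal window (with half-width
edge windows at the extremities) and the lateral extent of the funiculus
circumference q (Ramanujan's ellipse approximation of the cross-section).
The integral has an exact closed form built from
a·asinh(b/a) + b·asinh(a/b), which handles the electrode-inside-the-source
singularity. Stacking the coefficients gives φ = F·C; the CSD estimate is
the exact inverse, C = F⁻¹·φ, applied at every time point. Negative C is a
current sink, i.e. ORN activation.

Scalar response metrics follow the standard definitions: EAG amplitude
(post-onset negative peak minus pre-onset baseline), CSD response area
(sign-reversed integral over 1.5 s post-onset), CSD response amplitude
(pre- minus post-onset minima), and the center of mass of positive responses
for localization.

## Worked example

```r
library(antennaCSD)

geom  <- speciesGeometry("Zcuc")              # melon-fly funiculus preset
model <- buildModel(geom, c(0, 1/3, 2/3, 1))  # 4 electrodes -> 4 compartments
model
#> CompartmentModel (cylinder, printed lateral bounds): 4 compartments on 'Zcuc'
#>   windows (mm): [0, 0.1667] [0.1667, 0.5] [0.5, 0.8333] [0.8333, 1]
#>   circumferences (mm): 0.9425, 0.9425, 0.9425, 0.9425

# a proximal sink of unit density predicts this EAG distribution:
phi <- predictEAG(model, c(-1, 0, 0, 0))
phi
#> EAGSnapshot (mV) at 4 positions:
#>         0     0.333     0.667         1
#> -0.009094 -0.005457 -0.003345 -0.002394

# and inverting the potentials recovers the sink exactly:
round(csdValues(estimateCSD(model, phi)), 12)
#> [1] -1  0  0  0
```

The potential decays with distance from the proximal source (−0.0091 mV
under the source electrode down to −0.0024 mV at the tip), and the inverse
is an exact change of coordinates, so the sink is recovered to machine
precision. For recordings, `preprocessEAG()` smooths and
control-subtracts, `estimateCSDTimeseries()` maps every time point, and
`subsetAnalysis()` / `geometrySweep()` / `runRoundtrip()` /
`randomActivationExperiment()` quantify how electrode count, antennal
geometry and sub-compartment structure bias the estimates. A thin CLI is
shipped in `inst/scripts/antcsd` (subcommands `model`, `forward`, `csd`,
`metrics`, `simulate`, `funcmap`, `gcead`).

See the methods vignette (`vignettes/csd-methods.Rmd`) for the model's
assumptions, parameter conventions and known limitations.

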