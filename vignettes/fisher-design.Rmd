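---
title: "Designing neutron reflectometry experiments with the Fisher information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing neutron reflectometry experiments with the Fisher information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refdesign)
```

## The design problem

A specular neutron reflectivity curve R(Q) constrains the
scattering-length-density (SLD) depth profile of a layered sample, but the
inversion is ill-posed: many profiles fit one curve comparably well, and the
statistical quality of the data decides how tightly the slab-model
parameters — thicknesses, SLDs, roughnesses, hydrations, magnetic
moments — can be pinned down. Beamtime is scarce, so the design question is
concrete: given a fixed counting-time budget, which measurement angles,
solvent contrasts, time splits and sample modifications produce the most
information about the parameters of interest?

`refdesign` answers this by simulating the experiment's *expected* counts and
scoring designs with the Fisher information (FI) of the Poisson counting
statistics, so no fitting or posterior sampling is needed inside the search
loop.

## Models and their assumptions

**Reflectivity kernel.** Samples are stacks of homogeneous slabs between two
semi-infinite media. The kernel is the exact Abelès transfer-matrix solution,
verified in the test suite against an independently coded Parratt recursion
to 10⁻¹⁰ relative on randomized stacks. Assumptions and conventions:

* **Roughness** enters through Névot–Croce Gaussian factors
  exp(−2 k_n k_{n+1} σ²) at each interface — the convention of the standard
  slab-model analysis packages. Other roughness treatments (error-function
  micro-slicing) would shift absolute eigenvalues slightly.
* **Hydration** is linear volume-fraction mixing,
  ρ_eff = (1 − h) ρ + h ρ_solvent, applied before the kernel; solvent
  contrast changes touch nothing else ("molecular volumes fixed").
* **Polarized channels** (spin up/down) see ρ ± ρ_mag per layer, i.e.
  non-spin-flip scattering only; spin-flip channels are out of scope.
* **Resolution smearing** is Gaussian in Q with constant fractional width,
  `dq_over_q` read as the FWHM of dQ/Q (default 2 %). It is evaluated with
  fixed 17-point Gauss–Legendre quadrature over ±3.5 σ, with weights
  normalized to sum to one so a flat curve is conserved exactly; the tests
  hold this against dense (≥301-point) quadrature to 10⁻⁶ relative.
* **Background** is a constant added *after* scaling and smearing,
  R_tot = scale · R_smeared + b, matching data synthesized without
  background subtraction. Background-subtracted (Skellam-statistics) data
  are deliberately unsupported: the Poisson FI derivation does not hold for
  them, and the correct treatment is to keep the background in the model.
* An imaginary SLD slot exists for absorbing media but defaults to zero;
  no bundled sample needs it.
* SLDs are 10⁻⁶ Å⁻² everywhere in the interface; the conversion to absolute
  units happens once inside the kernel.

**Instrument.** A time-of-flight white beam over a wavelength band (default
[1, 14] Å) at fixed angle maps each wavelength to one Q point. The flux
profile stores neutrons/s per wavelength bin at a reference angle
(θ_ref = 0.3°) with the constant ~60 mm footprint absorbed into its
normalization; both apertures scale linearly with angle, so flux scales as
(θ/θ_ref)² and only that ratio matters. Q bins are logarithmically spaced
across the band (the conventional TOF binning; 100 points per angle by
default), and incident counts per bin integrate the piecewise-constant flux
density over the bin's wavelength interval.

`synthesize_flux()` generates a smooth Maxwellian-like moderator spectrum
(λ⁻⁵ exp(−5λ_peak²/2λ²), peak 2.5 Å, 5×10⁵ n/s integrated — a realistic
order of magnitude for a reflectometer at a spallation source) in place of a
measured instrument table; polarized profiles multiply in a logistic
transmission (cut-on 2.5 Å, width 0.5 Å) emulating the low-wavelength loss
of polarizing optics. A real instrument table drops in through
`read_flux_table()` (two-column ASCII) unchanged. **What this does not
emulate:** the measured spectral shape, absolute calibration and
polarization efficiency of any particular beamline. Relative comparisons
between designs — which is all the optimizers use — are insensitive to the
overall normalization, but absolute eigenvalues reported here are not
comparable to values computed with a measured flux profile.

**Counting statistics.** Expected counts are λₖ = R_tot(Qₖ) · Iₖ, exactly
linear in counting time. `realize()` draws nₖ ~ Poisson(λₖ) and reports
r = n/I, dr = √n/I; zero-count bins are kept with a one-count floor
(dr = 1/I) so log-scale fitting stays possible. Multi-angle experiments
remain lists of per-condition datasets — the FI sums over them, so no
stitching convention is ever needed.

## The information objective

For independent Poisson bins the FI over parameters θ is
G_ij = Σₖ λₖ⁻¹ (∂λₖ/∂θ_i)(∂λₖ/∂θ_j), in nats per parameter-unit². Numerical
choices:

* Derivatives are central finite differences with relative step 10⁻³ of the
  parameter value and an absolute floor of 10⁻⁸. A step-halving test keeps
  the matrix stable to better than 10⁻³ relative on every bundled model, and
  the matrix itself is checked against the Monte-Carlo average of observed
  Poisson Hessians over 5000 simulated datasets.
* Bins with λₖ = 0 contribute exactly zero (the Poisson limit), never NaN.
* Non-finite gradients raise an error naming the offending parameter; an
  inert parameter simply yields a zero row and a singular matrix, which
  `crb_uncertainties()` reports as unbounded.

**Importance scaling.** Eigenvalues of G are unit-dependent, so the scaled
matrix D G D with D = diag(w) is used for design. The default w_i = |θ_i|
makes the scaled FI dimensionless — information per *fractional* change —
which is the natural reading of "all parameters equally important in their
specified units" when those units differ by orders of magnitude; any custom
weighting can be supplied instead. This is a design choice of this package:
with a different importance convention the absolute eigenvalues (though
rarely the argmax of a design search) change. The default errors loudly if
some θ_i = 0 rather than silently weighting a parameter out.

**Objective.** The minimum eigenvalue of the scaled matrix (an E-optimality
criterion) scores the worst-determined linear combination; its negative is
handed to the minimizer. The Cramér–Rao bound gives per-parameter σ_i from
the inverse of the raw matrix (native units) and
σ_worst = 1/√(min eigenvalue) on the fractional scale; both are validated
against brute-force grid posteriors to within 15 % at high counts.

For kinetic measurements (a degrading monolayer tracked through its area per
molecule) there is a single parameter and no covariances, so the raw scalar
FI summed over the snapshot series is the objective directly.

## The sample zoo and its placeholders

The bundled models are structural archetypes, not refits of any measured
dataset; their parameter values are literature-typical placeholders, clearly
overridable, because the originally fitted values live in supplementary
material that is not reproduced here. Consequences: qualitative design
behaviour (endpoint contrasts optimal, null-reflecting water optimal for
monolayer kinetics, platinum-thickness sensitivity of the magnetic stack) is
the test surface; table-exact optimal SLD/thickness values from the source
experiments are not reproducible from these placeholders and are not
asserted anywhere.

* `contrast_bilayer()` — silicon / native oxide / head–tail–head bilayer /
  water, beam through the silicon, every hydrated layer mixed against a free
  water-contrast SLD in [−0.56, 6.36] × 10⁻⁶ Å⁻² (pure H₂O to pure D₂O,
  both recomputed from scattering lengths and densities rather than
  hardcoded). Deuteration swaps the tail SLD only. The FI set is oxide
  thickness/hydration, oxide–bilayer roughness, head thickness/hydration and
  tail thickness.
* `add_underlayers()` — up to three films between oxide and bilayer, SLD in
  [1, 9] × 10⁻⁶ Å⁻², thickness in [0, 500] Å, fixed 2 Å roughness and zero
  hydration. With underlayers present the oxide hydration is forced to zero
  and both it and the oxide–bilayer roughness leave the FI set; the
  underlayer parameters themselves are nuisance parameters (well determined
  by wafer characterization in practice) and never enter the objective.
* `apm_monolayer()` — air / tails / hydrated heads / water, with layer
  compositions derived from one area-per-molecule (APM) parameter via
  Σb/V packing; `kinetic_series()` spans 54.1→500 Å² in 20 linear steps
  (linear spacing and equal per-snapshot time are package choices; only the
  range, count and 150-minute total are canonical).
* `magnetic_stack()` — garnet substrate / garnet film / platinum cap with a
  21 Å magnetized sub-slab adjacent to the film whose thickness stays fixed
  as the cap thickens, conserving total moment. The conversion
  ρ_mag = (γ_n r_e/2) μ n uses the first-principles constant
  2.6955×10⁻⁵ Å/μ_B, validated in the tests by independent derivation.

## Design search

Landscapes (`scan_1d`/`scan_2d` over objective factories) and the joint
optimizers use **noise-free expected counts**: the large-budget limit in
which Poisson noise in the objective vanishes, which is exactly what a large
time budget is meant to approximate, and which makes every landscape
deterministic and bit-reproducible. Because the FI is linear in time,
rescaling the budget rescales every eigenvalue by the same factor and leaves
every argmax unchanged (asserted to 10⁻⁶ in the tests), so the budget's
absolute value is immaterial to the optimum.

The optimizer is a bounded best/1/bin differential evolution written for
this package (no DE implementation is among its dependencies):
population 15 × dim, F = 0.8, CR = 0.9, relative population-spread
convergence tolerance 0.01, maxiter 200, explicit seed, with non-finite
objective values penalized and logged rather than fatal. Time fractions are
searched on [0.01, 1]ⁿ and renormalized onto the simplex — a smooth,
bound-respecting alternative to constrained moves. Contrasts returned within
0.05 × 10⁻⁶ Å⁻² of each other are merged with their time fractions summed
(near-identical contrasts are the optimizer's way of saying "fewer contrasts
suffice"), and the reported objective is recomputed from the merged
conditions so the result row is self-consistent. Angle optimization holds
the contrasts fixed at the D₂O + H₂O pair by default, mirroring the
sequential contrasts-then-angles workflow; all contrasts share the same
angles and angle-time proportions.

## Validation tools

The Gaussian log-likelihood −½ Σ ((r_i − R_model(Q_i))/δr_i)² (normalization
constant omitted — it cancels in every ratio used) supports
model-discrimination scans: data are simulated from the
alternative model at a series of counting times (per measured spin state;
both non-spin-flip channels are counted) and the mean log likelihood-ratio
against the null model is reported with its replicate spread. Under the
alternative the curve grows with time; under the null, profiling the
likelihood over the extra parameter reproduces χ²₁-scale ratios (checked
loosely, factor-two band, in the tests). A brute-force two-parameter grid
posterior under flat priors provides the independent σ cross-check for the
Cramér–Rao bounds and warns when more than 1 % of its mass touches the grid
boundary.

## Problem sizes and numerical choices in the shipped checks

The test suite and the acceptance script run on deliberately modest sizes
chosen as representative rather than exhaustive: the synthetic flux uses
100–200 wavelength bins; kernels are cross-checked on 100 random ≤5-layer
stacks; the Monte-Carlo Hessian check uses 5000 Poisson replicates of a
two-parameter, 50-bin toy; the bundled two-contrast optimization runs DE
with population 20 and ≤30 generations (the endpoint optimum is reached long
before the default budget would allow); the monolayer landscape uses the
full 20-snapshot series on a 50-point contrast grid; discrimination scans
use 8 time points × 50 replicates. All seeds are explicit.

## Known limitations

* Absolute eigenvalues depend on the flux normalization, the per-bin
  incident-count convention and the importance weighting; only comparisons
  within one convention are meaningful, and cross-package eigenvalue
  comparisons require matching all three.
* The slab/hydration description cannot express lateral inhomogeneity,
  defect microstructure or volume changes with conditions.
* The FI is an asymptotic (Cramér–Rao) statement: it assumes the model is
  correct and bounds *unbiased* estimators; strongly multimodal posteriors
  at low counts can be wider than the bound suggests.
* Instrument resolution is a constant dQ/Q Gaussian; angle-dependent
  resolution functions and gravity/chopper corrections are not modelled.
* Changing contrast or angle is assumed free of overhead time; sharp optima
  should be weighed against flatter neighbouring regions when conditions
  cannot be controlled precisely.
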