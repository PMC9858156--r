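---
title: "Monte Carlo differential pathlength factors for layered skin: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo differential pathlength factors for layered skin: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skindpf)
```

## The problem

In reflection-mode near-infrared spectroscopy (NIRS) a source and a detector
sit on the skin surface a few millimetres apart. Because tissue scatters
strongly, detected photons travel far longer than the geometric
source-detector separation $d$; the modified Beer-Lambert law accounts for
this with the differential pathlength factor (DPF),

$$A_\lambda = \varepsilon_\lambda \, C \, d \, \mathrm{DPF}(\lambda, d),$$

so that chromophore concentrations $C$ inferred from attenuation $A$ are
scaled correctly. `skindpf` estimates $\mathrm{DPF}(\lambda, d)$ for human
skin by Monte Carlo photon transport through a layered tissue model, along
with per-layer partial pathlengths (which layer the detected light actually
sampled) and spatial sensitivity maps (the "banana" between source and
detector).

## Tissue model

The default model is a seven-layer stack — stratum corneum, epidermis,
papillary dermis, upper blood net dermis, reticular dermis, deep blood net
dermis and subcutaneous tissue — with thicknesses (0.02, 0.25, 0.1, 0.08,
0.2, 0.3, 2) mm and per-layer blood and water volume fractions, built by
`build_default_model()`. A single scattering spectrum (60.61, 41.74, 22.33,
15.05, 13.32, 9.5, 7.52 mm$^{-1}$ at 450–1050 nm in 100 nm steps) is applied
to every layer; per-layer spectra can be supplied through the YAML config
(`read_model_config()`).

Absorption is assembled from chromophore volume fractions. For a perfused
layer,

$$\mu_a = V_\text{blood}\,\big(S\,\mu_a^{HbO_2} + (1-S)\,\mu_a^{Hb}\big)
        + V_{H_2O}\,\mu_a^{H_2O}
        + \big(1 - V_\text{blood} - V_{H_2O}\big)\,\mu_a^{other},$$

with blood oxygen saturation $S$ (default 0.75). The epidermis replaces the
blood term with melanin, $\mu_a^{mel}(\lambda) = C_{mel}\,\lambda^{-3.33}$
with $C_{mel} = 6.6\times10^{10}$ (λ in nm, result in mm$^{-1}$); published
versions of this law differ in the constant by an order of magnitude
depending on units conventions, so the constant is an argument of
`melanin_mua()`. The source formulation of the epidermis mixture pairs the
water volume fraction with an oxyhemoglobin spectrum, almost certainly a
misprint for the water spectrum; both readings are implemented behind
`middle_term = c("water", "hbo2")` (default `"water"`) rather than silently
picking one.

The chromophore spectra themselves (water, Hb, HbO$_2$ at 150 g hemoglobin/L,
and a flat 0.01 mm$^{-1}$ residual baseline) are a literature-standard
compilation shipped in `chromophore_library()` and fully overridable: the
layered model is only as good as these inputs, and alternative compilations
can be swapped in without touching the transport code.

Parameters never fixed by the source compilation were set once to standard
tissue-optics values: anisotropy $g = 0.9$ for every layer, refractive index
$n = 1.37$ against air ($n = 1.0$), oxygen saturation $S = 0.75$. All are
per-layer configurable.

## Transport scheme

The engine (`run_transport()`, compiled C++) propagates weighted photon
packets launched as a pencil beam at the origin, +z into the tissue, with
the specular reflection of the normally incident beam deducted at launch.

* **Step sampling.** Two conventions are implemented. The default,
  `step_sampling_mode = "total"`, samples inter-event lengths at the total
  interaction rate $\mu_t = \mu_a + \mu_s$ — the standard unbiased
  multi-layer scheme, with steps carried across layer interfaces in optical
  depth. `"scattering"` samples at $\mu_s$ alone, the literal free-path
  density $p(l) = \mu_s e^{-\mu_s l}$ of the source description; it
  under-attenuates slightly when $\mu_a/\mu_s$ is not small and exists for
  fidelity comparisons. Both deposit $\Delta w = w\,\mu_a/(\mu_a+\mu_s)$
  per interaction.
* **Scattering.** Henyey-Greenstein polar cosine by inverse CDF, uniform
  azimuth, rotation in the local frame of the incoming direction
  (isotropic branch at $g = 0$; numerically degenerate vertical incoming
  directions handled separately).
* **Boundaries.** Unpolarized Fresnel reflection/Snell refraction at every
  refractive-index step, with total internal reflection beyond the critical
  angle; `matched_boundaries = TRUE` disables all index steps for
  sensitivity studies. With the default uniform $n = 1.37$ only the air
  interface carries a step.
* **Bottom boundary.** `"transmit"` (default) kills packets crossing the
  bottom of the last layer, booking them as transmitted; `"semi-infinite"`
  extends the last layer without bound, matching the semi-infinite slab
  idealization.
* **Termination.** Russian roulette below weight $10^{-4}$ with survival
  probability 0.1 (survivors reweighted by 10, conserving expected weight),
  plus a safety cap on total pathlength (default 1000 mm) whose kills are
  booked separately. A hard low-weight cutoff without reweighting would
  bias pathlength statistics; roulette does not.
* **RNG.** A small counter-seeded xoshiro256++ generator keyed by
  `(seed, stream)`, so every replicate is independent and individually
  reproducible bit-for-bit, independent of R's global RNG state.

Every run returns a detection ledger whose energy channels — specular, top
escape, bottom escape, absorption, roulette net loss, cap truncation — must
balance the launched weight; `conservation_residual()` is at floating-point
level ($<10^{-12}$) for any completed run and is asserted below $10^{-6}$
throughout the test suite.

## Detection and estimators

Detected means escaped through the top surface into a detector bin. Two
acceptance geometries are implemented, both with 0.5 mm default bin width:

* `"ring"` — annuli in exit radius $\sqrt{x^2+y^2}$ centred on each
  separation: the variance-optimal reading under radial symmetry;
* `"strip"` — bins in the exit $|x|$ coordinate: the literal Cartesian
  reading of a detector placed at $(d, 0, 0)$, accepting any $y$.

The DPF estimator (`dpf_from_ledger()`) divides the mean detected optical
pathlength by the separation. The default weights each packet by its
detected weight, the estimator consistent with packet weighting; the
unweighted mean over detected packets is available for comparison. Replicate
statistics (`replicate_sweep()`) use the sample standard deviation across
independently seeded runs.

## The replication configuration

The packaged replication protocol (the `paper` preset of
`experiment_spec()`, and the configuration used by `scripts/acceptance.R`
and the acceptance tests) is: default 2% melanin stack, **strip** detection,
**semi-infinite** subcutis, **weighted** estimator, total-rate sampling.
The strip/semi-infinite choices resolve two genuinely open readings of the
reference setup (a Cartesian point detector position, and a "semi-infinite"
stack whose printed thicknesses are finite); among the literal readings they
are the self-consistent pair, and with the literature chromophore
compilation they reproduce the published reference DPF values at the longer
wavelengths (750–1050 nm) to within a few percent at separations ≥ 1 mm
without any parameter adjustment.

At 450–550 nm the published reference values are not reproducible under
*any* configuration of this model with literature hemoglobin absorption: a
DPF of ~43 at 8 mm implies ~350 mm mean detected paths, which carry weight
$e^{-\mathcal{O}(100)}$ at the dermal $\mu_a \gtrsim 1\,$mm$^{-1}$ implied
by the stack's blood fractions — the reference values at short wavelengths
are consistent only with an effective absorption orders of magnitude below
literature blood spectra. The package keeps the literature compilation and
reports the discrepancy rather than fitting absorption to the reference
table. For the same reason, short-wavelength far-detector bins are empty
under roulette at any photon budget; replication runs at 450/550 nm
therefore disable roulette (unbiased for the weighted estimator) under a
150 mm path cap whose truncated weights are negligible against the weighted
mean.

## Oracles and validation

Two deliberately simple, code-independent references live in the package and
are exercised by `validate_suite()` and the test suite:

* `scalar_walker()` — a one-photon-at-a-time pure-R random walk with the
  same physics, no vectorization, R's own RNG; the engine must agree with
  it within 3 combined standard errors on a two-layer toy model.
* `diffusion_dpf()` — the steady-state diffusion closed form
  $\tfrac12\sqrt{3\mu_s'/\mu_a}\,[1 - 1/(1 + d\sqrt{3\mu_a\mu_s'})]$ for a
  homogeneous semi-infinite medium. Diffusion theory is itself only
  ~10–15% accurate near sources and boundaries, so the comparison tolerance
  is 15% and the check is made at 6–8 mm (several transport mean free
  paths): at 4 mm the zero-boundary closed form alone deviates from
  transport by ~19–29% depending on the albedo, so a comparison there would
  measure theory error, not engine error. It catches gross transport
  errors, not percent-level bias.
* `hg_mean_cos_numeric()` — quadrature of the Henyey-Greenstein density,
  checking sampled single-scattering moments.

Further always-on checks: exact energy bookkeeping; the Beer-Lambert limit
(transmitted fraction $e^{-\mu_a L}$ through a non-scattering matched slab);
DPF ≥ 1 wherever statistics exist; exact per-layer path decomposition;
the replicate spread of the mean detected pathlength growing with
separation and shrinking as $1/\sqrt{n_\text{photons}}$.

## Numerical choices and problem sizes

Stochastic test assertions use 3-standard-error bands (jointly, a
chi-square across a family of such bands); monotonicity of stochastic DPF
sequences is asserted up to 3 SE of each neighbouring difference. The test
suite runs the replication grid at $3\times10^5$ photons × 2 replicates per
wavelength and the acceptance script uses $1{-}1.5\times10^6$ photons per
target — sizes chosen so the Monte Carlo error is well inside the 15%
replication band; the `paper` preset ($10^8$ × 20 replicates) reproduces
the full production protocol when more time is available. Degenerate inputs
are defined: $\mu_s = 0$ layers propagate ballistically (and absorb wholly
at an interaction under total-rate sampling), $g = 0$ scatters
isotropically, single-replicate sweeps report zero SD and are flagged.

## Limitations

No polarization, fluorescence, time-resolved transport, curved geometry or
wavelength interpolation (the seven grid points only); one scattering
spectrum for all layers by default; the sensitivity map is the
detected-path visit histogram, not an adjoint fluence product; melanin and
baseline absorption are single-parameter conveniences. Synthetic transport
on an idealized plane-layered stack cannot capture inter-subject anatomy,
surface topography or probe-coupling effects in real skin: passing
validation here demonstrates correct transport physics on the stated model,
not clinical accuracy of any specific DPF value.
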