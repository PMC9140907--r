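---
title: "Models and methods in memscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in memscatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscatter)
```

memscatter characterizes fluid lipid bilayers containing cholesterol and
omega-3 (docosahexaenoyl, DHA) phosphocholines with three complementary
probes: neutron reflectometry (NR) of supported bilayers, small-angle neutron
scattering (SANS) of vesicle suspensions, and nitroxide spin-label EPR.
This vignette documents the models, the numerical choices, and the scope of
the synthetic-data generators that stand in for instrument data.

## Composition bookkeeping

Mixtures hold cholesterol at a fixed mole fraction of total lipids (0.4
throughout, matching its physiological plasma-membrane abundance and keeping
the mixture in a single liquid-ordered-like phase), with the phosphocholine
content split between POPC and one polyunsaturated lipid: the hybrid
18:0–22:6PC (one DHA chain) or the symmetric 22:6–22:6PC (two DHA chains).
`mixture_from_x()` converts the PUFA fraction over total PC into mole
fractions; `dha_fraction()` gives the DHA fraction over PC *tails*, which is
`x` for the symmetric lipid and `x/2` for the hybrid — the quantity on which
the two lipid classes are compared at equal DHA load.

Composite scattering length densities (SLD) use the volume-weighted mixing
rule `mix_sld()`: $\bar\rho = \sum_i f_i V_i \rho_i / \sum_i f_i V_i$.
Component SLDs and molecular volumes ship in
`inst/extdata/lipid_components.yaml`. These are literature defaults computed
from standard coherent scattering lengths and published fluid-phase volumes,
not values fitted here; every number is overridable by supplying a modified
species table. Silicon-matched water is *defined* by its D2O volume fraction
(0.38); its SLD, 2.07 × 10⁻⁶ Å⁻², is a derived check value, not a stored
constant.

## Neutron reflectometry forward model

The interface is a substrate → oxide → water gap → head slab → tail slab →
head slab → solvent stack; the two headgroup slabs are identical by
construction. Modelling proceeds in the volume-fraction domain:

1. `build_profiles()` lays down roughness-free boxes on a uniform z grid
   (0.5 Å step, margin 4× the largest roughness + 10 Å; sub-Å structure is
   far below instrument resolution). Boxes are cell-averaged
   (partial-volume) so each component's integral equals thickness ×
   occupancy exactly and the profile — and hence the reflectivity — varies
   smoothly with every thickness parameter. This smoothness matters: with
   hard 0.5 Å indicator boxes the fit Jacobian is zero almost everywhere.
2. `convolve_profiles()` smears the lipid components with a Gaussian of
   width equal to the intrinsic bilayer roughness, then every component
   (oxide and substrate included) with the substrate roughness. Kernels are
   discrete, truncated at 5σ and renormalized, so per-component volume is
   conserved to better than 1e-6; pointwise sums are renormalized to 1 to
   absorb edge truncation.
3. `profiles_to_sld()` forms ρ(z) = Σ φ_j(z) ρ_j + φ_solv(z) ρ_solv, and
   `reflectivity()` computes specular reflectivity by the Abeles/Parratt
   recursion over the micro-sliced profile (compiled kernel; leading and
   trailing constant-SLD runs are folded into the semi-infinite media, which
   changes only an overall phase).
4. Resolution smearing uses a constant fractional FWHM ΔQ/Q (default 0.1,
   the instrument wavelength spread; angular divergence is folded into the
   same number since only the wavelength spread is specified), applied by
   10-node Gauss–Hermite quadrature. In `nr_reflectivity()` the Abeles
   kernel is evaluated at the quadrature nodes directly rather than
   interpolated.

"Bilayer roughness" is the intrinsic (pre-substrate-convolution) Gaussian
width; the *global* boundary width, which adds the two convolution stages in
quadrature, is measured separately by `global_roughness()`. Because the
headgroup slab (7–13 Å) is comparable to typical total widths, the outer
head/solvent edge overlaps the tail/head edge; `global_roughness()` therefore
fits a shared-width double-erf to the solvent rise, which separates the
boundary width from the intrinsic head structure.

The area per lipid follows from the tail slab: Γ = d_tail(1 − f_solv) /
(2 V̄_tail) lipids per Å² per leaflet, with V̄_tail the mole-fraction-weighted
mean tail volume over all lipids including cholesterol; APL = 1/Γ.

## Multi-contrast co-refinement

`co_refine()` fits one structural model simultaneously to curves measured in
D2O, H2O and silicon-matched water, which differ only in solvent SLD (with
optional per-contrast scale and background, fixed at 1 and 0 by default).
The joint weighted χ² is minimized by a seeded Latin-hypercube multistart
feeding bounded Levenberg–Marquardt; a population-based global stage was
considered, but with ≤6 well-bounded parameters the multistart reaches the
same basin at a fraction of the cost. Uncertainty comes from an
affine-invariant ("stretch move") ensemble sampler run at the optimum under
uniform priors on the bounds: 95% credible intervals are the 2.5/97.5
percentiles, which accommodates the asymmetric intervals such posteriors
produce. The sampler is implemented in-package (~50 lines) and validated
against a Gaussian target in the tests. Multimodality is flagged when a
secondary histogram mode holds a substantial fraction of samples; the
reported mode is the one containing the best χ². No constraint ever imposes
the presence of a bilayer: the fitter is free to drive occupancies to zero,
and a dedicated test confirms it does so on bilayer-free data.

`sld_probability_map()` propagates posterior draws through the forward model
and histograms the SLD curves over (z, ρ) with unit column sums — the
standard visual check that the posterior concentrates on a supported-bilayer
profile (a deep well in the 30–40 Å tail region under D2O).

## SANS: lamellar-stack paracrystal

Vesicle suspensions are modelled in absolute units as
$I(q) = s\,\Delta\rho^2\, P_{\rm slab}(q)\, Z_N(q)/q^2 + b$,
with $P_{\rm slab}$ the uniform-slab lamellar form factor averaged over a
truncated Gaussian thickness distribution (15-node Gauss–Hermite, clipped at
positive thickness) and the finite-stack ideal paracrystal factor

$$Z_N(q) = 1 + \frac{2}{N}\sum_{k=1}^{N-1}(N-k)\cos(kqD)
\exp\!\left(-\tfrac{1}{2}k q^2 D^2 (\sigma_D/D)^2\right),$$

i.e. Gaussian cumulative spacing disorder; `Z_N(0) = N` and large disorder
collapses `Z_N → 1`. Non-integer mean stack sizes are handled by linear
interpolation between the two neighbouring integer evaluations, which is
continuous across integer boundaries. The factor is validated against a
Monte-Carlo lattice-sum oracle in the tests. No inter-aggregate structure
factor is applied. Published disorder values σ_D/⟨D⟩ above 1 are stored
verbatim as the model's dimensionless disorder parameter; at such values the
Bragg peak is fully washed out (no peak appears in the generated curves,
matching the measured profiles) and recovery claims rest on thickness and
stack size only. The thickness polydispersity column is treated as fixed,
not fitted. The absolute scale absorbs the unknown vesicle number density.

`fit_sans()` is bounded weighted least squares with seeded restarts; 1σ
uncertainties come from a forward-difference Jacobian at the optimum.
`power_law_slope()` regresses log I on log q after background subtraction;
thin-lamella curves show the characteristic exponent slightly above 2 at
intermediate q.

## EPR: fast-motion MOMD surrogate

Reference analyses of such spectra use a slow-motional stochastic-Liouville
solver. memscatter deliberately implements a lighter, fully documented
surrogate valid in the sub-ns to few-ns correlation-time regime the probes
report: partial tensor averaging under the order parameter S,

$$A'_\parallel = \langle A\rangle + \tfrac{2}{3}S\,\Delta A,\qquad
A'_\perp = \langle A\rangle - \tfrac{1}{3}S\,\Delta A,$$

(same form for g; the trace is conserved exactly), Redfield-type fast-motion
linewidths Γ(m) = A + Bm + Cm² with the motional terms scaled by (1 − S²)
(only the averaged-out anisotropy fluctuates) and an effective correlation
time combining the fixed parallel time (13.2 ns) and the fitted
perpendicular time through the 70° diffusion tilt,
$1/\tau_{\rm eff} = \cos^2\alpha/\tau_\parallel + \sin^2\alpha/\tau_\perp$.
This combination rule is a documented choice of the surrogate, validated
against its own oracle (exact linearity of B and C in τ_eff), not a claim
about the reference solver. MOMD powder averaging sums the three ¹⁴N lines
over 64 Gauss–Legendre director angles with sin θ weighting (doubling the
nodes changes the spectrum by <0.1% of peak); lines are pseudo-Voigt with
Gaussian fraction 0.3 standing in for unresolved proton hyperfine structure;
spectra are differentiated numerically and normalized to unit double
integral. Consequently the package's acceptance standard for EPR is
*parameter recovery on self-generated data*, not reproduction of published
S/τ values from unavailable raw spectra.

Probe tensors follow the fixed-parameter scheme (g and A constant per probe
across compositions; the listed PCSL g-component "2006" is read as 2.006).
The 5-PCSL tensor's trace mean is 14.63 G while 14.7 G is reported next to
it; the package computes and uses the trace mean and keeps the discrepancy
visible (`probe_defaults()$a_iso_reported`) rather than silently matching.
`fit_spectrum()` frees only S and τ_perp (amplitude and baseline are
analytic nuisance parameters) from five deterministic starts, mirroring the
strategy of fixing all but the informative parameters.

## Synthetic data: what it does and does not emulate

The generators reproduce the statistical structure the fits assume — exact
forward-model curves plus Gaussian noise at stated levels (NR 2% relative
with a 1e-8 floor; SANS 1% relative; EPR 1% of peak-to-peak; instrument
noise levels are not published, so these are stated assumptions chosen so
that uncertainties of the published order are achievable), on the measured
axes (NR: 75 log-spaced points over Q = 0.005–0.20 Å⁻¹ per contrast; SANS:
120 log-spaced points over 0.0023–0.45 Å⁻¹; EPR: 100 G sweep, 1024 points,
9.4 GHz). Generating truths are the published parameter rows; for NR the
tail solvent fraction is derived from the published area per lipid,
f = 1 − 2V̄/(d·APL). For the x = 0.8 symmetric-lipid row this expression is
negative with the configured volumes (the printed thickness × APL product is
smaller than twice the mean tail volume), so the generator clamps f at 0;
recovery claims for that row concern the tail thickness only. Unpublished
instrument-side quantities (oxide thickness 12 Å, substrate roughness 3 Å,
water gap 4 Å, head hydration 0.35) are fixed plausible values shared
between generator and fit.

Passing recovery tests therefore shows that the estimators are unbiased and
well-calibrated *under the assumed noise model*; they do not exercise
reduction artifacts, backgrounds, detector geometry, multiple scattering, or
model misspecification against real membranes.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed (default 20220510) and is
deterministic given it. The test suite and the acceptance script use
20 seeded repeats for NR recovery (four free parameters per fit, two
multistarts), single fits per SANS row, and a 9 × 4 (S, τ) EPR recovery
grid — sizes chosen to make the statistical claims while keeping a full run
in minutes on one core. Credible-interval MCMC defaults (16 walkers,
400 steps, half burn-in) suit the low-dimensional bounded posteriors here;
the walker count must exceed 2d + 2.

## Known limitations

- The EPR surrogate degrades outside the fast-motion window (τ_eff beyond a
  few ns at 9 GHz); `fast_motion_linewidths()` warns outside 1 ps–50 ns.
- The paracrystal disorder parameter is not identifiable from curves without
  a Bragg peak; only thickness and stack size are quantitative there.
- `co_refine()` assumes independent Gaussian uncertainties supplied with the
  data; correlated systematics are not modelled.
- Area per lipid inherits the configured molecular volumes; changing the
  component table rescales it proportionally.
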