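# memscatter

Structural analysis of cholesterol/omega-3 phospholipid bilayers from
neutron scattering and spin-label EPR.

Fluid membranes mixing cholesterol (ordering) with polyunsaturated
docosahexaenoyl (DHA) phosphocholines (disordering) are characterized by
three complementary techniques, and this package implements the inference
machinery for all three:

- **Neutron reflectometry (NR)** of supported bilayers: a volume-fraction
  slab model (substrate / oxide / water gap / head–tail–head / solvent) with
  two-stage Gaussian roughness convolution, translated to an SLD profile
  ρ(z) = Σ φ_j(z) ρ_j and to reflectivity R(Q) by the Abeles/Parratt
  recursion with ΔQ/Q resolution smearing. One structural model is
  co-refined against D2O, H2O and silicon-matched-water contrasts, with 95%
  credible intervals from an affine-invariant ensemble sampler, posterior
  SLD probability maps, and derived quantities — area per lipid
  APL = 2·V̄_tail / (d_tail·(1 − f_solv)) and global boundary roughness.
- **SANS** of vesicle suspensions: a lamellar-stack paracrystal model in
  absolute units, I(q) = s·Δρ²·P_slab(q)·Z_N(q)/q² + b, where
  Z_N(q) = 1 + (2/N)·Σ_k (N−k)·cos(kqD)·exp(−k q²D²(σ_D/D)²/2) is the
  finite-stack factor with Gaussian spacing disorder, with thickness
  polydispersity, weighted least-squares fitting and power-law slope
  diagnostics.
- **Nitroxide EPR** (9 GHz, first derivative): partial tensor averaging
  under an order parameter S (A′∥ = ⟨A⟩ + ⅔SΔA, trace-conserving),
  Redfield-type fast-motion linewidths Γ(m) = A + Bm + Cm², MOMD powder
  averaging over director angles, and least-squares recovery of S and τ⊥
  with the per-probe tensors, τ∥ = 13.2 ns and 70° diffusion tilt fixed.

A composition module handles the mixture algebra (cholesterol fixed at 0.4
of total lipids; x_DHA = x for the symmetric 22:6–22:6PC and x/2 for the
hybrid 18:0–22:6PC) and volume-weighted SLD mixing, and a seeded
synthetic-data module generates NR/SANS/EPR data with the study's noise
structure so every fit is testable without instrument files. See the
methods vignette (`vignettes/memscatter-methods.Rmd`) for models,
assumptions and numerical choices.

## Worked example

Recover the chol/POPC bilayer structure from synthetic three-contrast
reflectivity (2% noise):

```r
library(memscatter)

tm <- nr_truth_model("chol/POPC")          # generating truth + composition
curves <- gen_nr(tm$model, seed = 42, noise = 0.02)

free <- data.frame(
  name  = c("head_thickness", "tail_thickness",
            "bilayer_roughness", "tail_solvent_fraction"),
  lower = c(3, 10, 0.05, 0), upper = c(20, 60, 12, 0.6),
  init  = c(9, 30, 2, 0.1))
spec <- fit_spec(tm$model, free,
                 lapply(names(curves), function(nm)
                   list(solvent = solvent_contrast(nm),
                        curve = curves[[nm]])))
fit <- co_refine(spec, seed = 42, n_starts = 2,
                 mcmc = list(n_walkers = 12, n_steps = 150))
fit
#> Multi-contrast reflectometry co-refinement
#>                          best   lower   upper
#> head_thickness         7.2247  7.1577  7.3161
#> tail_thickness        35.7391 35.5988 35.8446
#> bilayer_roughness      2.8925  2.8114  2.9981
#> tail_solvent_fraction  0.0048  0.0028  0.0062
#> chi2 = 212.9 over 225 points (per contrast: 86.5, 60.6, 65.9)

round(area_per_lipid(fit$model, tm$mix), 1)
#> [1] 45.1
```

The fitted slab parameters sit on the generating truth (head 7.2 Å, tail
35.8 Å, roughness 2.9 Å) with χ² ≈ the number of points, and the derived
area per lipid reproduces the tightly packed 45 Å² characteristic of a
40 mol% cholesterol bilayer. `sld_probability_map(fit)` shows the posterior
concentrating on a profile with the deep tail-region well of a supported
bilayer, and `run_pipeline()` chains the EPR → SANS → NR stages for any of
the study compositions.

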