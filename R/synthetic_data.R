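# Seeded synthetic-data generators emulating the study conditions for all
# three techniques, plus the published parameter tables used as generating
# truths.

#' Study lipid compositions
#'
#' The thirteen investigated mixtures: fixed cholesterol fraction 0.4 of
#' total lipids, with the phosphocholine content split between POPC and one
#' omega-3 lipid over the full `x_pufa` range for both the symmetric and the
#' hybrid lipid.
#'
#' @return Data frame with `system`, `pufa_kind`, `x_pufa`, and the mole
#'   fractions `cholesterol`, `POPC`, `sym_22_6`, `hyb_18_0_22_6`, `x_dha`.
#' @export
study_compositions <- function() {
  xs <- c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1)
  rows <- list()
  for (kind in c("symmetric", "hybrid")) {
    for (x in xs) {
      if (x == 0 && kind == "hybrid") next  # chol/POPC listed once
      m <- mixture_from_x(x, kind, 0.4)
      rows[[length(rows) + 1]] <- data.frame(
        system = {
          lip <- if (kind == "hybrid") "18:0-22:6PC" else "22:6-22:6PC"
          if (x == 0) "chol/POPC"
          else if (x == 1) paste0("chol/", lip)   # POPC-free endpoints
          else sprintf("chol/POPC/%s x=%g", lip, x)
        },
        pufa_kind = kind, x_pufa = x,
        cholesterol = m$fractions[["cholesterol"]],
        POPC = m$fractions[["POPC"]],
        sym_22_6 = if (kind == "symmetric") m$fractions[["22:6-22:6PC"]] else 0,
        hyb_18_0_22_6 = if (kind == "hybrid") m$fractions[["18:0-22:6PC"]] else 0,
        x_dha = m$x_dha)
    }
  }
  do.call(rbind, rows)
}

#' Published SANS paracrystal parameter sets
#'
#' The three fitted lamellar-stack parameter rows (chol/POPC and the
#' symmetric-lipid mixtures at x = 0.2 and 0.8) used as generating truths.
#'
#' @return Data frame with `system`, `thickness`, `n_layers`, `d_spacing`,
#'   `sigma_d_rel`, `poly_thickness`.
#' @export
sans_truth_table <- function() {
  data.frame(
    system = c("chol/POPC", "chol/POPC/22:6-22:6PC x=0.2",
               "chol/POPC/22:6-22:6PC x=0.8"),
    thickness = c(38.09, 38.67, 34.60),
    n_layers = c(4.424, 3.801, 2.698),
    d_spacing = c(105.14, 94.73, 110.1),
    sigma_d_rel = c(1.311, 1.801, 1.877),
    poly_thickness = c(0.05, 0.1, 0.05))
}

#' Published reflectometry structural parameter sets
#'
#' The five co-refined supported-bilayer rows: best-fit headgroup thickness,
#' tail thickness and bilayer roughness with their 95% intervals, and the
#' derived area per lipid.
#'
#' @return Data frame, one row per system.
#' @export
nr_truth_table <- function() {
  data.frame(
    system = c("chol/POPC", "chol/POPC/22:6-22:6PC x=0.2",
               "chol/POPC/22:6-22:6PC x=0.8",
               "chol/POPC/18:0-22:6PC x=0.4", "chol/18:0-22:6PC"),
    pufa_kind = c("symmetric", "symmetric", "symmetric", "hybrid", "hybrid"),
    x_pufa = c(0, 0.2, 0.8, 0.4, 1),
    head_thickness = c(7.2, 8.5, 13.0, 12.4, 7.8),
    head_lo = c(6.8, 7.7, 13.0, 11.3, 7.1),
    head_hi = c(8.1, 9.3, 13.0, 12.5, 8.7),
    tail_thickness = c(35.8, 27.2, 23.3, 30.6, 29.1),
    tail_lo = c(33.6, 25.9, 22.7, 29.1, 28.5),
    tail_hi = c(37.8, 30.5, 25.5, 32.4, 29.8),
    bilayer_roughness = c(2.9, 0.7, 8.7, 3.4, 3.0),
    rough_lo = c(2.4, 0.6, 7.2, 2.8, 2.5),
    rough_hi = c(5.6, 3.0, 9.2, 4.5, 3.6),
    area_per_lipid = c(45, 84, 60, 77, 61),
    apl_err = c(1, 3, 4, 3, 1))
}

#' Generating-truth interface model for a study system
#'
#' Builds the supported-bilayer model for a [nr_truth_table()] row: slab
#' thicknesses and roughness from the published best fit, head/tail SLDs from
#' volume-weighted mixing of the component table (reflectometry samples use
#' d31-POPC), and the tail solvent fraction derived from the published area
#' per lipid via `f = 1 - 2 Vbar_tail / (d_tail * APL)` (clamped at 0 where
#' the printed geometry implies full occupancy).
#'
#' @param system Row name from [nr_truth_table()].
#' @param solvent A [solvent_contrast()].
#' @param head_solvent_fraction Headgroup hydration (default 0.35).
#' @param components Component table from [load_components()].
#' @return List with `model` (an [interface_model()]) and `mix` (the
#'   `mixture_composition`).
#' @export
nr_truth_model <- function(system = "chol/POPC",
                           solvent = solvent_contrast("D2O"),
                           head_solvent_fraction = 0.35,
                           components = load_components()) {
  tab <- nr_truth_table()
  row <- tab[tab$system == system, ]
  if (nrow(row) != 1) stop("unknown system: ", system, call. = FALSE)
  mix <- mixture_from_x(row$x_pufa, row$pufa_kind, 0.4, popc_name = "d31-POPC")
  slabs <- mixture_slabs(mix, components$species)
  f_tail <- max(0, 1 - 2 * slabs$tail_volume /
                  (row$tail_thickness * row$area_per_lipid))
  model <- interface_model(
    head_thickness = row$head_thickness, tail_thickness = row$tail_thickness,
    head_sld = slabs$head_sld, tail_sld = slabs$tail_sld,
    head_solvent_fraction = head_solvent_fraction,
    tail_solvent_fraction = f_tail,
    bilayer_roughness = row$bilayer_roughness, substrate_roughness = 3,
    water_gap = 4, oxide_thickness = 12,
    oxide_sld = components$substrate$oxide_sld,
    substrate_sld = components$substrate$silicon_sld,
    solvent = solvent)
  list(model = model, mix = mix)
}

#' Generate three-contrast synthetic reflectivity curves
#'
#' Runs the forward model for each solvent contrast, applies resolution
#' smearing and relative Gaussian noise with an absolute floor, and populates
#' the uncertainty column. Fixed seed gives byte-identical output; changing
#' only the seed changes only the noise realization.
#'
#' @param truth An [interface_model()] (its solvent slot is replaced per
#'   contrast).
#' @param seed Integer seed.
#' @param noise Relative 1-sigma noise (default 0.02).
#' @param q Q grid (A^-1); default 75 log-spaced points over 0.005-0.20.
#' @param contrasts Solvent names to generate.
#' @param dq_over_q Fractional FWHM resolution (default 0.1).
#' @param floor Absolute uncertainty floor (default 1e-8).
#' @return Named list of `scattering_curve` objects, one per contrast.
#' @export
gen_nr <- function(truth, seed = 1, noise = 0.02,
                   q = exp(seq(log(0.005), log(0.20), length.out = 75)),
                   contrasts = c("D2O", "H2O", "SiMW"), dq_over_q = 0.1,
                   floor = 1e-8) {
  stopifnot(inherits(truth, "interface_model"))
  set.seed(seed)
  out <- list()
  for (nm in contrasts) {
    m <- truth
    m$solvent <- solvent_contrast(nm)
    r <- nr_reflectivity(m, q, dq_over_q)
    dy <- pmax(noise * r, floor)
    out[[nm]] <- scattering_curve(q, r + dy * rnorm(length(q)), dy,
                                  dq = dq_over_q * q)
  }
  out
}

#' Generate a synthetic SANS curve
#'
#' Paracrystal model intensity over the measured Q range with relative
#' Gaussian noise.
#'
#' @param truth A [paracrystal_params()].
#' @param seed Integer seed.
#' @param noise Relative 1-sigma noise (default 0.01).
#' @param q Q grid; default 120 log-spaced points over 0.0023-0.45 A^-1.
#' @return A `scattering_curve`.
#' @export
gen_sans <- function(truth, seed = 1, noise = 0.01,
                     q = exp(seq(log(0.0023), log(0.45), length.out = 120))) {
  stopifnot(inherits(truth, "paracrystal_params"))
  set.seed(seed)
  i <- paracrystal_intensity(truth, q)
  dy <- pmax(noise * i, 1e-12)
  scattering_curve(q, i + dy * rnorm(length(q)), dy)
}

#' Generate a synthetic EPR spectrum
#'
#' Simulates the first-derivative MOMD spectrum of the truth model and adds
#' Gaussian noise scaled to the peak-to-peak amplitude.
#'
#' @param truth A `spin_probe_model`.
#' @param seed Integer seed.
#' @param noise Noise 1-sigma as a fraction of the peak-to-peak amplitude
#'   (default 0.01).
#' @param grid An [epr_grid()].
#' @return An `epr_spectrum` with a `truth_intensity` attribute.
#' @export
gen_epr <- function(truth, seed = 1, noise = 0.01, grid = epr_grid()) {
  stopifnot(inherits(truth, "spin_probe_model"))
  set.seed(seed)
  s <- simulate_spectrum(truth, grid)
  ptp <- diff(range(s$intensity))
  out <- s
  out$intensity <- s$intensity + noise * ptp * rnorm(length(s$intensity))
  attr(out, "truth_intensity") <- s$intensity
  out
}
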