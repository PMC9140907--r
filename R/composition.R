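# Lipid-mixture bookkeeping: mole-fraction algebra, DHA-fraction conversion,
# and volume-weighted SLD mixing for headgroups, tails, and solvent contrasts.

#' Define a lipid species
#'
#' A lipid species carries the neutron scattering length densities (SLD) and
#' molecular volumes of its headgroup and tail regions, plus tail bookkeeping
#' used to convert between polyunsaturated-lipid and DHA mole fractions.
#'
#' @param name Species identifier, e.g. `"POPC"`.
#' @param head_sld,tail_sld Headgroup/tail SLD in 10^-6 A^-2.
#' @param head_volume,tail_volume Molecular volumes in A^3 (must be > 0).
#' @param n_pc_tails Number of glycerophospholipid acyl chains (0 for sterols).
#' @param n_dha_tails Number of those chains that are docosahexaenoyl (22:6).
#' @return A `lipid_species` object (named list).
#' @export
lipid_species <- function(name, head_sld, tail_sld, head_volume, tail_volume,
                          n_pc_tails = 2L, n_dha_tails = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(head_volume > 0 && tail_volume > 0))
    stop("molecular volumes must be positive", call. = FALSE)
  if (!(n_dha_tails >= 0 && n_dha_tails <= n_pc_tails && n_pc_tails <= 2))
    stop("need 0 <= n_dha_tails <= n_pc_tails <= 2", call. = FALSE)
  structure(list(name = name, head_sld = head_sld, tail_sld = tail_sld,
                 head_volume = head_volume, tail_volume = tail_volume,
                 n_pc_tails = as.integer(n_pc_tails),
                 n_dha_tails = as.integer(n_dha_tails)),
            class = "lipid_species")
}

#' Load the component table shipped with the package
#'
#' Reads the species/solvent configuration (a YAML file of literature default
#' SLDs and molecular volumes; all values overridable) and returns the species
#' as a named list of [lipid_species()] objects together with solvent and
#' substrate constants.
#'
#' @param path Path to a components YAML file; defaults to the bundled one.
#' @return A list with elements `species`, `solvents`, `substrate`.
#' @export
load_components <- function(path = system.file("extdata", "lipid_components.yaml",
                                               package = "memscatter")) {
  cfg <- yaml::read_yaml(path)
  species <- lapply(names(cfg$species), function(nm) {
    s <- cfg$species[[nm]]
    lipid_species(nm, s$head_sld, s$tail_sld, s$head_volume, s$tail_volume,
                  s$n_pc_tails, s$n_dha_tails)
  })
  names(species) <- names(cfg$species)
  list(species = species, solvents = cfg$solvents, substrate = cfg$substrate)
}

#' Construct a ternary chol/POPC/PUFA-PC mixture from the PUFA fraction
#'
#' Mixtures hold a fixed cholesterol mole fraction of total lipids (0.4 in all
#' study compositions) with the phosphocholine content split between POPC and
#' one polyunsaturated lipid: the hybrid 18:0-22:6PC (one DHA chain) or the
#' symmetric 22:6-22:6PC (two DHA chains). `x_pufa` is the PUFA mole fraction
#' over total PC.
#'
#' @param x_pufa PUFA lipid mole fraction over total phosphocholine, in \[0,1\].
#' @param pufa_kind `"hybrid"` (18:0-22:6PC) or `"symmetric"` (22:6-22:6PC).
#' @param chol_fraction Cholesterol mole fraction of total lipids, in \[0,1).
#' @param popc_name Name used for the POPC species (e.g. `"d31-POPC"` for
#'   reflectometry samples with a deuterated palmitoyl chain).
#' @return A `mixture_composition`: named fractions over total lipids (summing
#'   to 1), `chol_fraction`, `x_pufa`, `pufa_kind`, and `x_dha` (DHA mole
#'   fraction over total PC tails).
#' @export
mixture_from_x <- function(x_pufa, pufa_kind = c("hybrid", "symmetric"),
                           chol_fraction = 0.4, popc_name = "POPC") {
  pufa_kind <- match.arg(pufa_kind)
  if (!(x_pufa >= 0 && x_pufa <= 1))
    stop("x_pufa must lie in [0, 1]", call. = FALSE)
  if (!(chol_fraction >= 0 && chol_fraction < 1))
    stop("chol_fraction must lie in [0, 1)", call. = FALSE)
  pufa_name <- if (pufa_kind == "hybrid") "18:0-22:6PC" else "22:6-22:6PC"
  fr <- c(chol_fraction,
          (1 - chol_fraction) * (1 - x_pufa),
          (1 - chol_fraction) * x_pufa)
  names(fr) <- c("cholesterol", popc_name, pufa_name)
  structure(list(fractions = fr, chol_fraction = chol_fraction,
                 x_pufa = x_pufa, pufa_kind = pufa_kind,
                 x_dha = if (pufa_kind == "hybrid") x_pufa / 2 else x_pufa),
            class = "mixture_composition")
}

#' @export
print.mixture_composition <- function(x, ...) {
  cat("Lipid mixture (mole fractions of total lipids):\n")
  print(round(x$fractions, 4))
  cat(sprintf("x_%s = %.3g, x_DHA = %.3g\n",
              if (x$pufa_kind == "hybrid") "18:0-22:6PC" else "22:6-22:6PC",
              x$x_pufa, x$x_dha))
  invisible(x)
}

#' DHA mole fraction over total phosphocholine tails
#'
#' Converts the PUFA-lipid fraction into the DHA fraction over PC tails:
#' equal to `x_pufa` for the symmetric di-DHA lipid and `x_pufa/2` for the
#' hybrid lipid (one DHA chain out of two).
#'
#' @param mix A `mixture_composition`.
#' @return DHA mole fraction over PC tails.
#' @export
dha_fraction <- function(mix) {
  stopifnot(inherits(mix, "mixture_composition"))
  mix$x_dha
}

#' Volume-weighted SLD of a mixture of components
#'
#' Mixing rule for composite scattering length densities: the SLD of a mixture
#' is the volume-weighted mean `sum(f V rho) / sum(f V)` over components with
#' mole fractions `f`, molecular volumes `V` and SLDs `rho`. For equal volumes
#' this reduces to the mole-fraction-weighted mean.
#'
#' @param sld SLD of each component (10^-6 A^-2).
#' @param volume Molecular volume of each component (A^3, > 0).
#' @param fraction Mole fraction of each component (must sum to 1).
#' @return Mixture SLD in 10^-6 A^-2.
#' @export
mix_sld <- function(sld, volume, fraction) {
  n <- length(sld)
  if (n == 0L) stop("empty component list", call. = FALSE)
  stopifnot(length(volume) == n, length(fraction) == n)
  if (any(volume <= 0)) stop("volumes must be positive", call. = FALSE)
  if (abs(sum(fraction) - 1) > 1e-9)
    stop("mole fractions must sum to 1", call. = FALSE)
  sum(fraction * volume * sld) / sum(fraction * volume)
}

#' Define a solvent contrast
#'
#' Named contrasts are D2O, H2O and SiMW (silicon-matched water, a 38/62 vol%
#' D2O/H2O mixture whose SLD equals that of bulk silicon). A mixture's SLD is
#' the volume-weighted mean of the endmember SLDs.
#'
#' @param name `"D2O"`, `"H2O"`, `"SiMW"`, or `"custom"`.
#' @param d2o_volume_fraction D2O volume fraction in \[0,1\]; ignored for the
#'   named pure solvents, required for `"custom"`.
#' @param d2o_sld,h2o_sld Endmember SLDs (10^-6 A^-2).
#' @return A `solvent_contrast` with fields `name`, `sld`,
#'   `d2o_volume_fraction`.
#' @export
solvent_contrast <- function(name = c("D2O", "H2O", "SiMW", "custom"),
                             d2o_volume_fraction = NULL,
                             d2o_sld = 6.35, h2o_sld = -0.56) {
  name <- match.arg(name)
  frac <- switch(name, D2O = 1, H2O = 0, SiMW = 0.38, custom = d2o_volume_fraction)
  if (is.null(frac) || !(frac >= 0 && frac <= 1))
    stop("d2o_volume_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(name = name,
                 sld = frac * d2o_sld + (1 - frac) * h2o_sld,
                 d2o_volume_fraction = frac),
            class = "solvent_contrast")
}

#' Mixture-average tail/head SLDs and volumes
#'
#' Applies the volume-weighted mixing rule to a mixture's species to obtain
#' the effective tail and headgroup SLD and mean molecular volumes used by the
#' reflectometry slab model.
#'
#' @param mix A `mixture_composition`.
#' @param species Named list of [lipid_species()]; defaults to the bundled
#'   component table.
#' @return List with `tail_sld`, `head_sld`, `tail_volume`, `head_volume`
#'   (mole-fraction-weighted mean volumes) for the mixture.
#' @export
mixture_slabs <- function(mix, species = load_components()$species) {
  sp <- species[names(mix$fractions)]
  if (any(vapply(sp, is.null, logical(1))))
    stop("unknown species in mixture: ",
         paste(setdiff(names(mix$fractions), names(species)), collapse = ", "),
         call. = FALSE)
  f <- unname(mix$fractions)
  tv <- vapply(sp, `[[`, numeric(1), "tail_volume")
  hv <- vapply(sp, `[[`, numeric(1), "head_volume")
  list(tail_sld = mix_sld(vapply(sp, `[[`, numeric(1), "tail_sld"), tv, f),
       head_sld = mix_sld(vapply(sp, `[[`, numeric(1), "head_sld"), hv, f),
       tail_volume = sum(f * tv),
       head_volume = sum(f * hv))
}
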