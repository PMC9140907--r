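# Supported-bilayer neutron reflectometry forward model: roughness-free
# volume-fraction profiles, two-stage Gaussian convolution, SLD profile,
# Abeles/Parratt reflectivity with resolution smearing, and derived
# quantities (area per lipid, global roughness).

#' Define a supported-bilayer interface model
#'
#' The interface stack runs substrate -> oxide -> water gap -> headgroup slab
#' -> tail slab -> headgroup slab -> bulk solvent. The two headgroup slabs are
#' identical by construction. The coordinate z increases from the substrate
#' into the solvent with z = 0 at the oxide/water-gap boundary.
#'
#' @param head_thickness,tail_thickness Slab thicknesses (A).
#' @param head_sld,tail_sld Slab SLDs (10^-6 A^-2) of the dry lipid matter.
#' @param head_solvent_fraction,tail_solvent_fraction Solvent volume fraction
#'   inside each slab, in \[0,1\].
#' @param bilayer_roughness Intrinsic Gaussian roughness (A) applied to the
#'   lipid/water components.
#' @param substrate_roughness Gaussian roughness (A) applied to the whole
#'   stack in a second convolution.
#' @param water_gap Thin water layer between oxide and bilayer (A).
#' @param oxide_thickness,oxide_sld Native oxide layer parameters.
#' @param substrate_sld Bulk substrate SLD (silicon: 2.07).
#' @param solvent A [solvent_contrast()].
#' @return An `interface_model` object.
#' @export
interface_model <- function(head_thickness, tail_thickness,
                            head_sld, tail_sld,
                            head_solvent_fraction = 0.3,
                            tail_solvent_fraction = 0.0,
                            bilayer_roughness = 3,
                            substrate_roughness = 3,
                            water_gap = 4,
                            oxide_thickness = 12, oxide_sld = 3.47,
                            substrate_sld = 2.07,
                            solvent = solvent_contrast("D2O")) {
  th <- c(head_thickness, tail_thickness, water_gap, oxide_thickness)
  if (any(!is.finite(th)) || any(th < 0))
    stop("thicknesses must be finite and >= 0", call. = FALSE)
  sf <- c(head_solvent_fraction, tail_solvent_fraction)
  if (any(sf < 0 | sf > 1))
    stop("solvent fractions must lie in [0, 1]", call. = FALSE)
  if (bilayer_roughness < 0 || substrate_roughness < 0)
    stop("roughnesses must be >= 0", call. = FALSE)
  stopifnot(inherits(solvent, "solvent_contrast"))
  structure(list(head_thickness = head_thickness,
                 tail_thickness = tail_thickness,
                 head_sld = head_sld, tail_sld = tail_sld,
                 head_solvent_fraction = head_solvent_fraction,
                 tail_solvent_fraction = tail_solvent_fraction,
                 bilayer_roughness = bilayer_roughness,
                 substrate_roughness = substrate_roughness,
                 water_gap = water_gap,
                 oxide_thickness = oxide_thickness, oxide_sld = oxide_sld,
                 substrate_sld = substrate_sld, solvent = solvent),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  cat("Supported-bilayer interface model (z = 0 at oxide/water boundary)\n")
  cat(sprintf("  oxide: %.1f A (SLD %.2f); water gap: %.1f A\n",
              x$oxide_thickness, x$oxide_sld, x$water_gap))
  cat(sprintf("  heads: %.1f A each (SLD %.2f, solvent %.2f)\n",
              x$head_thickness, x$head_sld, x$head_solvent_fraction))
  cat(sprintf("  tails: %.1f A (SLD %.2f, solvent %.2f)\n",
              x$tail_thickness, x$tail_sld, x$tail_solvent_fraction))
  cat(sprintf("  roughness: bilayer %.1f A, substrate %.1f A; solvent %s (SLD %.2f)\n",
              x$bilayer_roughness, x$substrate_roughness,
              x$solvent$name, x$solvent$sld))
  invisible(x)
}

#' Roughness-free volume fraction profiles of an interface model
#'
#' Generates box profiles for the substrate, oxide, headgroups (two identical
#' boxes, one component) and tails on a uniform z grid; solvent fills the
#' remainder (including the water gap), so the fractions sum to 1 everywhere.
#'
#' @param model An [interface_model()].
#' @param grid_step z-grid spacing in A (default 0.5).
#' @param margin Extra grid extension beyond the stack on each side; defaults
#'   to 4x the largest roughness plus 10 A.
#' @return A `volume_fraction_profile`: list with `z`, `step` and `phi`, a
#'   named list of component arrays (`substrate`, `oxide`, `head`, `tail`,
#'   `solvent`).
#' @export
build_profiles <- function(model, grid_step = 0.5, margin = NULL) {
  m <- model
  if (is.null(margin))
    margin <- 4 * max(m$bilayer_roughness, m$substrate_roughness) + 10
  z0 <- -m$oxide_thickness - margin
  z1 <- m$water_gap + 2 * m$head_thickness + m$tail_thickness + margin
  z <- seq(z0, z1, by = grid_step)
  # partial-volume boxes: each cell holds the fraction of [z-h/2, z+h/2]
  # inside [a, b], so integrals are exact and the profile varies smoothly
  # with slab thicknesses (not just in 1-cell jumps)
  h <- grid_step
  box <- function(a, b) {
    if (b <= a) return(numeric(length(z)))
    pmax(0, pmin(z + h / 2, b) - pmax(z - h / 2, a)) / h
  }
  phi <- list(
    substrate = pmax(0, pmin((-m$oxide_thickness - (z - h / 2)) / h, 1)),
    oxide     = box(-m$oxide_thickness, 0),
    head      = (1 - m$head_solvent_fraction) *
                (box(m$water_gap, m$water_gap + m$head_thickness) +
                 box(m$water_gap + m$head_thickness + m$tail_thickness,
                     m$water_gap + 2 * m$head_thickness + m$tail_thickness)),
    tail      = (1 - m$tail_solvent_fraction) *
                box(m$water_gap + m$head_thickness,
                    m$water_gap + m$head_thickness + m$tail_thickness))
  phi$solvent <- pmax(0, 1 - Reduce(`+`, phi))
  structure(list(z = z, step = grid_step, phi = phi),
            class = "volume_fraction_profile")
}

# Discrete Gaussian smoothing on a uniform grid; kernel truncated at 5 sigma
# and renormalized so per-component integrals are conserved. Edges are padded
# by replication (profiles are constant at both ends given adequate margin).
gauss_smooth <- function(x, sigma, step) {
  if (sigma <= 0) return(x)
  h <- max(1L, ceiling(5 * sigma / step))
  k <- dnorm(seq(-h, h) * step, sd = sigma)
  k <- k / sum(k)
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, k, sides = 2))[(h + 1):(h + length(x))]
}

#' Two-stage Gaussian convolution of volume fraction profiles
#'
#' First the lipid components (heads, tails) are convolved with a Gaussian of
#' width equal to the intrinsic bilayer roughness; then every component,
#' including the oxide and substrate, is convolved with a Gaussian of width
#' equal to the substrate roughness. Per-component integrals are conserved;
#' the solvent is recomputed as the residual and pointwise sums renormalized
#' to 1 to absorb edge truncation.
#'
#' @param p A `volume_fraction_profile` from [build_profiles()].
#' @param bilayer_roughness,substrate_roughness Gaussian widths in A (>= 0).
#' @return A convolved `volume_fraction_profile`.
#' @export
convolve_profiles <- function(p, bilayer_roughness, substrate_roughness) {
  stopifnot(inherits(p, "volume_fraction_profile"))
  if (bilayer_roughness < 0 || substrate_roughness < 0)
    stop("roughnesses must be >= 0", call. = FALSE)
  phi <- p$phi
  for (comp in c("head", "tail"))
    phi[[comp]] <- gauss_smooth(phi[[comp]], bilayer_roughness, p$step)
  for (comp in c("substrate", "oxide", "head", "tail"))
    phi[[comp]] <- gauss_smooth(phi[[comp]], substrate_roughness, p$step)
  tot <- phi$substrate + phi$oxide + phi$head + phi$tail
  excess <- pmax(tot, 1)
  for (comp in c("substrate", "oxide", "head", "tail"))
    phi[[comp]] <- phi[[comp]] / excess
  phi$solvent <- pmax(0, 1 - tot / excess)
  structure(list(z = p$z, step = p$step, phi = phi),
            class = "volume_fraction_profile")
}

#' Translate volume fraction profiles to an SLD profile
#'
#' `rho(z) = sum_j phi_j(z) rho_j + phi_solvent(z) rho_solvent`.
#'
#' @param p A `volume_fraction_profile`.
#' @param slds Named SLD for every non-solvent component in `p$phi`
#'   (10^-6 A^-2).
#' @param solvent_sld Solvent SLD (10^-6 A^-2).
#' @return An `sld_profile`: list with `z`, `step`, `rho`.
#' @export
profiles_to_sld <- function(p, slds, solvent_sld) {
  stopifnot(inherits(p, "volume_fraction_profile"))
  comps <- setdiff(names(p$phi), "solvent")
  missing <- setdiff(comps, names(slds))
  if (length(missing))
    stop("missing SLD for component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rho <- p$phi$solvent * solvent_sld
  for (comp in comps) rho <- rho + p$phi[[comp]] * slds[[comp]]
  structure(list(z = p$z, step = p$step, rho = rho), class = "sld_profile")
}

#' Specular reflectivity of an SLD profile
#'
#' Abeles/Parratt transfer-matrix reflectivity of the micro-sliced profile,
#' with the beam incident through the first (substrate) medium. Returns values
#' in \[0, 1\]; R = 1 below the critical edge when the backing SLD exceeds the
#' substrate SLD.
#'
#' @param sld An `sld_profile` (or a plain list with `rho` and `step`).
#' @param q Momentum transfer values, A^-1, all > 0.
#' @param irho Optional imaginary (absorption) SLD profile; default 0.
#' @return Reflectivity at each `q`.
#' @export
reflectivity <- function(sld, q, irho = NULL) {
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  rho <- sld$rho
  if (any(!is.finite(rho))) stop("non-finite SLD in profile", call. = FALSE)
  if (is.null(irho)) irho <- numeric(length(rho))
  # collapse constant leading/trailing runs into the semi-infinite media:
  # slices matching the fronting/backing SLD add only a phase, not amplitude
  n <- length(rho)
  i0 <- 1L
  while (i0 < n - 1L && abs(rho[i0 + 1L] - rho[1L]) < 1e-9 &&
         abs(irho[i0 + 1L] - irho[1L]) < 1e-9) i0 <- i0 + 1L
  i1 <- n
  while (i1 > i0 + 1L && abs(rho[i1 - 1L] - rho[n]) < 1e-9 &&
         abs(irho[i1 - 1L] - irho[n]) < 1e-9) i1 <- i1 - 1L
  abeles_reflectivity(q, rho[i0:i1], irho[i0:i1], sld$step)
}

# Gauss-Hermite quadrature (10 nodes) over a unit normal, used for constant
# dQ/Q resolution smearing: E[R(q + sigma U)] = sum w_i R(q + sqrt(2) sigma x_i)
.smear_nodes <- local({
  gh <- pracma::gaussHermite(10)
  list(u = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
})

#' Gaussian resolution smearing of a reflectivity curve
#'
#' Convolves `r(q)` with a Gaussian of width sigma_Q = (dq_over_q/2.355) q,
#' i.e. a constant FWHM fractional resolution dQ/Q (the instrument wavelength
#' spread). `dq_over_q = 0` returns the curve unchanged. The input curve is
#' interpolated linearly in q, clamped at its ends.
#'
#' @param r Reflectivity values on the grid `q`.
#' @param q Strictly increasing q grid (A^-1).
#' @param dq_over_q Fractional FWHM resolution (e.g. 0.1).
#' @return Smeared reflectivity on the same grid.
#' @export
smear <- function(r, q, dq_over_q) {
  if (dq_over_q < 0) stop("dq_over_q must be >= 0", call. = FALSE)
  if (dq_over_q == 0) return(r)
  nodes <- .smear_nodes
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    sigma <- dq_over_q / 2.355 * q[i]
    qi <- q[i] + sigma * nodes$u
    ri <- approx(q, r, xout = qi, rule = 2)$y
    out[i] <- sum(nodes$w * ri)
  }
  out
}

#' Full reflectometry forward model
#'
#' Builds the volume-fraction profiles of an interface model, applies the
#' two-stage roughness convolution, translates to an SLD profile and computes
#' the resolution-smeared reflectivity. Smearing is evaluated exactly (the
#' Abeles kernel is run at the quadrature q nodes rather than interpolated).
#'
#' @param model An [interface_model()].
#' @param q Momentum transfer grid (A^-1).
#' @param dq_over_q Fractional FWHM resolution (default 0.1).
#' @param grid_step z-grid spacing (default 0.5 A).
#' @param scale,background Optional multiplicative scale and additive
#'   background.
#' @return Reflectivity at each `q`.
#' @export
nr_reflectivity <- function(model, q, dq_over_q = 0.1, grid_step = 0.5,
                            scale = 1, background = 0) {
  p <- build_profiles(model, grid_step)
  p <- convolve_profiles(p, model$bilayer_roughness, model$substrate_roughness)
  sld <- profiles_to_sld(
    p,
    slds = c(substrate = model$substrate_sld, oxide = model$oxide_sld,
             head = model$head_sld, tail = model$tail_sld),
    solvent_sld = model$solvent$sld)
  if (dq_over_q == 0) {
    r <- reflectivity(sld, q)
  } else {
    nodes <- .smear_nodes
    qm <- outer(q, 1 + dq_over_q / 2.355 * nodes$u)
    qm[qm <= 0] <- min(q) * 1e-3
    rr <- reflectivity(sld, as.numeric(qm))
    r <- as.numeric(matrix(rr, nrow = length(q)) %*% nodes$w)
  }
  scale * r + background
}

#' Area per lipid from slab geometry and composition
#'
#' The lipid surface excess per leaflet is
#' `Gamma = d_tail (1 - f_solv) / (2 Vbar_tail)` with `Vbar_tail` the
#' mole-fraction-weighted mean tail volume over all lipids (cholesterol
#' included); the area per lipid is `1 / Gamma`.
#'
#' @param model An [interface_model()].
#' @param mix A `mixture_composition`.
#' @param species Named list of [lipid_species()] providing tail volumes.
#' @return Area per lipid in A^2 (`Inf` with a warning at zero occupancy).
#' @export
area_per_lipid <- function(model, mix, species = load_components()$species) {
  vbar <- mixture_slabs(mix, species)$tail_volume
  occ <- 1 - model$tail_solvent_fraction
  if (occ <= 0 || model$tail_thickness <= 0) {
    warning("zero tail occupancy: area per lipid is infinite")
    return(Inf)
  }
  2 * vbar / (model$tail_thickness * occ)
}

#' Global roughness of the bilayer/solvent boundary
#'
#' Fits an error-function edge to the solvent fraction rise at the outer
#' headgroup/solvent boundary of a convolved profile and returns its Gaussian
#' width. For two successive Gaussian convolutions the widths add in
#' quadrature, so the global width approaches
#' `sqrt(bilayer_roughness^2 + substrate_roughness^2)`.
#'
#' @param p_convolved A convolved `volume_fraction_profile`.
#' @return The fitted boundary width (A), with the erf midpoint position as
#'   attribute `"z0"`.
#' @export
global_roughness <- function(p_convolved) {
  stopifnot(inherits(p_convolved, "volume_fraction_profile"))
  z <- p_convolved$z
  lipid <- p_convolved$phi$head + p_convolved$phi$tail
  if (max(lipid) <= 0) return(structure(0, z0 = NA_real_))
  # outer edge: from the last point where lipid is at >= 90% of its peak
  s <- p_convolved$phi$solvent
  # solvent rise on the solvent side of the bilayer: both the tail/head and
  # the head/solvent transitions carry the same total Gaussian width, so a
  # shared-width double-erf model separates the boundary width from the
  # intrinsic headgroup structure even when the two edges overlap
  ipk <- which.max(lipid)
  idip <- ipk - 1 + which.min(s[ipk:length(s)])
  zi <- z[z >= z[idip]]; si <- s[z >= z[idip]]
  b <- si[1]
  icross <- max(which(si < (1 + b) / 2))
  obj <- function(par) {
    m1 <- par[1]; m2 <- par[2]
    s1 <- min(max(par[3], b), 1)
    sig <- exp(par[4])
    mod <- b + (s1 - b) * pnorm((zi - m1) / sig) +
      (1 - s1) * pnorm((zi - m2) / sig)
    sum((si - mod)^2)
  }
  i1 <- which(si > b + 0.15 * (1 - b))[1]
  fit <- NULL
  for (sig0 in c(0.5, 2, 6)) {
    f <- optim(c(zi[i1], zi[icross], 0.5, log(sig0)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  structure(exp(fit$par[4]), z0 = fit$par[2])
}
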