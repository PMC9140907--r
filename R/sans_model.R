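# Lamellar-stack paracrystal SANS model in absolute units, with thickness
# polydispersity, incoherent background, weighted least-squares fitting, and
# power-law slope diagnostics.

#' Define lamellar-stack paracrystal parameters
#'
#' Describes a stack of `n_layers` bilayers of the given thickness, with
#' Gaussian-disordered centre-to-centre spacing `d_spacing` (relative
#' disorder `sigma_d_rel` = sigma_D/<D>) and a Gaussian relative
#' polydispersity on the bilayer thickness.
#'
#' @param thickness Bilayer thickness (A), must be < `d_spacing`.
#' @param n_layers Mean number of stacked lamellae (>= 1, may be
#'   non-integer).
#' @param d_spacing Mean centre-to-centre lamellar spacing <D> (A).
#' @param sigma_d_rel Dimensionless spacing disorder sigma_D/<D> (>= 0).
#' @param poly_thickness Relative Gaussian width on thickness (>= 0).
#' @param contrast SLD contrast between bilayer and solvent (10^-6 A^-2).
#' @param scale Overall normalization absorbing the number density of
#'   scattering objects and unit conversion to cm^-1.
#' @param background Flat incoherent background (cm^-1, >= 0).
#' @return A `paracrystal_params` object.
#' @export
paracrystal_params <- function(thickness, n_layers, d_spacing, sigma_d_rel,
                               poly_thickness = 0.05, contrast = 6.0,
                               scale = 1e-6, background = 0.01) {
  if (!(thickness > 0 && thickness < d_spacing))
    stop("need 0 < thickness < d_spacing", call. = FALSE)
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (sigma_d_rel < 0 || poly_thickness < 0 || background < 0)
    stop("widths and background must be >= 0", call. = FALSE)
  structure(list(thickness = thickness, n_layers = n_layers,
                 d_spacing = d_spacing, sigma_d_rel = sigma_d_rel,
                 poly_thickness = poly_thickness, contrast = contrast,
                 scale = scale, background = background),
            class = "paracrystal_params")
}

# finite-stack ideal paracrystal factor for integer N:
# Z_N(q) = 1 + (2/N) sum_{k=1}^{N-1} (N-k) cos(k q D) exp(-k q^2 D^2 s^2 / 2)
paracrystal_zn_int <- function(q, n, d, s_rel) {
  if (n <= 1) return(rep(1, length(q)))
  z <- rep(1, length(q))
  for (k in seq_len(n - 1)) {
    z <- z + (2 / n) * (n - k) * cos(k * q * d) *
      exp(-k * q^2 * d^2 * s_rel^2 / 2)
  }
  z
}

#' Finite-stack paracrystal structure factor
#'
#' Lattice factor of a 1-D stack of `n_layers` lamellae with Gaussian
#' cumulative spacing disorder. `Z_N(q -> 0) -> N` for zero disorder, and
#' large disorder collapses `Z_N -> 1` beyond the first structure peak.
#' Non-integer `n_layers` is handled by linear interpolation between the
#' evaluations at `floor(N)` and `ceiling(N)`.
#'
#' @param q Momentum transfer (A^-1).
#' @param n_layers Mean stack size (>= 1).
#' @param d_spacing Mean lamellar spacing (A).
#' @param sigma_d_rel Relative spacing disorder.
#' @return `Z_N(q)` at each `q`.
#' @export
paracrystal_zn <- function(q, n_layers, d_spacing, sigma_d_rel) {
  lo <- floor(n_layers); hi <- ceiling(n_layers)
  zlo <- paracrystal_zn_int(q, lo, d_spacing, sigma_d_rel)
  if (hi == lo) return(zlo)
  zhi <- paracrystal_zn_int(q, hi, d_spacing, sigma_d_rel)
  w <- n_layers - lo
  (1 - w) * zlo + w * zhi
}

# thickness-polydispersity-averaged uniform-slab lamellar form factor,
# P_slab(q) = < (2 sin(q t/2) / q)^2 >_t, Gauss-Hermite over a truncated
# (t > 0) Gaussian thickness distribution
.gh15 <- pracma::gaussHermite(15)

slab_form_factor <- function(q, thickness, poly_thickness) {
  if (poly_thickness <= 0)
    return((2 * sin(q * thickness / 2) / q)^2)
  t_nodes <- thickness + sqrt(2) * poly_thickness * thickness * .gh15$x
  w <- .gh15$w / sqrt(pi)
  keep <- t_nodes > 0
  t_nodes <- t_nodes[keep]; w <- w[keep] / sum(w[keep])
  p <- numeric(length(q))
  for (i in seq_along(t_nodes))
    p <- p + w[i] * (2 * sin(q * t_nodes[i] / 2) / q)^2
  p
}

#' Absolute SANS intensity of the lamellar-stack paracrystal model
#'
#' `I(q) = scale * contrast^2 * P_slab(q) * Z_N(q) / q^2 + background`, with
#' `P_slab` the thickness-polydispersity-averaged uniform-slab lamellar form
#' factor and `Z_N` the finite-stack paracrystal factor from
#' [paracrystal_zn()]. No inter-aggregate structure factor is applied.
#'
#' @param p A [paracrystal_params()].
#' @param q Momentum transfer (A^-1), all > 0.
#' @param components If `TRUE`, also return `P`, `Z` and the background.
#' @return Intensity in cm^-1 (or a list when `components = TRUE`).
#' @export
paracrystal_intensity <- function(p, q, components = FALSE) {
  stopifnot(inherits(p, "paracrystal_params"))
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  P <- slab_form_factor(q, p$thickness, p$poly_thickness)
  Z <- paracrystal_zn(q, p$n_layers, p$d_spacing, p$sigma_d_rel)
  i <- p$scale * p$contrast^2 * P * Z / q^2 + p$background
  if (components) list(i = i, P = P, Z = Z, background = p$background) else i
}

#' Fit the paracrystal model to an absolute-intensity SANS curve
#'
#' Weighted least squares (bounded Levenberg-Marquardt with seeded restarts)
#' of the lamellar-stack paracrystal model; 1-sigma parameter uncertainties
#' come from the covariance at the optimum. The thickness polydispersity is
#' held fixed.
#'
#' @param curve A `scattering_curve` in absolute units with positive
#'   uncertainties.
#' @param init A [paracrystal_params()] starting point.
#' @param free Character vector of parameters to vary.
#' @param lower,upper Optional named bound overrides.
#' @param seed Integer seed for the restart jitter.
#' @param n_starts Number of restarts (first start is `init`).
#' @return A `sans_fit`: `params` (fitted [paracrystal_params()]), `se`
#'   (named 1-sigma uncertainties), `chi2`, `n_points`.
#' @export
fit_sans <- function(curve, init,
                     free = c("thickness", "n_layers", "d_spacing",
                              "sigma_d_rel", "scale", "background"),
                     lower = NULL, upper = NULL, seed = 20220510,
                     n_starts = 4) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(init, "paracrystal_params"))
  if (any(curve$dy <= 0))
    stop("curve must carry positive uncertainties", call. = FALSE)
  set.seed(seed)
  p0 <- unlist(init[free])
  lo <- c(thickness = 5, n_layers = 1, d_spacing = 20, sigma_d_rel = 0,
          scale = 0, background = 0)[free]
  hi <- c(thickness = 200, n_layers = 50, d_spacing = 500, sigma_d_rel = 5,
          scale = 1, background = 10)[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  resfun <- function(par) {
    pp <- init
    pp[free] <- as.list(pmax(pmin(par, hi), lo))
    if (pp$thickness >= pp$d_spacing) return(rep(1e6, length(curve$q)))
    (paracrystal_intensity(pp, curve$q) - curve$y) / curve$dy
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) p0 else pmin(pmax(p0 * exp(0.2 * rnorm(length(p0))),
                                           lo), hi)
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lo, upper = hi, fn = resfun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("SANS fit failed to converge from every start", call. = FALSE)
  pars <- init
  pars[free] <- as.list(as.numeric(best$par))
  # 1-sigma from a forward-difference Jacobian at the optimum
  bf <- as.numeric(best$par)
  r0 <- resfun(bf)
  J <- matrix(0, length(r0), length(free))
  for (jp in seq_along(free)) {
    h <- 1e-5 * max(abs(bf[jp]), 1e-6)
    pj <- bf; pj[jp] <- pj[jp] + h
    J[, jp] <- (resfun(pj) - r0) / h
  }
  se <- rep(NA_real_, length(free))
  cv <- try(solve(crossprod(J)), silent = TRUE)
  if (!inherits(cv, "try-error")) {
    dg <- diag(cv); dg[dg < 0] <- NA
    se <- sqrt(dg)
  }
  structure(list(params = pars, se = setNames(se, free),
                 chi2 = best$deviance, n_points = length(curve$q)),
            class = "sans_fit")
}

#' @export
print.sans_fit <- function(x, ...) {
  cat("Lamellar-stack paracrystal fit\n")
  p <- x$params
  vals <- c(thickness = p$thickness, n_layers = p$n_layers,
            d_spacing = p$d_spacing, sigma_d_rel = p$sigma_d_rel,
            scale = p$scale, background = p$background)
  tab <- data.frame(value = vals,
                    se = x$se[match(names(vals), names(x$se))])
  print(signif(tab, 5))
  cat(sprintf("chi2 = %.1f over %d points\n", x$chi2, x$n_points))
  invisible(x)
}

#' Log-log power-law slope of a scattering curve
#'
#' Weighted linear regression of `log I` vs `log q` over a q window after
#' background subtraction; returns the exponent alpha of `I ~ q^-alpha`.
#'
#' @param curve A `scattering_curve`.
#' @param q_min,q_max Window bounds (A^-1).
#' @param background Constant subtracted before taking logs.
#' @return The power-law exponent alpha.
#' @export
power_law_slope <- function(curve, q_min, q_max, background = 0) {
  sel <- curve$q >= q_min & curve$q <= q_max
  if (sum(sel) < 5) stop("need at least 5 points in the window", call. = FALSE)
  y <- curve$y[sel] - background
  if (any(y <= 0))
    stop("non-positive intensities after background subtraction", call. = FALSE)
  q <- curve$q[sel]
  w <- (y / curve$dy[sel])^2  # delta(log y) = dy / y
  fit <- stats::lm(log(y) ~ log(q), weights = w)
  -unname(coef(fit)[2])
}
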