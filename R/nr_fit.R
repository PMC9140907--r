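# Simultaneous refinement of one structural model against reflectivity curves
# in multiple solvent contrasts, with 95% credible intervals and SLD
# probability maps.

# model fields that can be freed in a fit
.nr_param_names <- c("head_thickness", "tail_thickness", "head_sld", "tail_sld",
                     "head_solvent_fraction", "tail_solvent_fraction",
                     "bilayer_roughness", "substrate_roughness", "water_gap",
                     "oxide_thickness", "oxide_sld")

# apply named parameter values (structural fields and per-contrast
# "scale_<k>"/"background_<k>") to an interface model
set_model_params <- function(model, values) {
  nm <- names(values)
  structural <- intersect(nm, .nr_param_names)
  for (p in structural) model[[p]] <- unname(values[[p]])
  model
}

#' Specify a multi-contrast reflectometry co-refinement
#'
#' All contrasts share the structural parameters and differ only in solvent
#' SLD (and optional per-contrast scale/background, freed by naming them
#' `scale_<k>` / `background_<k>` with `k` the contrast index).
#'
#' @param model Base [interface_model()]; its solvent slot is replaced
#'   per-contrast.
#' @param free Data frame with columns `name`, `lower`, `upper`, `init`
#'   listing the free parameters (names from the interface model fields).
#' @param contrasts List of `list(solvent = solvent_contrast, curve =
#'   scattering_curve)` entries.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(model, free, contrasts) {
  stopifnot(inherits(model, "interface_model"),
            is.data.frame(free),
            all(c("name", "lower", "upper", "init") %in% names(free)),
            length(contrasts) >= 1)
  if (any(!is.finite(free$lower) | !is.finite(free$upper) |
          free$lower >= free$upper))
    stop("parameter bounds must be finite with lower < upper", call. = FALSE)
  if (any(free$init < free$lower | free$init > free$upper))
    stop("initial values must lie within bounds", call. = FALSE)
  for (ct in contrasts) {
    if (!inherits(ct$solvent, "solvent_contrast") ||
        !inherits(ct$curve, "scattering_curve"))
      stop("each contrast needs a solvent_contrast and a scattering_curve",
           call. = FALSE)
    if (any(ct$curve$dy <= 0))
      stop("curves must carry positive uncertainties", call. = FALSE)
  }
  structure(list(model = model, free = free, contrasts = contrasts),
            class = "fit_spec")
}

# weighted residual vector over all contrasts for parameter vector `par`
# (named). Profiles are built and convolved once; only the SLD translation
# and Abeles kernel run per contrast.
nr_residuals <- function(par, spec, dq_over_q = 0.1, grid_step = 0.5) {
  m <- set_model_params(spec$model, par)
  p <- build_profiles(m, grid_step)
  p <- convolve_profiles(p, m$bilayer_roughness, m$substrate_roughness)
  nodes <- .smear_nodes
  res <- vector("list", length(spec$contrasts))
  for (k in seq_along(spec$contrasts)) {
    ct <- spec$contrasts[[k]]
    sld <- profiles_to_sld(
      p, slds = c(substrate = m$substrate_sld, oxide = m$oxide_sld,
                  head = m$head_sld, tail = m$tail_sld),
      solvent_sld = ct$solvent$sld)
    q <- ct$curve$q
    if (dq_over_q > 0) {
      qm <- outer(q, 1 + dq_over_q / 2.355 * nodes$u)
      qm[qm <= 0] <- min(q) * 1e-3
      rr <- reflectivity(sld, as.numeric(qm))
      r <- as.numeric(matrix(rr, nrow = length(q)) %*% nodes$w)
    } else {
      r <- reflectivity(sld, q)
    }
    sc_nm <- paste0("scale_", k); bg_nm <- paste0("background_", k)
    sc <- if (sc_nm %in% names(par)) par[[sc_nm]] else 1
    bg <- if (bg_nm %in% names(par)) par[[bg_nm]] else 0
    res[[k]] <- (sc * r + bg - ct$curve$y) / ct$curve$dy
  }
  unlist(res)
}

#' Co-refine a structural model against multiple solvent contrasts
#'
#' Minimizes the joint weighted chi-square over all contrasts (seeded
#' Latin-hypercube multistart feeding bounded Levenberg-Marquardt), then
#' optionally samples the posterior under uniform priors on the bounds with an
#' affine-invariant ensemble sampler to produce 95% credible intervals
#' (2.5/97.5 percentiles). Deterministic given `seed`.
#'
#' @param spec A [fit_spec()].
#' @param seed Integer seed (default 20220510).
#' @param n_starts Number of multistart points (the supplied `init` is always
#'   the first).
#' @param mcmc `NULL` to skip sampling (intervals then come from the local
#'   covariance), or a list with `n_walkers`, `n_steps`, `burn`.
#' @param dq_over_q Fractional FWHM resolution of the data (default 0.1).
#' @param grid_step z-grid spacing for the forward model (A).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An `nr_fit` object: `best_fit` (named vector), `ci95` (data frame
#'   with `lower`/`upper`), `samples` (matrix or NULL), `chi2_per_contrast`,
#'   `chi2`, `n_points`, `multimodal` flag, and the refined `model`.
#' @export
co_refine <- function(spec, seed = 20220510, n_starts = 4, mcmc = NULL,
                      dq_over_q = 0.1, grid_step = 0.5, maxiter = 50) {
  stopifnot(inherits(spec, "fit_spec"))
  set.seed(seed)
  free <- spec$free
  d <- nrow(free)
  pnames <- free$name
  ssq <- function(par) {
    names(par) <- pnames
    r <- nr_residuals(par, spec, dq_over_q, grid_step)
    sum(r^2)
  }
  resfun <- function(par) {
    names(par) <- pnames
    nr_residuals(par, spec, dq_over_q, grid_step)
  }
  starts <- matrix(free$init, nrow = 1)
  if (n_starts > 1) {
    u <- lhs::randomLHS(n_starts - 1, d)
    starts <- rbind(starts,
                    sweep(sweep(u, 2, free$upper - free$lower, `*`),
                          2, free$lower, `+`))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = starts[s, ], lower = free$lower, upper = free$upper, fn = resfun,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ptol = 1e-10))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("co-refinement failed from every start", call. = FALSE)
  bf <- setNames(as.numeric(best$par), pnames)

  samples <- NULL; multimodal <- FALSE
  if (!is.null(mcmc)) {
    nw <- if (!is.null(mcmc$n_walkers)) mcmc$n_walkers else max(16, 2 * d + 2)
    ns <- if (!is.null(mcmc$n_steps)) mcmc$n_steps else 400
    burn <- if (!is.null(mcmc$burn)) mcmc$burn else floor(ns / 2)
    log_post <- function(par) {
      if (any(par < free$lower | par > free$upper)) return(-Inf)
      -0.5 * ssq(par)
    }
    span <- free$upper - free$lower
    init <- t(replicate(nw, pmin(pmax(bf + 0.01 * span * rnorm(d),
                                      free$lower), free$upper)))
    run <- stretch_sampler(log_post, init, n_steps = ns, burn = burn)
    samples <- run$samples
    colnames(samples) <- pnames
    ci <- t(apply(samples, 2, quantile, probs = c(0.025, 0.975)))
    # crude multimodality flag: a secondary histogram mode holding > 10% of
    # samples, separated from the main one by a deep valley
    for (jc in seq_len(d)) {
      rngj <- range(samples[, jc])
      if (diff(rngj) == 0) next
      brj <- seq(rngj[1], rngj[2], length.out = 31)
      cnt <- tabulate(findInterval(samples[, jc], brj, all.inside = TRUE),
                      nbins = 30)
      pk <- which(diff(sign(diff(c(-1, cnt, -1)))) == -2)
      pk <- pk[cnt[pk] > 0.1 * max(cnt)]
      if (length(pk) >= 2) {
        for (ia in head(pk, -1)) for (ib in pk[pk > ia]) {
          if (ib - ia >= 5 && min(cnt[ia:ib]) < 0.3 * min(cnt[ia], cnt[ib]) &&
              min(cnt[ia], cnt[ib]) > 0.1 * sum(cnt)) multimodal <- TRUE
        }
      }
    }
  } else {
    # local covariance intervals from a forward-difference Jacobian
    r0 <- resfun(bf)
    J <- matrix(0, length(r0), d)
    for (jp in seq_len(d)) {
      h <- 1e-4 * max(abs(bf[jp]), 1e-3)
      pj <- bf; pj[jp] <- pj[jp] + h
      J[, jp] <- (resfun(pj) - r0) / h
    }
    se <- rep(NA_real_, d)
    cv <- try(solve(crossprod(J)), silent = TRUE)
    if (!inherits(cv, "try-error")) {
      dg <- diag(cv); dg[dg < 0] <- NA
      se <- sqrt(dg)
    }
    ci <- cbind(bf - 1.96 * se, bf + 1.96 * se)
  }
  ci95 <- data.frame(lower = pmax(ci[, 1], free$lower),
                     upper = pmin(ci[, 2], free$upper), row.names = pnames)

  # per-contrast chi-square at the best fit
  r_all <- resfun(bf)
  npts <- vapply(spec$contrasts, function(ct) length(ct$curve$q), integer(1))
  idx <- rep(seq_along(npts), npts)
  chi2_per_contrast <- tapply(r_all^2, idx, sum)
  structure(list(best_fit = bf, ci95 = ci95, samples = samples,
                 chi2_per_contrast = as.numeric(chi2_per_contrast),
                 chi2 = sum(r_all^2), n_points = sum(npts),
                 multimodal = multimodal,
                 model = set_model_params(spec$model, bf), spec = spec),
            class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("Multi-contrast reflectometry co-refinement\n")
  tab <- data.frame(best = x$best_fit, x$ci95)
  print(round(tab, 4))
  cat(sprintf("chi2 = %.1f over %d points (per contrast: %s)\n", x$chi2,
              x$n_points, paste(round(x$chi2_per_contrast, 1), collapse = ", ")))
  if (x$multimodal) cat("note: posterior flagged as multimodal\n")
  invisible(x)
}

#' SLD probability map from a sampled posterior
#'
#' Propagates posterior parameter draws through the forward model and bins
#' the resulting SLD curves into a normalized 2D histogram over (z, rho);
#' each z column integrates to 1.
#'
#' @param fit An `nr_fit` with samples (or a matrix of parameter draws via
#'   `samples`).
#' @param solvent The [solvent_contrast()] to evaluate profiles under.
#' @param n_rho Number of SLD bins.
#' @param max_draws Cap on the number of posterior draws propagated.
#' @param grid_step z-grid spacing (A).
#' @return List with `z`, `rho_mid` (bin centres), and `density`
#'   (length(rho_mid) x length(z) matrix, columns summing to 1).
#' @export
sld_probability_map <- function(fit, solvent = solvent_contrast("D2O"),
                                n_rho = 80, max_draws = 300, grid_step = 0.5) {
  stopifnot(inherits(fit, "nr_fit"))
  draws <- fit$samples
  if (is.null(draws)) draws <- matrix(fit$best_fit, nrow = 1,
                                      dimnames = list(NULL, names(fit$best_fit)))
  if (nrow(draws) == 0) stop("empty posterior sample", call. = FALSE)
  if (nrow(draws) > max_draws)
    draws <- draws[seq(1, nrow(draws), length.out = max_draws), , drop = FALSE]
  curves <- NULL; zref <- NULL
  base <- fit$spec$model
  for (i in seq_len(nrow(draws))) {
    m <- set_model_params(base, draws[i, ])
    m$solvent <- solvent
    p <- build_profiles(m, grid_step, margin = 4 * max(base$bilayer_roughness,
                                                       base$substrate_roughness) + 30)
    p <- convolve_profiles(p, m$bilayer_roughness, m$substrate_roughness)
    sld <- profiles_to_sld(
      p, slds = c(substrate = m$substrate_sld, oxide = m$oxide_sld,
                  head = m$head_sld, tail = m$tail_sld),
      solvent_sld = solvent$sld)
    if (is.null(zref)) {
      zref <- sld$z
      curves <- matrix(NA_real_, nrow(draws), length(zref))
    }
    curves[i, ] <- approx(sld$z, sld$rho, xout = zref, rule = 2)$y
  }
  rng <- range(curves)
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_rho + 1)
  dens <- apply(curves, 2, function(col) {
    h <- tabulate(findInterval(col, brk, all.inside = TRUE), nbins = n_rho)
    h / sum(h)
  })
  list(z = zref, rho_mid = (brk[-1] + brk[-(n_rho + 1)]) / 2, density = dens)
}
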