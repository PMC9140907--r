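# Independent oracles used to cross-check the package implementations.

# Characteristic-matrix (Abeles 2x2) reflectivity, implemented independently
# of the C++ Parratt recursion. rho in 1e-6 A^-2; uniform slice thickness.
oracle_reflectivity <- function(q, rho, step) {
  vapply(q, function(qv) {
    k <- sqrt(as.complex(qv^2 / 4 - 4 * pi * (rho - rho[1]) * 1e-6))
    n <- length(k)
    M <- diag(2)
    for (j in 2:(n - 1)) {
      b <- k[j] * step
      Mj <- matrix(c(cos(b), -1i * k[j] * sin(b),
                     -1i * sin(b) / k[j], cos(b)), 2, 2)
      M <- M %*% Mj
    }
    num <- (M[1, 1] + M[1, 2] * k[n]) * k[1] - (M[2, 1] + M[2, 2] * k[n])
    den <- (M[1, 1] + M[1, 2] * k[n]) * k[1] + (M[2, 1] + M[2, 2] * k[n])
    Mod(num / den)^2
  }, numeric(1))
}

# analytic single-film (two-interface) reflectivity oracle
oracle_single_slab <- function(q, rho0, rho1, rho2, d) {
  k0 <- sqrt(as.complex(q^2 / 4))
  k1 <- sqrt(as.complex(q^2 / 4 - 4 * pi * (rho1 - rho0) * 1e-6))
  k2 <- sqrt(as.complex(q^2 / 4 - 4 * pi * (rho2 - rho0) * 1e-6))
  r01 <- (k0 - k1) / (k0 + k1)
  r12 <- (k1 - k2) / (k1 + k2)
  ph <- exp(2i * k1 * d)
  Mod((r01 + r12 * ph) / (1 + r01 * r12 * ph))^2
}

# brute-force numerical Gaussian resolution convolution on a dense grid
oracle_smear <- function(r_fun, q, dq_over_q, n_sub = 801) {
  vapply(q, function(qi) {
    sigma <- dq_over_q / 2.355 * qi
    qq <- seq(qi - 4 * sigma, qi + 4 * sigma, length.out = n_sub)
    qq <- qq[qq > 0]
    w <- dnorm(qq, mean = qi, sd = sigma)
    sum(w * r_fun(qq)) / sum(w)
  }, numeric(1))
}

# Monte-Carlo lattice-sum oracle for the finite-stack paracrystal factor:
# average |sum_j exp(i q x_j)|^2 / N over stacks with Gaussian-disordered
# spacings (cumulative disorder)
oracle_paracrystal_zn <- function(q, n, d, s_rel, n_mc = 20000, seed = 42) {
  set.seed(seed)
  z <- numeric(length(q))
  for (r in seq_len(n_mc)) {
    x <- cumsum(c(0, rnorm(n - 1, mean = d, sd = s_rel * d)))
    for (iq in seq_along(q)) {
      s <- sum(exp(1i * q[iq] * x))
      z[iq] <- z[iq] + Mod(s)^2 / n
    }
  }
  z / n_mc
}

# default free-parameter table for supported-bilayer recovery fits
nr_free_table <- function(init) {
  data.frame(
    name = c("head_thickness", "tail_thickness", "bilayer_roughness",
             "tail_solvent_fraction"),
    lower = c(3, 10, 0.05, 0), upper = c(20, 60, 12, 0.6), init = init)
}

# build a fit_spec for a truth system and generated curves
nr_recovery_spec <- function(tm, curves, init) {
  fit_spec(tm$model, nr_free_table(init),
           lapply(names(curves), function(nm)
             list(solvent = solvent_contrast(nm), curve = curves[[nm]])))
}
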