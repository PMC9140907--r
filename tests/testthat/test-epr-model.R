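# Tensor averaging, fast-motion widths, MOMD spectra, and S/tau recovery.

test_that("isotropic hyperfine couplings match the probe scheme", {
  expect_equal(round(isotropic_hyperfine(probe_defaults("7-PCSL")$a_tensor), 1),
               14.4)
  expect_equal(round(isotropic_hyperfine(probe_defaults("14-PCSL")$a_tensor), 1),
               14.1)
  expect_equal(round(isotropic_hyperfine(probe_defaults("CNO")$a_tensor), 1),
               14.3)
  expect_equal(isotropic_hyperfine(c(8, 8, 8)), 8)
  # the 5-PCSL tensor's trace mean disagrees with its reported rounded value;
  # the package computes the trace mean and keeps the discrepancy visible
  d5 <- probe_defaults("5-PCSL")
  expect_equal(isotropic_hyperfine(d5$a_tensor), 14.6333, tolerance = 1e-4)
  expect_false(round(isotropic_hyperfine(d5$a_tensor), 1) == d5$a_iso_reported)
})

test_that("partial averaging interpolates between isotropic and rigid limits", {
  for (probe in c("5-PCSL", "7-PCSL", "10-PCSL", "14-PCSL", "CNO")) {
    d <- probe_defaults(probe)
    m0 <- spin_probe_model(probe, 0, 1)
    av0 <- partial_average(m0)
    expect_equal(av0$a_par, mean(d$a_tensor), tolerance = 1e-12)
    expect_equal(av0$a_perp, mean(d$a_tensor), tolerance = 1e-12)
    m1 <- spin_probe_model(probe, 1, 1)
    av1 <- partial_average(m1)
    expect_equal(av1$a_par, d$a_tensor[3], tolerance = 1e-12)
    expect_equal(av1$a_perp, mean(d$a_tensor[1:2]), tolerance = 1e-12)
    # trace conservation at arbitrary S
    for (S in c(0.17, 0.5, 0.83)) {
      av <- partial_average(spin_probe_model(probe, S, 1))
      expect_equal((av$a_par + 2 * av$a_perp) / 3, mean(d$a_tensor),
                   tolerance = 1e-12)
      expect_equal((av$g_par + 2 * av$g_perp) / 3, mean(d$g_tensor),
                   tolerance = 1e-12)
    }
  }
})

test_that("fast-motion width coefficients have Redfield structure", {
  w <- fast_motion_linewidths(spin_probe_model("14-PCSL", 0, 0.5))
  expect_true(all(w[c("A", "C")] > 0))
  expect_lt(w["B"], 0)                       # low-field line narrowest
  expect_lt(w["A"] + w["B"] + w["C"],        # m = +1 narrower than m = -1
            w["A"] - w["B"] + w["C"])
  # motional terms vanish in the extreme-narrowing limit
  w0 <- fast_motion_linewidths(spin_probe_model("14-PCSL", 0, 1e-3,
                                                tau_par = 1e-3))
  expect_lt(abs(w0["B"]), 1e-3)
  expect_lt(w0["C"], 1e-3)
  # B and C are exactly linear in the effective correlation time
  m1 <- spin_probe_model("14-PCSL", 0, 0.5)
  m2 <- spin_probe_model("14-PCSL", 0, 1.0)
  r_tau <- memscatter:::effective_tau(m2) / memscatter:::effective_tau(m1)
  w1 <- fast_motion_linewidths(m1); w2 <- fast_motion_linewidths(m2)
  expect_equal(unname(w2["C"] / w1["C"]), r_tau, tolerance = 1e-12)
  expect_equal(unname(w2["B"] / w1["B"]), r_tau, tolerance = 1e-12)
  expect_equal(r_tau, 2, tolerance = 0.05)   # doubling tau_perp ~doubles C
  expect_warning(fast_motion_linewidths(spin_probe_model("14-PCSL", 0, 200)),
                 "validity")
})

test_that("MOMD spectra show the expected splittings", {
  # isotropic CNO triplet split by its trace-mean coupling
  s <- simulate_spectrum(spin_probe_model("CNO", 0, 0.33))
  centers <- line_centers(s)
  expect_length(centers, 3)
  expect_equal(mean(diff(centers)), 14.33, tolerance = 0.05)
  # derivative of the absorption integrates to ~zero over the sweep (the
  # Lorentzian wings leave a small edge residual)
  step <- s$field[2] - s$field[1]
  expect_lt(abs(sum(s$intensity) * step), 1e-3 * max(abs(s$intensity)))
  # outer splitting grows strictly with S
  sp <- vapply(c(0.2, 0.4, 0.6, 0.8), function(S)
    outer_splitting(simulate_spectrum(spin_probe_model("14-PCSL", S, 1))),
    numeric(1))
  expect_true(all(diff(sp) > 0))
  # rigid limit: outer splitting approaches 2 Azz
  rigid <- simulate_spectrum(spin_probe_model("14-PCSL", 0.999, 0.05,
                                              intrinsic_width = 1))
  expect_equal(outer_splitting(rigid), 2 * 28, tolerance = 0.05)
  expect_error(simulate_spectrum(spin_probe_model("CNO", 0, 0.33),
                                 epr_grid(n_points = 128)), "coarse")
})

test_that("the CNO g tensor spreads the spectrum more than the PCSL one", {
  cno <- spin_probe_model("CNO", 0.5, 1)
  pc_likeg <- spin_probe_model("14-PCSL", 0.5, 1, a_tensor = cno$a_tensor)
  e_cno <- diff(range(line_centers(simulate_spectrum(cno))))
  e_pc <- diff(range(line_centers(simulate_spectrum(pc_likeg))))
  expect_gt(e_cno, e_pc)
})

test_that("director-grid quadrature is converged at the default density", {
  m <- spin_probe_model("5-PCSL", 0.6, 1)
  s64 <- simulate_spectrum(m, n_director = 64)
  s128 <- simulate_spectrum(m, n_director = 128)
  expect_lt(max(abs(s64$intensity - s128$intensity)),
            0.001 * max(abs(s64$intensity)))
})

test_that("noise-free spectra round-trip through the fitter", {
  truth <- spin_probe_model("14-PCSL", 0.5, 1)
  s <- simulate_spectrum(truth)
  fit <- fit_spectrum(s, spin_probe_model("14-PCSL", 0.3, 0.6))
  expect_equal(fit$order_parameter, 0.5, tolerance = 1e-3)
  expect_equal(fit$tau_perp, 1, tolerance = 1e-2)
})

test_that("fitted S preserves ordering of similar spectra", {
  f <- vapply(1:4, function(seed) {
    lo <- fit_spectrum(gen_epr(spin_probe_model("5-PCSL", 0.2, 1),
                               seed = seed, noise = 0.01),
                       spin_probe_model("5-PCSL", 0.5, 1))
    hi <- fit_spectrum(gen_epr(spin_probe_model("5-PCSL", 0.4, 1),
                               seed = seed, noise = 0.01),
                       spin_probe_model("5-PCSL", 0.5, 1))
    hi$order_parameter - lo$order_parameter
  }, numeric(1))
  expect_true(all(f > 0))
})

test_that("order profiles assemble, sort, and difference correctly", {
  p <- build_s_profile(c(14, 5, 10, 7), c(0.2, 0.6, 0.3, 0.5))
  expect_equal(p$position, c(5, 7, 10, 14))
  expect_true(all(diff(p$s) < 0))  # chol/POPC-like decreasing profile
  expect_error(build_s_profile(c(5, 5), c(0.1, 0.2)), "duplicate")
  d <- s_profile_difference(p, p)
  expect_equal(d$s, rep(0, 4))
  expect_equal(nrow(build_s_profile(7, 0.4)), 1)
})
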