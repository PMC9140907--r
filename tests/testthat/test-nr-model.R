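# Volume-fraction profiles, convolution, SLD translation, Abeles
# reflectivity, smearing, and derived quantities.

base_model <- function(...) {
  interface_model(head_thickness = 7.2, tail_thickness = 35.8,
                  head_sld = 1.78, tail_sld = 2.28,
                  head_solvent_fraction = 0.3, tail_solvent_fraction = 0,
                  bilayer_roughness = 2.9, substrate_roughness = 3,
                  solvent = solvent_contrast("D2O"), ...)
}

test_that("box profiles partition space and integrate to slab volumes", {
  m <- base_model()
  p <- build_profiles(m, 0.5)
  tot <- Reduce(`+`, p$phi)
  expect_lt(max(abs(tot - 1)), 1e-9)
  # tail occupancy integral = thickness x occupancy
  expect_equal(sum(p$phi$tail) * p$step, 35.8, tolerance = 1e-9)
  # two head boxes, each thickness x (1 - solvent fraction)
  expect_equal(sum(p$phi$head) * p$step, 2 * 7.2 * 0.7, tolerance = 1e-9)
  expect_equal(max(p$phi$head), 0.7, tolerance = 1e-12)
  # empty bilayer leaves substrate/oxide/solvent only
  m0 <- interface_model(0, 0, 1.78, 2.28, solvent = solvent_contrast("D2O"))
  p0 <- build_profiles(m0, 0.5)
  expect_equal(sum(p0$phi$head) + sum(p0$phi$tail), 0)
  expect_lt(max(abs(Reduce(`+`, p0$phi) - 1)), 1e-9)
  expect_error(interface_model(-1, 30, 1, 1), "thickness")
})

test_that("two-stage convolution conserves volume and produces erf edges", {
  m <- base_model()
  p <- build_profiles(m, 0.5)
  # identity at zero roughness
  p_id <- convolve_profiles(p, 0, 0)
  expect_equal(p_id$phi$tail, p$phi$tail)
  # integral conservation under both convolutions
  pc <- convolve_profiles(p, 2.9, 3)
  for (comp in c("oxide", "head", "tail")) {
    expect_equal(sum(pc$phi[[comp]]), sum(p$phi[[comp]]),
                 tolerance = 1e-6)
  }
  expect_lt(max(abs(Reduce(`+`, pc$phi) - 1)), 1e-9)
  # a smeared step follows the error function of the kernel width: use the
  # outer tail edge, far from the opposite edge relative to the kernel
  sig <- 3
  p1 <- convolve_profiles(p, sig, 0)
  edge <- m$water_gap + m$head_thickness + m$tail_thickness
  near <- abs(p1$z - edge) < 8
  expect_equal(p1$phi$tail[near], pnorm((edge - p1$z[near]) / sig),
               tolerance = 0.02)
})

test_that("SLD translation obeys contrast matching and solvent locality", {
  m <- base_model()
  p <- convolve_profiles(build_profiles(m, 0.5), 2.9, 3)
  slds <- c(substrate = 4, oxide = 4, head = 4, tail = 4)
  s_flat <- profiles_to_sld(p, slds, solvent_sld = 4)
  expect_lt(max(abs(s_flat$rho - 4)), 1e-12)
  # swapping the solvent changes rho only where solvent is present
  slds2 <- c(substrate = m$substrate_sld, oxide = m$oxide_sld,
             head = m$head_sld, tail = m$tail_sld)
  s_d2o <- profiles_to_sld(p, slds2, 6.35)
  s_h2o <- profiles_to_sld(p, slds2, -0.56)
  delta <- abs(s_d2o$rho - s_h2o$rho)
  expect_true(all(delta[p$phi$solvent < 1e-14] < 1e-12))
  expect_true(all(delta[p$phi$solvent > 0.5] > 1))
  # deuterated solvent leaves a deep well in the tail region: the interface
  # minimum (beyond the oxide) sits between the slabs of the bilayer
  iface <- which(s_d2o$z > 0 & s_d2o$z < 70)
  z_min <- s_d2o$z[iface][which.min(s_d2o$rho[iface])]
  expect_lt(min(s_d2o$rho[iface]), 2.5)
  expect_gt(z_min, 10); expect_lt(z_min, 45)
  expect_error(profiles_to_sld(p, slds2[-1], 6.35), "missing SLD")
})

test_that("Abeles kernel matches analytic and matrix oracles", {
  # bare Fresnel interface: critical edge and exact curve
  prof <- list(rho = c(2.07, 2.07, 6.35, 6.35), step = 0.5)
  q <- seq(0.004, 0.12, by = 0.002)
  R <- reflectivity(prof, q)
  qc <- sqrt(16 * pi * (6.35 - 2.07) * 1e-6)
  expect_equal(qc, 0.0147, tolerance = 1e-2)
  expect_true(all(R[q < qc] > 1 - 1e-9))
  expect_equal(R, oracle_single_slab(q, 2.07, 2.07, 6.35, 0.5),
               tolerance = 1e-10)
  # single 40 A slab against the closed-form two-interface formula
  nsl <- 80
  prof2 <- list(rho = c(0, rep(4, nsl), 6.35), step = 0.5)
  R2 <- reflectivity(prof2, q)
  expect_equal(R2, oracle_single_slab(q, 0, 4, 6.35, nsl * 0.5),
               tolerance = 1e-8)
  # random multi-slab profile against the independent characteristic-matrix
  # implementation
  set.seed(11)
  rho <- c(2.07, rep(3.47, 24), runif(120, -0.5, 6.5), rep(6.35, 2))
  prof3 <- list(rho = rho, step = 0.5)
  expect_equal(reflectivity(prof3, q), oracle_reflectivity(q, rho, 0.5),
               tolerance = 1e-10)
  # uniform profile reflects nothing
  expect_lt(max(reflectivity(list(rho = rep(3, 50), step = 0.5), q)), 1e-14)
})

test_that("reflectivity is reciprocal for non-absorbing profiles", {
  set.seed(7)
  rho <- c(0, cumsum(rnorm(30, 0, 0.5)), 3)
  q <- seq(0.03, 0.2, by = 0.005)  # above both critical edges
  Rf <- reflectivity(list(rho = rho, step = 1), q)
  # solvent-side incidence: reversed profile, q measured in the new fronting
  # medium; compare at equal vacuum wavevector
  kz2 <- sqrt(q^2 / 4 - 4 * pi * (rho[length(rho)] - rho[1]) * 1e-6)
  Rb <- reflectivity(list(rho = rev(rho), step = 1), 2 * kz2)
  expect_equal(Rf, Rb, tolerance = 1e-8)
})

test_that("contrast matching extinguishes reflectivity entirely", {
  m <- base_model()
  m$solvent <- solvent_contrast("custom", d2o_volume_fraction = 0.5)
  rho0 <- m$solvent$sld
  m$head_sld <- rho0; m$tail_sld <- rho0; m$oxide_sld <- rho0
  m$substrate_sld <- rho0
  q <- exp(seq(log(0.005), log(0.2), length.out = 40))
  expect_lt(max(nr_reflectivity(m, q, dq_over_q = 0)), 1e-12)
})

test_that("resolution smearing damps fringes and preserves constants", {
  q <- seq(0.01, 0.2, length.out = 400)
  r_fun <- function(qq) oracle_single_slab(qq, 0, 4, 6.35, 300)
  r <- r_fun(q)
  expect_identical(smear(r, q, 0), r)
  expect_equal(smear(rep(0.5, length(q)), q, 0.1), rep(0.5, length(q)),
               tolerance = 1e-12)
  sm <- smear(r, q, 0.1)
  expect_equal(sm, oracle_smear(r_fun, q, 0.1), tolerance = 0.02)
  # fringe amplitude strictly reduced at interior extrema
  i <- 30:(length(q) - 30)
  ext <- i[(r[i] - r[i - 1]) * (r[i + 1] - r[i]) < 0]
  maxima <- ext[r[ext] > r[ext - 1]]
  minima <- ext[r[ext] < r[ext - 1]]
  expect_true(all(sm[maxima] < r[maxima]))
  expect_true(all(sm[minima] > r[minima]))
})

test_that("area per lipid scales with occupancy and matches the headline value", {
  tm <- nr_truth_model("chol/POPC")
  expect_equal(area_per_lipid(tm$model, tm$mix), 45, tolerance = 0.01)
  m2 <- tm$model; m2$tail_solvent_fraction <- 1 - (1 - tm$model$tail_solvent_fraction) / 2
  expect_equal(area_per_lipid(m2, tm$mix),
               2 * area_per_lipid(tm$model, tm$mix), tolerance = 1e-9)
  # unit consistency: Vbar = d/2 per unit area at full occupancy -> APL = 1
  sp <- list(unit = lipid_species("unit", 0, 0, 1, 10, 0, 0))
  mix1 <- mixture_from_x(0, "hybrid", 0)
  mix1$fractions <- c(unit = 1)
  m3 <- interface_model(5, 20, 1, 1, tail_solvent_fraction = 0,
                        solvent = solvent_contrast("D2O"))
  expect_equal(area_per_lipid(m3, mix1, species = sp), 1)
  m4 <- m3; m4$tail_solvent_fraction <- 1
  expect_warning(apl <- area_per_lipid(m4, mix1, species = sp), "infinite")
  expect_identical(apl, Inf)
})

test_that("global roughness adds the two convolution widths in quadrature", {
  m <- base_model()
  p <- build_profiles(m, 0.5)
  expect_lt(as.numeric(global_roughness(convolve_profiles(p, 0, 0))), 0.3)
  g <- as.numeric(global_roughness(convolve_profiles(p, 3, 4)))
  expect_equal(g, 5, tolerance = 0.05)
  # monotone in substrate roughness
  gs <- vapply(c(1, 2.5, 4, 6), function(s)
    as.numeric(global_roughness(convolve_profiles(p, 3, s))), numeric(1))
  expect_true(all(diff(gs) > 0))
})
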