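test_that("a single harmonic bond is recovered from its Hessian", {
  k_true <- 3.3e5
  d <- diatomic_system(k = k_true, r0 = 0.11, r = 0.11)
  H <- qmdff:::.hessian_packed(d$config$pos, 0,
                               qmdff:::.pack_ff(d$topo, d$ff), 1e-6)
  bundle <- list(geometry = d$config$pos, hessian = H, state = "S0",
                 charges = c(0, 0))
  fit <- fit_harmonic_parameters(bundle, d$topo)
  expect_equal(fit$ff$bond_k, k_true, tolerance = 1e-10)
  expect_equal(fit$ff$bond_r0, 0.11, tolerance = 1e-12)
})

test_that("zero-noise teacher descriptors are recovered exactly by the two-step fit", {
  fxb <- fx_bundle("CYC_S0", "S0")
  full <- fit_qmdff(fxb$bundle, fxb$sub$topo)
  teacher <- fxb$sub$ff
  expect_equal(full$ff$bond_k, teacher$bond_k, tolerance = 1e-6)
  expect_equal(full$ff$angle_k, teacher$angle_k, tolerance = 1e-6)
  expect_equal(full$ff$stiff_k, teacher$stiff_k, tolerance = 1e-6)
  expect_equal(unname(full$ff$flex_coef), unname(teacher$flex_coef),
               tolerance = 1e-6)
  expect_lt(full$harmonic_fit$sd, 1e-8)
  expect_equal(full$ff$bond_r0, teacher$bond_r0, tolerance = 1e-9)
})

test_that("the fit standard deviation grows monotonically with Hessian noise", {
  fxb <- fx_bundle("CYC_S0", "S0")
  sds <- sapply(c(0, 0.1, 1.0), function(s) {
    b <- add_descriptor_noise(fxb$bundle, sigma_hessian = s, seed = 12)
    fit_harmonic_parameters(b, fxb$sub$topo)$sd
  })
  expect_true(all(diff(sds) > 0))
})

test_that("the FIRA residual fit reproduces a sin^2 torsion and is LS-optimal", {
  fxb <- fx_bundle("CYC_S0", "S0")
  hfit <- fit_harmonic_parameters(fxb$bundle, fxb$sub$topo)
  tor <- fit_torsional_fourier(fxb$bundle$profiles$delta3, fxb$sub$topo,
                               hfit$ff, "delta3", 6)
  expect_equal(tor$coef[c(1, 3)], c(11.5, -11.5), tolerance = 1e-8)
  expect_lt(tor$residual_rms, 1e-9)
  expect_error(fit_torsional_fourier(fxb$bundle$profiles$delta3,
                                     fxb$sub$topo, hfit$ff, "delta3",
                                     order = 13), "overdetermination")
  # residual RMS never exceeds the RMS of the residual energies themselves
  noisy <- fxb$bundle$profiles$delta3
  set.seed(31)
  noisy$energy <- noisy$energy + rnorm(length(noisy$energy), sd = 0.5)
  tn <- fit_torsional_fourier(noisy, fxb$sub$topo, hfit$ff, "delta3", 4)
  packed <- qmdff:::.pack_ff(fxb$sub$topo, hfit$ff)
  e_other <- vapply(noisy$geometries, function(g)
    qmdff:::.energy_packed(g, 0, packed), numeric(1))
  expect_lte(tn$residual_rms, sqrt(mean((noisy$energy - e_other)^2)))
})

test_that("two-step order independence: torsions fit identically against teacher or fitted harmonics", {
  fxb <- fx_bundle("PYR_S0", "S0")
  hfit <- fit_harmonic_parameters(fxb$bundle, fxb$sub$topo)
  via_fitted <- fit_torsional_fourier(fxb$bundle$profiles$delta3,
                                      fxb$sub$topo, hfit$ff, "delta3", 6)
  teacher_partial <- fxb$sub$ff
  teacher_partial$flex_coef <- teacher_partial$flex_coef * 0
  via_teacher <- fit_torsional_fourier(fxb$bundle$profiles$delta3,
                                       fxb$sub$topo, teacher_partial,
                                       "delta3", 6)
  expect_equal(via_fitted$coef, via_teacher$coef, tolerance = 1e-8)
})

test_that("profile symmetrization mirrors, averages overlaps and is idempotent", {
  half <- structure(list(angle = seq(0, 90, 15),
                         energy = c(0, 1, 3, 6, 3.5, 2, 1.5),
                         geometries = NULL, dihedral = NA, label = "toy",
                         state = "S1"), class = "torsion_profile")
  s <- symmetrize_profile(half, 90)
  expect_equal(s$angle, seq(0, 180, 15))
  expect_equal(s$energy, rev(s$energy))
  s2 <- symmetrize_profile(s, 90)
  expect_equal(s2$angle, s$angle)
  expect_equal(s2$energy, s$energy)
  toy <- structure(list(angle = c(80, 90), energy = c(1, 0),
                        geometries = NULL, dihedral = NA, label = NA,
                        state = NA), class = "torsion_profile")
  st <- symmetrize_profile(toy, 90)
  expect_equal(st$angle, c(80, 90, 100))
  expect_equal(st$energy, c(1, 0, 1))
  expect_error(symmetrize_profile(structure(list(angle = numeric(),
    energy = numeric()), class = "torsion_profile")), "empty")
})

test_that("high-level torsion import fits tables directly and is a fixed point", {
  const <- structure(list(angle = seq(0, 180, 15),
                          energy = rep(4.2, 13)), class = "torsion_profile")
  f <- import_highlevel_torsion(const, 6)
  expect_equal(f$coef[1], 4.2, tolerance = 1e-10)
  expect_lt(max(abs(f$coef[-1])), 1e-10)
  # refitting the fitted curve on the same grid returns the coefficients
  ts <- build_teacher_system("PYR_S1")
  sc <- relaxed_scan(ts, "S1", "delta4", seq(90, 180, 15))
  tab <- symmetrize_profile(sc, 90)
  f1 <- import_highlevel_torsion(tab, 6)
  resampled <- tab
  resampled$energy <- sapply(tab$angle, function(d)
    sum(f1$coef * cos((0:6) * deg2rad(d))))
  f2 <- import_highlevel_torsion(resampled, 6)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
  expect_error(import_highlevel_torsion(sc, 6), "coverage")
})

test_that("the clockwise wall is one-sided, continuous and active in the energy", {
  w <- build_clockwise_restraint(c(1, 2, 3, 4), 0, 100)
  expect_equal(wall_energy(w, 10), 0)
  expect_equal(wall_energy(w, -10), 0.5 * 100 * deg2rad(10)^2)
  expect_lt(abs(wall_energy(w, 1e-6) - wall_energy(w, -1e-6)), 1e-8)
  s <- chain4_system(coef = rep(0, 7), delta_deg = -10,
                     wall = build_clockwise_restraint(c(1, 2, 3, 4), 0, 100))
  e <- evaluate_energy(s$config, s$topo, s$ff)
  expect_equal(e$terms[["wall"]], 0.5 * 100 * deg2rad(10)^2, tolerance = 1e-6)
  s2 <- chain4_system(coef = rep(0, 7), delta_deg = 10,
                      wall = build_clockwise_restraint(c(1, 2, 3, 4), 0, 100))
  expect_equal(evaluate_energy(s2$config, s2$topo, s2$ff)$terms[["wall"]], 0)
})

test_that("frequency validation pairs modes and sees parameter changes", {
  fxb <- fx_bundle("CYC_S0", "S0")
  full <- fit_qmdff(fxb$bundle, fxb$sub$topo)
  cmp <- validate_frequencies(full$ff, fxb$bundle, fxb$sub$topo)
  expect_equal(nrow(cmp), 30)
  expect_lt(max(cmp$abs_dev), 1)
  cmp_self <- validate_frequencies(fxb$sub$ff, fxb$bundle, fxb$sub$topo)
  expect_lt(max(cmp_self$abs_dev), 1e-3)
  # halving a local-mode force constant scales its frequency by 1/sqrt(2)
  k <- 4e5
  d1 <- diatomic_system(k = k, r0 = 0.1, r = 0.1)
  d2 <- diatomic_system(k = k / 2, r0 = 0.1, r = 0.1)
  f1 <- max(normal_modes(ff_hessian(d1$config, d1$topo, d1$ff),
                         rep(10, 2), d1$config$pos)$frequencies)
  f2 <- max(normal_modes(ff_hessian(d2$config, d2$topo, d2$ff),
                         rep(10, 2), d2$config$pos)$frequencies)
  expect_equal((f1 - f2) / f1, 1 - 1 / sqrt(2), tolerance = 1e-6)
})
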