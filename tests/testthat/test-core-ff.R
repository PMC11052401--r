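test_that("energy terms vanish at their reference values", {
  # harmonic bond at its equilibrium length
  d <- diatomic_system(k = 2e5, r0 = 0.1, r = 0.1)
  e <- evaluate_energy(d$config, d$topo, d$ff)
  expect_equal(e$terms[["bond"]], 0)
  # two neutral LJ particles at r = sigma sit at the 12-6 zero crossing
  p <- pair_system(eps = c(1, 1), sigma = c(0.3, 0.3), r = 0.3)
  expect_equal(evaluate_energy(p$config, p$topo, p$ff)$terms[["lj"]], 0,
               tolerance = 1e-12)
})

test_that("a 42 sin^2 torsion expressed as c0 = 21, c2 = -21 gives 42 kJ/mol at 90 degrees", {
  s <- chain4_system(coef = c(21, 0, -21, 0, 0, 0, 0), delta_deg = 90)
  e <- evaluate_energy(s$config, s$topo, s$ff)
  expect_equal(e$terms[["flexible_dihedral"]], 42, tolerance = 1e-10)
  # and the trans arrangement is the zero of that potential
  s0 <- chain4_system(delta_deg = 180)
  expect_equal(evaluate_energy(s0$config, s0$topo, s0$ff)$terms[["flexible_dihedral"]],
               0, tolerance = 1e-10)
})

test_that("the energy report total equals the sum of its terms", {
  ts <- build_teacher_system("CYC_S0", "water", 8, seed = 2)
  cfg <- ts$config
  e <- evaluate_energy(cfg, ts$topology, ts$ff$S0, cutoff = 0.4)
  expect_equal(e$total, sum(e$terms), tolerance = 1e-9)
})

test_that("analytic forces match central differences on random configurations", {
  fixtures <- list(
    gas = {
      ts <- build_teacher_system("CYC_S0")
      list(topo = ts$topology, ff = ts$ff$S0, pos = ts$config$pos, box = 0,
           cutoff = 0)
    },
    solvated = {
      ts <- build_teacher_system("PYR_S1", "water", 16, seed = 4)
      list(topo = ts$topology, ff = ts$ff$S1, pos = ts$config$pos,
           box = ts$config$box, cutoff = 0.4)
    },
    charged_pair = {
      p <- pair_system(q = c(0.5, -0.3), eps = c(0.8, 0.4),
                       sigma = c(0.3, 0.32), r = 0.25)
      list(topo = p$topo, ff = p$ff, pos = p$config$pos, box = 0, cutoff = 0)
    })
  set.seed(101)
  h <- 1e-6
  for (fxn in names(fixtures)) {
    f <- fixtures[[fxn]]
    n <- nrow(f$pos)
    worst <- 0
    for (rep in 1:100) {
      pos <- f$pos + matrix(rnorm(3 * n, sd = 0.003), n, 3)
      cfg <- system_configuration(pos, box = f$box)
      fa <- evaluate_forces(cfg, f$topo, f$ff, cutoff = f$cutoff,
                            coulomb = "reaction_field")
      fd <- matrix(0, n, 3)
      for (a in seq_len(n)) for (dim in 1:3) {
        pp <- pos; pp[a, dim] <- pp[a, dim] + h
        pm <- pos; pm[a, dim] <- pm[a, dim] - h
        fd[a, dim] <- -(evaluate_energy(system_configuration(pp, box = f$box),
                                        f$topo, f$ff, f$cutoff,
                                        "reaction_field")$total -
                        evaluate_energy(system_configuration(pm, box = f$box),
                                        f$topo, f$ff, f$cutoff,
                                        "reaction_field")$total) / (2 * h)
      }
      worst <- max(worst, max(abs(fa - fd)) / max(abs(fa)))
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("forces obey Newton's third law and sum to zero", {
  p <- pair_system(q = c(0.4, 0.4), r = 0.25)
  f <- evaluate_forces(p$config, p$topo, p$ff)
  expect_equal(f[1, ], -f[2, ])
  expect_gt(f[2, 1], 0)  # like charges repel along +x
  ts <- build_teacher_system("CYC_S0")
  cfg <- ts$config
  cfg$pos <- cfg$pos + matrix(rnorm(36, sd = 0.002), 12, 3)
  ff <- evaluate_forces(cfg, ts$topology, ts$ff$S0)
  expect_lt(max(abs(colSums(ff))), 1e-8)
})

test_that("intramolecular energies are invariant under rigid translation and rotation", {
  ts <- build_teacher_system("CYC_S1")
  set.seed(7)
  cfg <- ts$config
  cfg$pos <- cfg$pos + matrix(rnorm(36, sd = 0.005), 12, 3)
  e0 <- evaluate_energy(cfg, ts$topology, ts$ff$S1)$total
  shifted <- cfg
  shifted$pos <- sweep(cfg$pos, 2, c(-1.3, 0.7, 2.1), "+")
  expect_equal(evaluate_energy(shifted, ts$topology, ts$ff$S1)$total, e0,
               tolerance = 1e-9 / max(1, abs(e0)))
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- cfg
  rotated$pos <- cfg$pos %*% t(R)
  expect_equal(evaluate_energy(rotated, ts$topology, ts$ff$S1)$total, e0,
               tolerance = 1e-9 / max(1, abs(e0)))
})

test_that("dihedral angles follow the IUPAC convention and sign", {
  p <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(compute_dihedral(p, 1, 2, 3, 4), 180)
  p[4, ] <- c(1, 1, 0)
  expect_equal(compute_dihedral(p, 1, 2, 3, 4), 0)
  p[4, ] <- c(1, -0.5, 0.5)
  phi <- compute_dihedral(p, 1, 2, 3, 4)
  mirr <- p %*% diag(c(1, 1, -1))
  expect_equal(compute_dihedral(mirr, 1, 2, 3, 4), -phi)
  expect_error(compute_dihedral(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                      c(3, 1, 0)), 1, 2, 3, 4),
               "degenerate")
  expect_error(compute_dihedral(p, 1, 2, 2, 4), "distinct")
})

test_that("torsion terms are periodic in the dihedral", {
  for (delta in c(-170, 10, 95)) {
    a <- chain4_system(delta_deg = delta)
    b <- chain4_system(delta_deg = delta + 360)
    ea <- evaluate_energy(a$config, a$topo, a$ff)$terms[["flexible_dihedral"]]
    eb <- evaluate_energy(b$config, b$topo, b$ff)$terms[["flexible_dihedral"]]
    expect_equal(ea, eb, tolerance = 1e-12)
  }
})

test_that("the force-field Hessian is symmetric and matches the analytic diatomic block", {
  d <- diatomic_system(k = 2e5, r0 = 0.1, r = 0.1)
  H <- ff_hessian(d$config, d$topo, d$ff)
  # along the bond axis (x): curvature +k on the diagonal, -k coupling
  expect_equal(H[1, 1], 2e5, tolerance = 1e-6)
  expect_equal(H[1, 4], -2e5, tolerance = 1e-6)
  expect_equal(H[4, 4], 2e5, tolerance = 1e-6)
  ts <- build_teacher_system("CYC_S0")
  cfg <- ts$config
  cfg$pos <- cfg$pos + matrix(rnorm(36, sd = 0.002), 12, 3)
  Hc <- ff_hessian(cfg, ts$topology, ts$ff$S0)
  expect_lt(norm(Hc - t(Hc), "F") / norm(Hc, "F"), 1e-8)
})

test_that("teacher Hessians agree between the descriptor generator and ff_hessian", {
  ts <- build_teacher_system("CYC_S0")
  gh <- generate_hessian(ts, "S0")
  sub <- qmdff:::.solute_subsystem(ts, "S0")
  H2 <- ff_hessian(system_configuration(gh$geometry), sub$topo, sub$ff)
  expect_lt(max(abs(H2 - gh$hessian)) / max(abs(gh$hessian)), 1e-4)
})

test_that("normal modes reproduce the diatomic closed form and six rigid-body zeros", {
  k <- 4e5; m <- 12
  d <- diatomic_system(k = k, r0 = 0.12, mass = m, r = 0.12)
  H <- ff_hessian(d$config, d$topo, d$ff)
  nm <- normal_modes(H, rep(m, 2), d$config$pos)
  mu <- m / 2
  nu_expect <- sqrt(k / mu * 1e24) / (2 * pi * 2.99792458e10)
  expect_equal(max(nm$frequencies), nu_expect, tolerance = 1e-6)
  # nonlinear molecule at its minimum: exactly 6 near-zero modes
  ts <- build_teacher_system("PYR_S0")
  gh <- generate_hessian(ts, "S0")
  modes <- normal_modes(gh$hessian, ts$topology$atoms$mass[1:12], gh$geometry)
  expect_equal(sum(abs(modes$frequencies) < 1), 6)
  expect_true(all(modes$frequencies[-(1:6)] > 1))
  expect_error(normal_modes(matrix(0, 3, 4), 1), "square")
})

test_that("configuration errors are reported", {
  ts <- build_teacher_system("CYC_S0", "water", 8, seed = 3)
  expect_error(evaluate_energy(ts$config, ts$topology, ts$ff$S0,
                               cutoff = ts$config$box),
               "configuration error")
  bad <- ts$ff$S0
  bad$charges <- bad$charges[-1]
  expect_error(evaluate_energy(ts$config, ts$topology, bad))
})
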