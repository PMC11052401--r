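test_that("preset torsional barriers match their documented values", {
  dd <- seq(0, 180, 0.05)
  vprof <- function(cf) sapply(dd, function(x) sum(cf * cos((0:6) * deg2rad(x))))
  cyc <- build_teacher_system("CYC_S1")
  v <- vprof(cyc$ff$S1$flex_coef["delta4", ])
  expect_equal(max(v) - v[length(v)], 42, tolerance = 1e-9)
  pyr <- build_teacher_system("PYR_S1")
  v <- vprof(pyr$ff$S1$flex_coef["delta4", ])
  expect_equal(v[dd == 90], -20, tolerance = 1e-9)        # funnel depth
  expect_equal(max(v[dd >= 90]) - v[length(v)], 7, tolerance = 1e-5)
  v3p <- vprof(pyr$ff$S0$flex_coef["delta3", ])
  expect_equal(v3p[dd == 90] - v3p[1], 19, tolerance = 1e-9)
  v3c <- vprof(cyc$ff$S0$flex_coef["delta3", ])
  expect_equal(max(v3c) - min(v3c), 23, tolerance = 1e-9)
})

test_that("per-state charges carry the documented O2 steps and conserve total charge", {
  cyc <- build_teacher_system("CYC_S0")
  o2 <- select_atoms(cyc$topology, "O2")
  expect_equal(generate_state_charges(cyc, "S0")[o2], -0.71)
  expect_equal(generate_state_charges(cyc, "S1")[o2], -0.63)
  pyr <- build_teacher_system("PYR_S0")
  o2p <- select_atoms(pyr$topology, "O2")
  expect_equal(generate_state_charges(pyr, "S0")[o2p], -0.74)
  expect_equal(generate_state_charges(pyr, "S1")[o2p], -0.66)
  for (t in list(cyc, pyr))
    expect_equal(sum(generate_state_charges(t, "S0")),
                 sum(generate_state_charges(t, "S1")), tolerance = 1e-12)
})

test_that("solvent boxes are neutral, at liquid density, without clashes", {
  for (kind in c("water", "ethanol_like", "acetonitrile_like")) {
    ts <- build_teacher_system("CYC_S0", kind, 16, seed = 5)
    expect_equal(nrow(ts$config$pos), 12 + 48)
    q <- ts$ff$S0$charges
    for (mid in unique(ts$topology$atoms$mol[ts$topology$atoms$role == "solvent"]))
      expect_lt(abs(sum(q[ts$topology$atoms$mol == mid])), 1e-10)
    # no hard overlap on the lattice start
    d <- as.matrix(dist(ts$config$pos))
    mol <- ts$topology$atoms$mol
    inter <- d[outer(mol, mol, "!=")]
    expect_gt(min(inter), 0.08)
  }
  expect_error(build_teacher_system("CYC_S0", "oil", 10), "should be one of")
  expect_error(build_teacher_system("XYZ_S0"))
  expect_error(build_teacher_system("CYC_S0", "water", -3), "n_solvent")
})

test_that("generate_hessian converges to a true minimum", {
  ts <- build_teacher_system("CYC_S1")
  gh <- generate_hessian(ts, "S1")
  expect_lt(gh$grad_rms, 1e-6)
  ev <- eigen(gh$hessian, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(sum(ev > 1e-3), 3 * 12 - 6)
})

test_that("relaxed scans hit the requested grid, are min-referenced and exact for the teacher", {
  ts <- build_teacher_system("CYC_S1")
  sc <- relaxed_scan(ts, "S1", "delta4", seq(0, 180, 15))
  expect_length(sc$angle, 13)
  expect_equal(min(sc$energy), 0)
  # torsion decoupled from all other internals: profile equals V exactly
  expect_lt(max(abs(sc$energy - 42 * sin(deg2rad(sc$angle))^2)), 1e-8)
  expect_error(relaxed_scan(ts, "S1", "delta4", c(0, 30, 30)), "increasing")
  expect_error(relaxed_scan(ts, "S1", "nosuch"), "flexible")
})

test_that("relaxed scans are invariant under rigid rotation of the start geometry", {
  ts <- build_teacher_system("PYR_S0")
  grid <- seq(0, 180, 30)
  a <- relaxed_scan(ts, "S0", "delta3", grid)
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  start <- qmdff:::.chromophore_def()$pos %*% t(R)
  b <- relaxed_scan(ts, "S0", "delta3", grid, start = start)
  expect_equal(a$energy, b$energy, tolerance = 1e-7)
})

test_that("mock vertical transitions behave like a bright planar transition", {
  ts <- build_teacher_system("CYC_S0")
  same <- ts
  same$ff$S1 <- ts$ff$S0
  tr <- mock_vertical_transitions(ts$config, same, offset_eV = 3.2)
  expect_equal(tr$energy_ev, 3.2)
  # oscillator strength vanishes at the 90-degree twist
  sub <- qmdff:::.solute_subsystem(ts, "S0")
  quad <- sub$topo$flexible_dihedrals["delta4", ]
  tail <- qmdff:::.dihedral_tail(sub$topo, quad)
  twisted <- ts$config
  twisted$pos <- qmdff:::.set_dihedral(ts$config$pos, quad, tail, 90)
  tr90 <- mock_vertical_transitions(twisted, ts, f0 = 0.8)
  expect_equal(tr90$strength, 0, tolerance = 1e-20)
  # variational ordering: gap at the S0 minimum >= gap at the S1 minimum
  ts1 <- build_teacher_system("PYR_S1")
  g0 <- generate_hessian(ts1, "S0")
  g1 <- generate_hessian(ts1, "S1")
  gap <- function(geom) vertical_gap(system_configuration(geom),
    qmdff:::.solute_subsystem(ts1, "S0")$topo,
    qmdff:::.solute_subsystem(ts1, "S0")$ff,
    qmdff:::.solute_subsystem(ts1, "S1")$ff)
  expect_gte(gap(g0$geometry), gap(g1$geometry))
})

test_that("descriptor bundles are well-formed and noise injection is controlled", {
  b <- fx_bundle("CYC_S0", "S0")$bundle
  expect_equal(nrow(b$hessian), 36)
  expect_lt(max(abs(b$hessian - t(b$hessian))), 1e-8)
  for (p in b$profiles) expect_equal(min(p$energy), 0)

  expect_identical(add_descriptor_noise(b, 0, 0, seed = 3), b)
  n1 <- add_descriptor_noise(b, sigma_hessian = 1, sigma_scan = 0.1, seed = 4)
  n2 <- add_descriptor_noise(b, sigma_hessian = 1, sigma_scan = 0.1, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1$hessian, b$hessian))
  expect_lt(max(abs(n1$hessian - t(n1$hessian))), 1e-12)
  dev <- n1$hessian - b$hessian
  expect_equal(var(as.vector(dev)), 1, tolerance = 0.1)
  expect_error(add_descriptor_noise(b, -1, 0), "sigma")
})

test_that("all teacher presets run stable gas-phase microcanonical dynamics", {
  for (preset in c("CYC_S0", "CYC_S1", "PYR_S0", "PYR_S1")) {
    st <- substr(preset, 5, 6)
    ts <- build_teacher_system(preset)
    cfg <- ts$config
    cfg$vel <- maxwell_velocities(ts$topology, 300, 21)
    stn <- integrator_settings(dt = 1e-4, thermostat = "none", cutoff = 0,
                               com_interval = 0)
    tr <- run_md(cfg, ts$topology, ts$ff[[st]], stn, 100000, log_every = 2000)
    et <- tr$log$epot + tr$log$ekin
    expect_true(all(is.finite(et)))
    expect_lt(max(abs(et - et[1])) / 12, 0.02)
  }
})
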