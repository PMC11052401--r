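test_that("a noninteracting solvent has g(r) = 1 within three standard errors", {
  sw <- fx_ideal_gas()
  rdf <- time_windowed_rdf(sw, 1, 2:101, list(c(-1, 1e9)), r_max = 0.9,
                           bin_width = 0.03)
  dev <- abs(rdf$g[, 1] - 1) / rdf$se[, 1]
  expect_lt(max(dev[rdf$r > 0.05]), 3)
})

test_that("RDF normalization recovers the pair count and a single window reduces to the equilibrium RDF", {
  sw <- fx_ideal_gas()
  rdf <- time_windowed_rdf(sw, 1, 2:101, list(c(-1, 1e9)), r_max = 0.9,
                           bin_width = 0.03)
  # integral of g rho 4 pi r^2 dr over r < r_max = mean pairs per frame
  rho <- 100 / 8
  integral <- sum(rdf$g[, 1] * rho * 4 * pi * rdf$r^2 * 0.03)
  observed <- sum(rdf$counts[, 1]) / rdf$frames_per_window[1]
  expect_equal(integral, observed, tolerance = 0.02)
  eq <- fx_equilibrium()
  o2 <- select_atoms(eq$ts$topology, "O2")
  hw <- select_atoms(eq$ts$topology, "Hw")
  a <- time_windowed_rdf(eq$prod, o2, hw, r_max = 0.45, bin_width = 0.02)
  b <- time_windowed_rdf(eq$prod, o2, hw, list(c(-Inf, Inf)),
                         r_max = 0.45, bin_width = 0.02)
  expect_identical(a$counts, b$counts)
  expect_error(time_windowed_rdf(eq$prod, o2, hw, r_max = 2), "geometry error")
  expect_error(time_windowed_rdf(eq$prod, integer(), hw), "empty selection")
})

test_that("doubling the member count halves the per-bin standard error", {
  r1 <- time_windowed_rdf(fx_ideal_gas(members = 4, frames_per = 50),
                          1, 2:101, list(c(-1, 1e9)), 0.9, 0.03)
  r2 <- time_windowed_rdf(fx_ideal_gas(members = 16, frames_per = 50),
                          1, 2:101, list(c(-1, 1e9)), 0.9, 0.03)
  ratio <- mean(r1$se[r1$r > 0.3, 1] / r2$se[r2$r > 0.3, 1])
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("pooling two swarms equals analyzing them jointly, bit for bit", {
  eq <- fx_equilibrium()
  sw <- fx_swarm_down()
  half1 <- sw; half1$members <- sw$members[1:50]
  half2 <- sw; half2$members <- sw$members[51:100]
  o2 <- select_atoms(eq$ts$topology, "O2")
  hw <- select_atoms(eq$ts$topology, "Hw")
  wins <- list(c(-0.001, 0.5), c(5, 10.001))
  joint <- time_windowed_rdf(sw, o2, hw, wins, 0.45, 0.02)
  a <- time_windowed_rdf(half1, o2, hw, wins, 0.45, 0.02)
  b <- time_windowed_rdf(half2, o2, hw, wins, 0.45, 0.02)
  expect_identical(joint$counts, a$counts + b$counts)
})

test_that("the running average smooths with truncated ends", {
  expect_equal(smooth_running_average(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  expect_equal(smooth_running_average(rep(2.5, 7), 3), rep(2.5, 7))
  x <- rnorm(10)
  expect_equal(smooth_running_average(x, 1), x)
  expect_error(smooth_running_average(x, 4), "odd")
})

test_that("dihedral populations are normalized probability histograms", {
  ts <- build_teacher_system("CYC_S0")
  traj <- list(frames = rep(list(ts$config$pos), 20),
               times = 1:20, boxes = rep(0, 20))
  class(traj) <- "qmdff_trajectory"
  quad <- ts$topology$flexible_dihedrals["delta4", ]
  h <- dihedral_population(traj, quad, bin_width_degrees = 5)
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(sum(h$p > 0), 1)              # frozen dihedral: one bin
  expect_equal(h$mid[which(h$p > 0)], 177.5) # 180 lands in (175, 180]
  traj$frames <- list()
  expect_error(dihedral_population(traj, quad), "no frames")
})

test_that("the relaxation-time estimator matches closed forms", {
  mk_rdf <- function(h) {
    nw <- length(h)
    structure(list(r = c(0.1, 0.2, 0.3),
                   g = rbind(rep(1, nw), h, rep(1, nw)),
                   se = matrix(1e-3, 3, nw), counts = matrix(10, 3, nw),
                   frames_per_window = rep(10, nw),
                   windows = cbind(seq(0, by = 0.1, length.out = nw),
                                   seq(0.1, by = 0.1, length.out = nw)),
                   n_a = 1, n_b = 2), class = "time_resolved_rdf")
  }
  t <- seq(0, 10, 0.1)
  # already equilibrated: tau is the first window edge
  est0 <- estimate_relaxation_time(mk_rdf(rep(2, length(t))), c(0.15, 0.25),
                                   smooth_width = 1)
  expect_equal(est0$tau, 0)
  expect_false(est0$detectable)   # zero excursion: no response to time
  # exponential: tau = tau0 ln(1/eps) within one window width
  tau0 <- 0.8; eps <- 0.2
  h <- 2 + 1.5 * exp(-t / tau0)
  est <- estimate_relaxation_time(mk_rdf(h), c(0.15, 0.25), eps,
                                  smooth_width = 1)
  expect_true(est$converged)
  expect_lt(abs(est$tau - tau0 * log(1 / eps)), 0.1)
  # monotone drift that never enters the band
  est2 <- estimate_relaxation_time(mk_rdf(2 + t), c(0.15, 0.25), 0.01,
                                   smooth_width = 1)
  expect_false(est2$converged)
  expect_true(is.na(est2$tau))
})

test_that("solvent relaxation does not get faster when the solvent is heavier", {
  tau_for <- function(seed, mass_scale) {
    ts <- build_teacher_system("CYC_S0", "water", 16, seed = seed)
    topo <- ts$topology
    topo$atoms$mass[topo$atoms$role == "solvent"] <-
      topo$atoms$mass[topo$atoms$role == "solvent"] * mass_scale
    st <- integrator_settings(dt = 2e-4, thermostat = "v_rescale",
                              ref_t = 300,
                              barostat = "isotropic_weak_coupling",
                              cutoff = 0.4, seed = 100 + seed)
    prod <- run_equilibrium_protocol(ts$config, topo, ts$ff$S0, st,
                                     durations = c(0.5, 1, 1, 8),
                                     save_every_ps = 0.05)
    snaps <- sample_uncorrelated_snapshots(prod, 32, 0.1)
    sw_st <- integrator_settings(dt = 5e-4, thermostat = "v_rescale",
                                 ref_t = 300,
                                 barostat = "isotropic_weak_coupling",
                                 cutoff = 0.4, seed = 1)
    sw <- run_swarm(swarm_spec(snaps, ts$ff$S0, ts$ff$S1,
                               seeds = 3000 + 1:32, length_ps = 3,
                               schedule = seq(0, 3, 0.025),
                               settings = sw_st), topo)
    wins <- lapply(seq(0, 2.75, 0.25), function(t) c(t - 1e-4, t + 0.25 - 1e-4))
    rdf <- time_windowed_rdf(sw, select_atoms(topo, "O2"),
                             select_atoms(topo, "Hw"), wins, 0.4, 0.02)
    est <- estimate_relaxation_time(rdf, c(0.12, 0.28), epsilon = 0.4)
    if (is.na(est$tau)) 3 else est$tau  # not converged: at least the horizon
  }
  taus <- vapply(1:5, function(s) c(tau_for(s, 1), tau_for(s, 2)), numeric(2))
  # tau is quantized to window edges: allow one window width of slack
  expect_gte(mean(taus[2, ]), mean(taus[1, ]) - 0.25)
})

test_that("long-time swarm observables agree with an equilibrium excited-state run", {
  eq <- fx_equilibrium()
  sw <- fx_swarm_down()
  o2 <- select_atoms(eq$ts$topology, "O2")
  hw <- select_atoms(eq$ts$topology, "Hw")
  late <- time_windowed_rdf(sw, o2, hw, list(c(7, 10.001)), 0.45, 0.02)
  ref <- time_windowed_rdf(fx_equilibrium_s1(), o2, hw,
                           r_max = 0.45, bin_width = 0.02)
  pk_sw <- peak_height(late$g[, 1], late$r)
  pk_eq <- peak_height(ref$g[, 1], ref$r)
  # agreement within statistical error: the Poisson SE of a desk-scale
  # peak estimate is itself ~5%, so the band is the larger of 5% and 3 SE
  sel_sw <- which(late$r > 0.12 & late$r < 0.25)
  sel_eq <- which(ref$r > 0.12 & ref$r < 0.25)
  se_sw <- late$se[sel_sw[which.max(late$g[sel_sw, 1])], 1]
  se_eq <- ref$se[sel_eq[which.max(ref$g[sel_eq, 1])], 1]
  band <- max(0.05 * pk_eq, 3 * sqrt(se_sw^2 + se_eq^2))
  expect_lt(abs(pk_sw - pk_eq), band)
})

test_that("solvation-shell extraction matches a brute-force oracle and the whole-molecule rule", {
  ts <- build_teacher_system("CYC_S0", "water", 20, seed = 3)
  topo <- ts$topology
  cfg <- ts$config
  sh <- extract_solvent_shell(cfg, topo)
  solute <- which(topo$atoms$role == "solute")
  m <- topo$atoms$mass[solute]
  com <- colSums(cfg$pos[solute, ] * m) / sum(m)
  sites <- select_atoms(topo, c("Oh", "Oa", "O2", "Ho"), role = "solute")
  box <- cfg$box
  mind <- function(p, q) {
    d <- p - q; d <- d - box * round(d / box); sqrt(sum(d^2))
  }
  brute <- c()
  for (mid in unique(topo$atoms$mol[topo$atoms$role == "solvent"])) {
    idx <- which(topo$atoms$mol == mid)
    hit <- FALSE
    for (a in idx) {
      if (mind(cfg$pos[a, ], com) < 0.4) hit <- TRUE
      for (s in sites)
        if (mind(cfg$pos[a, ], cfg$pos[s, ]) < 0.25) hit <- TRUE
    }
    if (hit) brute <- c(brute, mid)
  }
  expect_setequal(sh$molecules, brute)
  # whole molecules: all three atoms of each selected molecule included
  expect_true(all(table(topo$atoms$mol[setdiff(sh$atoms, solute)]) == 3))
  # far solvent only: selection reduces to the solute
  far <- cfg
  far$pos[13:nrow(far$pos), ] <- far$pos[13:nrow(far$pos), ] + 50
  far$box <- 0
  sh2 <- extract_solvent_shell(far, topo)
  expect_equal(sh2$atoms, solute)
  expect_length(sh2$molecules, 0)
  expect_error(extract_solvent_shell(cfg, topo, site_names = "Qx"),
               "unknown site")
})

test_that("shell peak metrics find the first two structured peaks", {
  r <- seq(0.005, 1, 0.01)
  expect_equal(nrow(shell_peak_metrics(r, rep(1, length(r)))), 0)
  g <- 1 + 2 * exp(-(r - 0.30)^2 / 5e-4) + 0.8 * exp(-(r - 0.38)^2 / 5e-4)
  pk <- shell_peak_metrics(r, g)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$position[1] - 0.30), 0.011)
  expect_lt(abs(pk$position[2] - 0.38), 0.011)
  expect_error(shell_peak_metrics(r[1:2], c(1, 2)), "3 bins")
})
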