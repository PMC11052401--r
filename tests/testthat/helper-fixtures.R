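# Shared fixtures, built lazily and cached for the whole test run.  All
# seeds are fixed so every fixture (and therefore every statistical
# assertion) is deterministic on one platform.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# -- small hand-built systems ------------------------------------------------

# diatomic with one harmonic bond
diatomic_system <- function(k = 2e5, r0 = 0.1, mass = 10, q = c(0, 0),
                            eps = c(0, 0), sigma = c(0.3, 0.3), r = r0) {
  atoms <- data.frame(name = c("A", "B"), element = c("X", "X"),
                      mass = mass, mol = c(1L, 2L)[c(1, 1)],
                      moltype = "diatomic", role = "solute")
  atoms$mol <- 1L
  topo <- topology(atoms, rbind(c(1L, 2L)), matrix(integer(), 0, 3))
  ff <- forcefield_parameters("S0", k, r0, numeric(), numeric(),
                              charges = q, lj_eps = eps, lj_sigma = sigma)
  cfg <- system_configuration(rbind(c(0, 0, 0), c(r, 0, 0)))
  list(topo = topo, ff = ff, config = cfg)
}

# two free nonbonded particles (one-atom molecules)
pair_system <- function(q = c(0, 0), eps = c(0, 0), sigma = c(0.3, 0.3),
                        r = 0.3, box = 0) {
  atoms <- data.frame(name = c("A", "B"), element = c("X", "X"),
                      mass = 10, mol = c(1L, 2L), moltype = "mono",
                      role = "solute")
  topo <- topology(atoms, matrix(integer(), 0, 2), matrix(integer(), 0, 3))
  ff <- forcefield_parameters("S0", numeric(), numeric(), numeric(),
                              numeric(), charges = q, lj_eps = eps,
                              lj_sigma = sigma)
  cfg <- system_configuration(rbind(c(0, 0, 0), c(r, 0, 0)), box = box)
  list(topo = topo, ff = ff, config = cfg)
}

# 4-atom chain with one flexible dihedral (for torsion-term checks)
chain4_system <- function(coef = c(21, 0, -21, 0, 0, 0, 0),
                          delta_deg = 180, wall = NULL) {
  atoms <- data.frame(name = c("A", "B", "C", "D"), element = "X",
                      mass = 12, mol = 1L, moltype = "chain", role = "solute",
                      stringsAsFactors = FALSE)
  topo <- topology(atoms, rbind(c(1, 2), c(2, 3), c(3, 4)),
                   rbind(c(1, 2, 3), c(2, 3, 4)),
                   flexible_dihedrals = rbind(delta = c(1L, 2L, 3L, 4L)),
                   nb_policy = list(chain = list(mode = "exclude_all",
                                                 fudge_lj = 0, fudge_q = 0)))
  ff <- forcefield_parameters("S0", rep(2e5, 3), rep(0.15, 3),
                              rep(400, 2), rep(110, 2),
                              flex_coef = matrix(coef, 1),
                              charges = rep(0, 4), lj_eps = rep(0, 4),
                              lj_sigma = rep(0.3, 4), wall = wall)
  th <- deg2rad(180 - 110)
  pos <- rbind(c(0, 0, 0), c(0.15, 0, 0),
               c(0.15 + 0.15 * cos(th), 0.15 * sin(th), 0))
  posD <- qmdff:::.place_atom(pos[3, ], pos[2, ], pos[1, ], 0.15, 110, delta_deg)
  pos <- rbind(pos, posD)
  cfg <- system_configuration(pos)
  list(topo = topo, ff = ff, config = cfg)
}

# Lennard-Jones fluid (argon-like), one-atom molecules on a lattice
lj_fluid_system <- function(n = 125, density = 21.1, eps = 0.998,
                            sigma = 0.3405, mass = 39.948) {
  box <- (n / density)^(1 / 3)
  atoms <- data.frame(name = "Ar", element = "Ar", mass = mass,
                      mol = seq_len(n), moltype = "lj", role = "solvent")
  topo <- topology(atoms, matrix(integer(), 0, 2), matrix(integer(), 0, 3))
  ff <- forcefield_parameters("S0", numeric(), numeric(), numeric(),
                              numeric(), charges = rep(0, n),
                              lj_eps = rep(eps, n), lj_sigma = rep(sigma, n))
  m <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m)))[seq_len(n), ]
  pos <- (g - 0.5) * box / m
  list(topo = topo, ff = ff, config = system_configuration(pos, box = box))
}

# wrap a list of snapshots as a t = 0 swarm (one frame per member)
snapshots_as_swarm <- function(snaps) {
  structure(list(members = lapply(snaps, function(s)
    list(frames = list(s$pos), times = 0, boxes = s$box)),
    schedule = 0, seeds = seq_along(snaps),
    failed = rep(FALSE, length(snaps)), errors = character()),
    class = "trajectory_swarm")
}

peak_height <- function(g, r, lo = 0.12, hi = 0.25) {
  max(smooth_running_average(g)[r > lo & r < hi])
}

# -- heavy shared fixtures ---------------------------------------------------

# equilibrium S0 production of the solvated chromophore (24 waters) plus
# 100 uncorrelated snapshots; the source for all swarm-based fixtures
fx_equilibrium <- function() fx("equilibrium", function() {
  ts <- build_teacher_system("CYC_S0", "water", 24, seed = 17)
  st <- integrator_settings(dt = 2e-4, thermostat = "v_rescale", ref_t = 300,
                            barostat = "isotropic_weak_coupling",
                            cutoff = 0.45, seed = 17)
  prod <- run_equilibrium_protocol(ts$config, ts$topology, ts$ff$S0, st,
                                   durations = c(0.5, 2, 4, 20),
                                   save_every_ps = 0.05)
  snaps <- sample_uncorrelated_snapshots(prod, 100, 0.1)
  list(ts = ts, prod = prod, snaps = snaps, settings = st)
})

fx_swarm_settings <- function()
  integrator_settings(dt = 5e-4, thermostat = "v_rescale", ref_t = 300,
                      barostat = "isotropic_weak_coupling", cutoff = 0.45,
                      seed = 1)

fx_swarm_schedule <- function() c(seq(0, 1, 0.025), seq(1.25, 10, 0.25))

# S0 -> S1 switch swarm (O2 charge -0.71 -> -0.63)
fx_swarm_down <- function() fx("swarm_down", function() {
  eq <- fx_equilibrium()
  spec <- swarm_spec(eq$snaps, eq$ts$ff$S0, eq$ts$ff$S1,
                     seeds = 1000 + seq_along(eq$snaps), length_ps = 10,
                     schedule = fx_swarm_schedule(),
                     settings = fx_swarm_settings())
  run_swarm(spec, eq$ts$topology)
})

# mirrored charge step (O2 charge -0.71 -> -0.79), same everything else
fx_swarm_up <- function() fx("swarm_up", function() {
  eq <- fx_equilibrium()
  topo <- eq$ts$topology
  mir <- eq$ts$ff$S1
  mir$charges[select_atoms(topo, "O2")] <- -0.79
  mir$charges[select_atoms(topo, "C2")] <- -0.21 + 0.79
  spec <- swarm_spec(eq$snaps, eq$ts$ff$S0, mir,
                     seeds = 2000 + seq_along(eq$snaps), length_ps = 10,
                     schedule = fx_swarm_schedule(),
                     settings = fx_swarm_settings())
  run_swarm(spec, topo)
})

# independent equilibrium run on the S1 surface with the same integrator
# settings as the swarm (long-time consistency reference)
fx_equilibrium_s1 <- function() fx("equilibrium_s1", function() {
  eq <- fx_equilibrium()
  st <- fx_swarm_settings()
  st$seed <- 99L
  run_equilibrium_protocol(eq$ts$config, eq$ts$topology, eq$ts$ff$S1, st,
                           durations = c(0.5, 2, 2, 40),
                           save_every_ps = 0.05)
})

# chromophore + 64 flexible waters, 0.1 fs step: short NVT settle then
# 10 ps NVE
fx_nve <- function() fx("nve", function() {
  ts <- build_teacher_system("CYC_S0", "water", 64, seed = 11)
  cfg <- ts$config
  cfg$vel <- maxwell_velocities(ts$topology, 300, 11)
  stt <- integrator_settings(dt = 1e-4, thermostat = "v_rescale",
                             ref_t = 300, cutoff = 0.6,
                             coulomb = "reaction_field", seed = 11)
  settle <- run_md(cfg, ts$topology, ts$ff$S0, stt, 5000, log_every = 0)
  stn <- integrator_settings(dt = 1e-4, thermostat = "none", cutoff = 0.6,
                             coulomb = "reaction_field", com_interval = 0)
  nve <- run_md(settle$final, ts$topology, ts$ff$S0, stn, 100000,
                log_every = 500)
  list(ts = ts, nve = nve)
})

# 50 ps NVT Lennard-Jones fluid at 300 K under stochastic velocity rescaling
fx_lj_nvt <- function() fx("lj_nvt", function() {
  s <- lj_fluid_system()
  cfg <- s$config
  cfg$vel <- maxwell_velocities(s$topo, 300, 5)
  st <- integrator_settings(dt = 2e-3, thermostat = "v_rescale",
                            ref_t = 300, tau_t = 0.2, cutoff = 0.85, seed = 9)
  tr <- run_md(cfg, s$topo, s$ff, st, 25000, log_every = 10,
               save_every = 1000)
  list(sys = s, traj = tr)
})

# 64-water NPT production at a longer stride: the density-stationarity
# check needs this box size (a 24-water cell has ~4% natural density
# fluctuation, larger than the 3% stationarity band)
fx_npt64 <- function() fx("npt64", function() {
  ts <- build_teacher_system("CYC_S0", "water", 64, seed = 11)
  st <- integrator_settings(dt = 2e-4, thermostat = "v_rescale", ref_t = 300,
                            barostat = "isotropic_weak_coupling",
                            cutoff = 0.6, coulomb = "reaction_field",
                            seed = 11)
  run_equilibrium_protocol(ts$config, ts$topology, ts$ff$S0, st,
                           durations = c(0.5, 1, 3, 12), save_every_ps = 0.1)
})

# ideal-gas frame swarm for RDF normalization checks
fx_ideal_gas <- function(members = 1, frames_per = 200, n = 101, box = 2,
                         seed = 1) {
  set.seed(seed)
  mk <- function()
    list(frames = lapply(seq_len(frames_per), function(i)
           matrix(runif(3 * n, 0, box), n, 3)),
         times = (seq_len(frames_per) - 1) * 0.1,
         boxes = rep(box, frames_per))
  structure(list(members = lapply(seq_len(members), function(i) mk()),
                 schedule = 0, seeds = seq_len(members),
                 failed = rep(FALSE, members), errors = character()),
            class = "trajectory_swarm")
}

fx_bundle <- function(preset, state) {
  key <- paste0("bundle_", preset, "_", state)
  fx(key, function() {
    ts <- build_teacher_system(preset)
    list(ts = ts, sub = qmdff:::.solute_subsystem(ts, state),
         bundle = generate_descriptor_bundle(ts, state))
  })
}
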