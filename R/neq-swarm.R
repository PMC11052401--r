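#' Vertical-excitation force-field switch
#'
#' Mimics Franck-Condon photoexcitation: positions and velocities are kept
#' bit-identical while the chromophore's intramolecular parameters and
#' charges are replaced by the excited-state set.  Solvent parameters must
#' be identical across the two states.
#'
#' @param config a [system_configuration()].
#' @param topo shared [topology()].
#' @param ff_S0,ff_S1 ground- and excited-state [forcefield_parameters()].
#' @return list with `config` (unchanged) and `ff` (the active S1 set).
#' @export
switch_state <- function(config, topo, ff_S0, ff_S1) {
  .check_switch_compatible(topo, ff_S0, ff_S1)
  list(config = config, ff = ff_S1)
}

.check_switch_compatible <- function(topo, ff_S0, ff_S1) {
  if (length(ff_S0$charges) != length(ff_S1$charges) ||
      length(ff_S0$bond_k) != length(ff_S1$bond_k))
    stop("structural error: state parameter sets have mismatched sizes")
  solvent <- topo$atoms$role == "solvent"
  if (any(ff_S0$charges[solvent] != ff_S1$charges[solvent]) ||
      any(ff_S0$lj_eps[solvent] != ff_S1$lj_eps[solvent]) ||
      any(ff_S0$lj_sigma[solvent] != ff_S1$lj_sigma[solvent]))
    stop("structural error: solvent parameters differ between states")
}

#' Vertical energy gap between two electronic states
#'
#' (E_S1 - E_S0) at fixed nuclear coordinates, converted to eV, plus an
#' electronic offset.
#'
#' @inheritParams switch_state
#' @param offset_eV electronic offset (eV).
#' @param cutoff,coulomb nonbonded options (see [evaluate_energy()]).
#' @return gap in eV.
#' @export
vertical_gap <- function(config, topo, ff_S0, ff_S1, offset_eV = 0,
                         cutoff = 0, coulomb = "cut_shift") {
  .check_switch_compatible(topo, ff_S0, ff_S1)
  e0 <- evaluate_energy(config, topo, ff_S0, cutoff, coulomb)$total
  e1 <- evaluate_energy(config, topo, ff_S1, cutoff, coulomb)$total
  kjmol2ev(e1 - e0) + offset_eV
}

#' Default non-equilibrium frame schedule
#'
#' Dense at early times to resolve sub-picosecond solvent response, sparse
#' later: every 5 fs below 2 ps, every 1 ps below 100 ps, every 10 ps
#' beyond.
#'
#' @param length_ps propagation length (ps).
#' @return sorted vector of frame times (ps), starting at 0.
#' @export
default_frame_schedule <- function(length_ps) {
  t1 <- seq(0, min(2, length_ps), by = 5e-3)
  t2 <- if (length_ps > 2) seq(3, min(100, length_ps), by = 1) else numeric()
  t3 <- if (length_ps > 100) seq(110, length_ps, by = 10) else numeric()
  unique(c(t1, t2, t3))
}

#' Specification of a non-equilibrium trajectory swarm
#'
#' @param snapshots list of initial [system_configuration()] (typically
#'   from [sample_uncorrelated_snapshots()]); their velocities are kept.
#' @param ff_S0,ff_S1 the two state parameter sets.
#' @param seeds one RNG seed per member (unique).
#' @param length_ps propagation length on the excited surface.
#' @param schedule frame times (ps) relative to the switch at t = 0.
#' @param settings an [integrator_settings()]; the thermostat/barostat
#'   machinery stays active after the switch (NPT by default, pass an NVT
#'   settings object to disable pressure coupling).
#' @export
swarm_spec <- function(snapshots, ff_S0, ff_S1, seeds, length_ps,
                       schedule = NULL, settings = integrator_settings()) {
  if (!length(snapshots)) stop("need at least one initial condition")
  if (length(seeds) != length(snapshots) || anyDuplicated(seeds))
    stop("seeds must be unique, one per member")
  if (is.null(schedule)) schedule <- default_frame_schedule(length_ps)
  schedule <- sort(unique(schedule))
  structure(list(snapshots = snapshots, ff_S0 = ff_S0, ff_S1 = ff_S1,
                 seeds = as.integer(seeds), length_ps = length_ps,
                 schedule = schedule, settings = settings),
            class = "swarm_spec")
}

#' Run a swarm of independent non-equilibrium trajectories
#'
#' Each member starts from its ground-state snapshot (coordinates and
#' velocities preserved across the switch), is propagated on the S1
#' surface with its own seed, and saves frames on the shared schedule.
#' Members are independent: results do not depend on execution order.  A
#' member that blows up is recorded as failed without aborting the others.
#'
#' @param spec a [swarm_spec()].
#' @param topo shared [topology()].
#' @return object of class `trajectory_swarm`: `members` (list with
#'   `frames`, `times`, `boxes` each), `schedule`, `seeds`, `failed`
#'   (logical), `errors`.
#' @export
run_swarm <- function(spec, topo) {
  .check_switch_compatible(topo, spec$ff_S0, spec$ff_S1)
  nst <- round(spec$length_ps / spec$settings$dt)
  save_steps <- unique(round(spec$schedule / spec$settings$dt))
  save_steps <- save_steps[save_steps >= 0 & save_steps <= nst]
  members <- vector("list", length(spec$snapshots))
  failed <- logical(length(members))
  errors <- character(length(members))
  for (i in seq_along(members)) {
    st <- spec$settings
    st$seed <- spec$seeds[i]
    snap <- spec$snapshots[[i]]
    snap$time <- 0
    res <- tryCatch({
      tr <- run_md(snap, topo, spec$ff_S1, st, nst,
                   save_steps = save_steps, log_every = 0,
                   store_velocities = FALSE)
      list(frames = tr$frames, times = tr$times, boxes = tr$boxes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      errors[i] <- conditionMessage(res)
    } else members[[i]] <- res
  }
  structure(list(members = members, schedule = spec$schedule,
                 seeds = spec$seeds, failed = failed,
                 errors = errors[failed]),
            class = "trajectory_swarm")
}

#' @export
print.trajectory_swarm <- function(x, ...) {
  cat("trajectory swarm:", length(x$members), "members (",
      sum(x$failed), "failed ),",
      length(x$schedule), "scheduled frames\n")
  invisible(x)
}

#' Coerce a single trajectory into a one-member swarm
#'
#' Lets equilibrium trajectories flow through the swarm-based analysis
#' functions (e.g. a single-window RDF).
#'
#' @param traj a [run_md()] trajectory.
#' @export
as_swarm <- function(traj) {
  structure(list(members = list(list(frames = traj$frames,
                                     times = traj$times - traj$times[1],
                                     boxes = traj$boxes)),
                 schedule = traj$times - traj$times[1],
                 seeds = traj$settings$seed, failed = FALSE,
                 errors = character()),
            class = "trajectory_swarm")
}
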