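#' Integrator and ensemble settings
#'
#' Velocity-Verlet propagation with optional stochastic velocity rescaling
#' (canonical sampling) and an isotropic weak-coupling barostat.  The
#' defaults follow the reference protocol: 0.1 fs time step (no bond
#' constraints anywhere in this package) and a 1.2 nm nonbonded cutoff;
#' desk-scale runs typically shrink the cutoff together with the box.
#'
#' @param dt time step (ps); default 1e-4 (0.1 fs).
#' @param thermostat `"none"` or `"v_rescale"`.
#' @param ref_t target temperature (K).
#' @param tau_t temperature coupling time (ps).
#' @param barostat `"none"` or `"isotropic_weak_coupling"`.
#' @param ref_p target pressure (bar).
#' @param tau_p pressure coupling time (ps).
#' @param compressibility isothermal compressibility (bar^-1).
#' @param cutoff nonbonded cutoff (nm); 0 disables.
#' @param coulomb Coulomb truncation scheme (see [evaluate_energy()]);
#'   `"reaction_field"` keeps pair forces continuous at the cutoff and is
#'   the default for dynamics.
#' @param lj_shift shift LJ potential to zero at the cutoff.
#' @param seed integer RNG seed for thermostat noise.
#' @param com_interval remove centre-of-mass motion every this many steps.
#' @param nstpcouple barostat period (steps).
#' @return list of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 1e-4, thermostat = c("none", "v_rescale"),
                                ref_t = 300, tau_t = 0.1,
                                barostat = c("none", "isotropic_weak_coupling"),
                                ref_p = 1, tau_p = 1,
                                compressibility = 4.5e-5,
                                cutoff = 1.2,
                                coulomb = c("reaction_field", "cut_shift", "cut"),
                                lj_shift = TRUE, seed = 1,
                                com_interval = 100, nstpcouple = 10) {
  thermostat <- match.arg(thermostat)
  barostat <- match.arg(barostat)
  coulomb <- match.arg(coulomb)
  stopifnot(dt > 0, cutoff >= 0, tau_t > dt, tau_p > dt)
  structure(list(dt = dt, thermostat = thermostat, ref_t = ref_t,
                 tau_t = tau_t, barostat = barostat, ref_p = ref_p,
                 tau_p = tau_p, compressibility = compressibility,
                 cutoff = cutoff, coulomb = coulomb, lj_shift = lj_shift,
                 seed = as.integer(seed), com_interval = com_interval,
                 nstpcouple = nstpcouple),
            class = "integrator_settings")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param topo a [topology()].
#' @param temperature target temperature (K).
#' @param seed RNG seed.
#' @param remove_com subtract the centre-of-mass velocity.
#' @return n x 3 velocity matrix (nm/ps).
#' @export
maxwell_velocities <- function(topo, temperature, seed = 1,
                               remove_com = TRUE) {
  set.seed(seed)
  m <- topo$atoms$mass
  v <- matrix(stats::rnorm(3 * length(m)), ncol = 3) *
    sqrt(.kB * temperature / m)
  if (remove_com) v <- sweep(v, 2, colSums(v * m) / sum(m))
  v
}

#' Single stochastic velocity-rescaling update
#'
#' Exposes one thermostat step: the kinetic energy relaxes toward the
#' canonical distribution through a deterministic exponential term plus a
#' Wiener noise term, and a single scaling factor is applied to all
#' velocities.  In the decoupled limit (tau -> Inf) the factor tends to 1.
#'
#' @param velocities n x 3 matrix (nm/ps).
#' @param masses atomic masses (amu).
#' @param target_T target temperature (K).
#' @param tau coupling time (ps).
#' @param dt time step (ps).
#' @param seed RNG seed for this update.
#' @param ndf number of degrees of freedom (default 3n - 3).
#' @return list with `velocities` (scaled) and `alpha` (the factor).
#' @export
v_rescale_step <- function(velocities, masses, target_T, tau, dt, seed = 1,
                           ndf = NULL) {
  K <- 0.5 * sum(masses * rowSums(velocities^2))
  if (K <= 0 && target_T > 0)
    stop("degenerate-state error: zero kinetic energy with nonzero target")
  if (is.null(ndf)) ndf <- 3 * nrow(velocities) - 3
  K0 <- 0.5 * ndf * .kB * target_T
  alpha <- if (is.infinite(tau)) 1 else
    .vrescale_alpha_cpp(K, K0, as.integer(ndf), tau, dt, as.integer(seed))
  list(velocities = alpha * velocities, alpha = alpha)
}

#' Propagate molecular dynamics
#'
#' @param config starting [system_configuration()].
#' @param topo a [topology()].
#' @param ff a [forcefield_parameters()] set.
#' @param settings an [integrator_settings()].
#' @param nsteps number of steps.
#' @param save_every frame-saving stride in steps (0: only first/last), or
#'   pass explicit `save_steps`.
#' @param save_steps integer vector of step indices at which to save.
#' @param log_every stride (steps) for the energy/temperature/pressure log.
#' @param posres optional list `list(k =, ref =)` with per-atom restraint
#'   constants (kJ mol^-1 nm^-2) and reference positions.
#' @param store_velocities keep per-frame velocities (needed when frames
#'   seed further runs).
#' @return object of class `qmdff_trajectory`: `frames` (list of position
#'   matrices), `vel_frames`, `times`, `boxes`, `log` (data.frame),
#'   `final` (configuration), `settings`.
#' @export
run_md <- function(config, topo, ff, settings, nsteps,
                   save_every = 0, save_steps = NULL, log_every = 100,
                   posres = NULL, store_velocities = TRUE) {
  .check_box_cutoff(config$box, settings$cutoff)
  packed <- .pack_ff(topo, ff, settings$cutoff, settings$coulomb,
                     settings$lj_shift)
  if (is.null(save_steps)) {
    save_steps <- if (save_every > 0) unique(c(0, seq(save_every, nsteps,
                                                      by = save_every)))
                  else c(0, nsteps)
  }
  opts <- list(
    dt = settings$dt, nsteps = as.double(nsteps),
    thermostat = if (settings$thermostat == "v_rescale") 1L else 0L,
    ref_T = settings$ref_t, tau_T = settings$tau_t,
    barostat = if (settings$barostat == "isotropic_weak_coupling") 1L else 0L,
    ref_P = settings$ref_p, tau_P = settings$tau_p,
    compressibility = settings$compressibility,
    nstpcouple = as.integer(settings$nstpcouple),
    com_interval = as.integer(settings$com_interval),
    seed = settings$seed,
    save_steps = as.double(sort(unique(save_steps))),
    log_interval = as.integer(log_every),
    time0 = config$time,
    remove_com_start = TRUE)
  if (!is.null(posres)) {
    opts$posres_k <- posres$k
    opts$posres_ref <- as.matrix(posres$ref)
  }
  r <- .md_run_cpp(config$pos, config$vel, topo$atoms$mass, config$box,
                   packed, opts)
  final <- system_configuration(r$pos, r$vel, r$box, r$time)
  structure(list(frames = r$frame_pos,
                 vel_frames = if (store_velocities) r$frame_vel else NULL,
                 times = r$frame_time, boxes = r$frame_box,
                 log = as.data.frame(r$log), final = final,
                 settings = settings),
            class = "qmdff_trajectory")
}

#' @export
print.qmdff_trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,",
      format(utils::tail(x$times, 1) - x$times[1], digits = 6), "ps span\n")
  invisible(x)
}

#' Three-step equilibration plus production
#'
#' Stage 1 equilibrates the solvent for a short time with the solute held
#' by stiff position restraints (k = 1000 kJ mol^-1 nm^-2); stage 2 is
#' unrestrained NVT; stage 3 NPT equilibration; stage 4 the NPT production
#' run, whose frames (with velocities) are returned.  Default durations
#' are desk-scale; the full-scale protocol (1 ps / 1 ns / 5 ns / 50 ns)
#' is obtained by passing those durations explicitly.
#'
#' @param config starting configuration (velocities drawn at `ref_t` if
#'   all zero).
#' @param topo,ff,settings as in [run_md()].
#' @param durations numeric vector of the four stage lengths (ps), named or
#'   in order restrained / nvt / npt / production.
#' @param save_every_ps production frame stride (ps).
#' @param posres_k solute restraint constant for stage 1.
#' @return the production [run_md()] trajectory; the preceding stages are
#'   attached as attribute `"equilibration_logs"`.
#' @export
run_equilibrium_protocol <- function(config, topo, ff, settings,
                                     durations = c(restrained = 1, nvt = 10,
                                                   npt = 50, production = 500),
                                     save_every_ps = NULL, posres_k = 1000) {
  stopifnot(length(durations) == 4)
  nst <- round(durations / settings$dt)
  if (all(config$vel == 0))
    config$vel <- maxwell_velocities(topo, settings$ref_t, settings$seed)
  solute <- topo$atoms$role == "solute"
  logs <- list()

  s1 <- settings; s1$thermostat <- "v_rescale"; s1$barostat <- "none"
  tr <- run_md(config, topo, ff, s1, nst[1], log_every = max(1, nst[1] %/% 20),
               posres = list(k = ifelse(solute, posres_k, 0),
                             ref = config$pos),
               save_every = 0, store_velocities = TRUE)
  logs$restrained <- tr$log

  s2 <- s1; s2$seed <- s1$seed + 1L
  tr <- run_md(tr$final, topo, ff, s2, nst[2],
               log_every = max(1, nst[2] %/% 50), save_every = 0)
  logs$nvt <- tr$log

  s3 <- s1; s3$barostat <- "isotropic_weak_coupling"; s3$seed <- s1$seed + 2L
  tr <- run_md(tr$final, topo, ff, s3, nst[3],
               log_every = max(1, nst[3] %/% 50), save_every = 0)
  logs$npt <- tr$log

  s4 <- s3; s4$seed <- s1$seed + 3L
  if (is.null(save_every_ps)) save_every_ps <- durations[4] / 200
  stride <- max(1, round(save_every_ps / settings$dt))
  prod <- run_md(tr$final, topo, ff, s4, nst[4], save_every = stride,
                 log_every = max(1, nst[4] %/% 200), store_velocities = TRUE)
  attr(prod, "equilibration_logs") <- logs
  prod
}

#' Uniformly spaced snapshots from a production trajectory
#'
#' Returns `n` frames at uniform stride ending at the final frame (so
#' `n = 1` gives the last frame), each carrying positions and velocities.
#'
#' @param traj a [run_md()] trajectory with stored velocities.
#' @param n number of snapshots.
#' @param min_spacing minimum time between snapshots (ps).
#' @return list of [system_configuration()].
#' @export
sample_uncorrelated_snapshots <- function(traj, n, min_spacing = 0) {
  nf <- length(traj$frames)
  if (is.null(traj$vel_frames))
    stop("trajectory was saved without velocities")
  stride <- nf %/% n
  if (stride < 1)
    stop("length error: need at least ", n, " frames, have ", nf)
  idx <- nf - stride * (n:1 - 1)
  if (n > 1) {
    spacing <- traj$times[idx[2]] - traj$times[idx[1]]
    if (spacing < min_spacing)
      stop("length error: snapshot spacing ", spacing,
           " ps below required ", min_spacing,
           " ps; extend the trajectory to at least ",
           n * min_spacing, " ps of saved frames")
  }
  lapply(idx, function(i)
    system_configuration(traj$frames[[i]], traj$vel_frames[[i]],
                         traj$boxes[i], traj$times[i]))
}
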