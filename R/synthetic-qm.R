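#' Synthetic QM backend: teacher systems with known potentials
#'
#' In place of electronic-structure calculations, this module generates all
#' QM-style descriptors (optimized geometries, Hessians, relaxed torsional
#' scans, per-state charges, vertical transitions) from analytically defined
#' "teacher" force fields whose parameters are known exactly.  The teacher
#' chromophore is a 12-atom planar conjugated toy with a hydroxyl donor
#' (Oh-Ho), two carbonyl-type acceptors (Cd=Oa and C2=O2), one flexible
#' aryl-type torsion (`delta3`) and one isomerizable double-bond torsion
#' (`delta4`).  Four presets are available:
#'
#' * `CYC_S0` / `CYC_S1`: aryl barrier 23 kJ/mol; the excited state carries
#'   a high 42 kJ/mol isomerization barrier (slow photoisomerization) and an
#'   O2 charge step -0.71 -> -0.63 e.
#' * `PYR_S0` / `PYR_S1`: aryl barrier 19 kJ/mol; the excited state reaches
#'   the conical-intersection funnel at 90 degrees (set at -20 kJ/mol) over
#'   a small 7 kJ/mol barrier, with an O2 charge step -0.74 -> -0.66 e.
#'
#' @name synthetic_qm
NULL

.presets <- c("CYC_S0", "CYC_S1", "PYR_S0", "PYR_S1")
.solvent_kinds <- c("none", "water", "ethanol_like", "acetonitrile_like")

# NeRF placement: atom bonded to A at distance r, with angle X-A-B = theta
# (deg) and dihedral X-A-B-C = phi (deg).  Only used with phi = 0/180 here,
# so the torsion sign convention never matters.
.place_atom <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  u <- A - B; u <- u / sqrt(sum(u^2))
  ab <- B - C
  n <- .cross3(ab, u); n <- n / sqrt(sum(n^2))
  m2 <- .cross3(n, u)
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  A + d[1] * u + d[2] * m2 + d[3] * n
}

# Planar 12-atom chromophore: geometry, topology blocks and the
# state-independent part of the teacher parameters.
.chromophore_def <- function() {
  nm <- c("Ca", "Cb", "Oh", "Ho", "Cc", "Cd", "Oa", "Ce", "Cf", "C2", "O2", "Hc")
  el <- c("C", "C", "O", "H", "C", "C", "O", "C", "C", "C", "O", "H")
  mass <- c(C = 12.011, O = 15.999, H = 1.008)[el]
  pos <- matrix(0, 12, 3, dimnames = list(nm, NULL))
  pos["Ca", ] <- c(0, 0, 0)
  pos["Cb", ] <- c(0.145, 0, 0)
  pos["Cc", ] <- pos["Cb", ] + 0.145 * c(cos(pi / 3), sin(pi / 3), 0)
  pos["Oh", ] <- .place_atom(pos["Cb", ], pos["Ca", ], pos["Cc", ], 0.136, 120, 180)
  pos["Ho", ] <- .place_atom(pos["Oh", ], pos["Cb", ], pos["Cc", ], 0.097, 108, 0)
  pos["Cd", ] <- .place_atom(pos["Cc", ], pos["Cb", ], pos["Ca", ], 0.148, 120, 180)
  pos["Ce", ] <- .place_atom(pos["Cd", ], pos["Cc", ], pos["Cb", ], 0.146, 120, 180)
  pos["Oa", ] <- .place_atom(pos["Cd", ], pos["Cc", ], pos["Cb", ], 0.123, 120, 0)
  pos["Cf", ] <- .place_atom(pos["Ce", ], pos["Cd", ], pos["Cc", ], 0.134, 120, 180)
  pos["C2", ] <- .place_atom(pos["Cf", ], pos["Ce", ], pos["Cd", ], 0.148, 120, 180)
  pos["O2", ] <- .place_atom(pos["C2", ], pos["Cf", ], pos["Ce", ], 0.122, 120, 0)
  pos["Hc", ] <- .place_atom(pos["C2", ], pos["Cf", ], pos["Ce", ], 0.110, 120, 180)

  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(5, 6), c(6, 7),
                 c(6, 8), c(8, 9), c(9, 10), c(10, 11), c(10, 12))
  bond_r0 <- c(0.145, 0.136, 0.097, 0.145, 0.148, 0.123,
               0.146, 0.134, 0.148, 0.122, 0.110)
  bond_k <- c(2.2e5, 2.6e5, 4.6e5, 2.2e5, 2.2e5, 4.0e5,
              2.2e5, 3.5e5, 2.2e5, 4.0e5, 3.0e5)
  angles <- rbind(c(1, 2, 3), c(1, 2, 5), c(3, 2, 5), c(2, 3, 4), c(2, 5, 6),
                  c(5, 6, 7), c(5, 6, 8), c(7, 6, 8), c(6, 8, 9),
                  c(8, 9, 10), c(9, 10, 11), c(9, 10, 12), c(11, 10, 12))
  angle_theta0 <- c(120, 120, 120, 108, 120, 120, 120, 120, 120, 120, 120, 120, 120)
  angle_k <- c(rep(450, 3), 350, rep(450, 9))
  # the last three are improper-style planarity terms: out-of-plane motion
  # at an sp2 centre held by 120-degree angles alone is only quartic, so a
  # proper-dihedral term supplies the harmonic restoring force
  stiff <- rbind(c(1, 2, 5, 6), c(5, 2, 3, 4), c(5, 6, 8, 9), c(8, 9, 10, 11),
                 c(3, 2, 5, 6), c(7, 6, 8, 9), c(12, 10, 9, 8))
  stiff_phi0 <- c(180, 0, 180, 0, 0, 0, 180)
  stiff_k <- c(35, 12, 35, 40, 40, 40, 40)
  flex <- rbind(delta3 = c(2, 5, 6, 8), delta4 = c(6, 8, 9, 10))
  lj_eps <- ifelse(el == "C", 0.30, ifelse(el == "O", 0.65, 0))
  lj_sigma <- ifelse(el == "C", 0.34, ifelse(el == "O", 0.30, 0.10))
  list(names = nm, elements = el, masses = unname(mass), pos = pos,
       bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
       angles = angles, angle_k = angle_k, angle_theta0 = angle_theta0,
       stiff = stiff, stiff_k = stiff_k, stiff_phi0 = stiff_phi0,
       flex = flex, lj_eps = lj_eps, lj_sigma = lj_sigma)
}

# Fourier rows (order 6) for the state/preset-specific flexible torsions
.flex_coef_preset <- function(preset) {
  fam <- substr(preset, 1, 3)
  state <- substr(preset, 5, 6)
  coef <- matrix(0, 2, 7, dimnames = list(c("delta3", "delta4"), NULL))
  B <- if (fam == "CYC") 23 else 19           # aryl barrier, kJ/mol
  coef["delta3", c(1, 3)] <- c(B / 2, -B / 2)  # B sin^2(delta)
  if (state == "S0") {
    coef["delta4", c(1, 3)] <- c(75, -75)      # 150 sin^2: rigid double bond
  } else if (fam == "CYC") {
    coef["delta4", c(1, 3)] <- c(21, -21)      # 42 sin^2: high barrier
  } else {
    # c0 + c2 cos2d + c4 cos4d with V(180) = 0, V(90) = -20 kJ/mol and a
    # local maximum 7 kJ/mol above the trans minimum
    c4 <- -(17 + sqrt(189)) / 4
    c2 <- 10
    c0 <- -10 - c4
    coef["delta4", c(1, 3, 5)] <- c(c0, c2, c4)
  }
  coef
}

.solute_charges <- function(preset) {
  fam <- substr(preset, 1, 3)
  state <- substr(preset, 5, 6)
  qO2 <- if (fam == "CYC") {
    if (state == "S0") -0.71 else -0.63
  } else {
    if (state == "S0") -0.74 else -0.66
  }
  q <- c(Ca = 0.10, Cb = 0.15, Oh = -0.55, Ho = 0.40, Cc = 0.10, Cd = 0.30,
         Oa = -0.40, Ce = -0.10, Cf = 0.11, C2 = -0.21 - qO2, O2 = qO2,
         Hc = 0.10)
  unname(q)
}

# Three-site solvent models (flexible bonds so that unconstrained dynamics
# at a short time step is meaningful).  Charges follow published-style
# 3-site models; the acetonitrile analogue is given a slight 170-degree
# equilibrium bend so the harmonic angle term stays regular.
.solvent_model <- function(kind) {
  switch(kind,
    water = list(
      names = c("Ow", "Hw", "Hw"), elements = c("O", "H", "H"),
      masses = c(15.999, 1.008, 1.008),
      q = c(-0.834, 0.417, 0.417),
      eps = c(0.63639, 0, 0), sigma = c(0.31506, 0.04, 0.04),
      bonds = rbind(c(1, 2), c(1, 3)), bond_k = c(4.6e5, 4.6e5),
      bond_r0 = c(0.09572, 0.09572),
      angles = rbind(c(2, 1, 3)), angle_k = 383, angle_theta0 = 104.52,
      density = 33.43),
    ethanol_like = list(
      names = c("Cet", "Oe", "He"), elements = c("C", "O", "H"),
      masses = c(29.062, 15.999, 1.008),
      q = c(0.265, -0.700, 0.435),
      eps = c(0.866, 0.711, 0), sigma = c(0.3775, 0.307, 0.04),
      bonds = rbind(c(1, 2), c(2, 3)), bond_k = c(2.6e5, 4.6e5),
      bond_r0 = c(0.143, 0.0945),
      angles = rbind(c(1, 2, 3)), angle_k = 380, angle_theta0 = 108.5,
      density = 10.32),
    acetonitrile_like = list(
      names = c("Me", "Cz", "Nz"), elements = c("C", "C", "N"),
      masses = c(15.035, 12.011, 14.007),
      q = c(0.269, 0.129, -0.398),
      eps = c(0.867, 0.415, 0.416), sigma = c(0.36, 0.34, 0.33),
      bonds = rbind(c(1, 2), c(2, 3)), bond_k = c(2.2e5, 6.0e5),
      bond_r0 = c(0.146, 0.117),
      angles = rbind(c(1, 2, 3)), angle_k = 300, angle_theta0 = 170,
      density = 11.52),
    stop("parameter error: unknown solvent kind '", kind, "'"))
}

# geometry of one solvent molecule, centred on its centre of mass
.solvent_geometry <- function(model) {
  g <- matrix(0, 3, 3)
  g[2, ] <- c(model$bond_r0[1], 0, 0)
  if (model$bonds[2, 1] == 1) {        # water: both H bonded to site 1
    a <- deg2rad(model$angle_theta0)
    g[3, ] <- model$bond_r0[2] * c(cos(a), sin(a), 0)
  } else {                             # chain: site3 bonded to site2
    a <- deg2rad(180 - model$angle_theta0)
    g[3, ] <- g[2, ] + model$bond_r0[2] * c(cos(a), sin(a), 0)
  }
  com <- colSums(g * model$masses) / sum(model$masses)
  sweep(g, 2, com)
}

#' Build a teacher system: toy chromophore plus optional solvent box
#'
#' Constructs the 12-atom chromophore with its exact teacher force fields
#' for both electronic states of the chosen preset family, optionally
#' soaked in a cubic box of a 3-site solvent placed on a lattice at the
#' solvent's liquid density.  Barrier heights of the preset torsional
#' potentials are asserted against their nominal values at build time.
#'
#' @param preset one of `"CYC_S0"`, `"CYC_S1"`, `"PYR_S0"`, `"PYR_S1"`
#'   (the family selects the parameter set; both states' force fields are
#'   always returned).
#' @param solvent_kind `"none"`, `"water"`, `"ethanol_like"` or
#'   `"acetonitrile_like"`.
#' @param n_solvent number of solvent molecules (>= 0).
#' @param box cubic box edge (nm); defaults to the edge that gives the
#'   solvent its liquid density around the solute.
#' @param seed RNG seed for solvent placement orientations.
#' @return an object of class `qmdff_teacher` with elements `topology`,
#'   `ff` (list with `S0` and `S1` [forcefield_parameters()]), `config`
#'   (a [system_configuration()] with zero velocities), `preset`,
#'   `solvent_kind`, `seed`.
#' @export
build_teacher_system <- function(preset, solvent_kind = "none",
                                 n_solvent = 0, box = NULL, seed = 1) {
  preset <- match.arg(preset, .presets)
  solvent_kind <- match.arg(solvent_kind, .solvent_kinds)
  if (n_solvent < 0) stop("parameter error: n_solvent must be >= 0")
  if (solvent_kind == "none") n_solvent <- 0
  fam <- substr(preset, 1, 3)
  ch <- .chromophore_def()
  ns <- if (n_solvent > 0) 3 * n_solvent else 0
  n <- 12 + ns

  atoms <- data.frame(name = ch$names, element = ch$elements,
                      mass = ch$masses, mol = 1L, moltype = "chromophore",
                      role = "solute", stringsAsFactors = FALSE)
  bonds <- ch$bonds; angles <- ch$angles
  bond_k <- ch$bond_k; bond_r0 <- ch$bond_r0
  angle_k <- ch$angle_k; angle_theta0 <- ch$angle_theta0
  pos <- ch$pos
  sv <- NULL
  if (n_solvent > 0) {
    sv <- .solvent_model(solvent_kind)
    atoms <- rbind(atoms, data.frame(
      name = rep(sv$names, n_solvent), element = rep(sv$elements, n_solvent),
      mass = rep(sv$masses, n_solvent),
      mol = rep(seq_len(n_solvent) + 1L, each = 3),
      moltype = solvent_kind, role = "solvent", stringsAsFactors = FALSE))
    for (m in seq_len(n_solvent)) {
      off <- 12L + 3L * (m - 1L)
      bonds <- rbind(bonds, sv$bonds + off)
      angles <- rbind(angles, sv$angles + off)
    }
    bond_k <- c(bond_k, rep(sv$bond_k, n_solvent))
    bond_r0 <- c(bond_r0, rep(sv$bond_r0, n_solvent))
    angle_k <- c(angle_k, rep(sv$angle_k, n_solvent))
    angle_theta0 <- c(angle_theta0, rep(sv$angle_theta0, n_solvent))
    if (is.null(box))
      box <- (n_solvent / sv$density + 0.40)^(1 / 3)
    pos <- .pack_solvent_box(ch$pos, sv, n_solvent, box, seed)
  } else if (is.null(box)) box <- 0

  nb_policy <- list(chromophore = list(mode = "exclude_all",
                                       fudge_lj = 0, fudge_q = 0))
  if (n_solvent > 0)
    nb_policy[[solvent_kind]] <- list(mode = "bonded",
                                      fudge_lj = 0.5, fudge_q = 0.5)
  topo <- topology(atoms, bonds, angles, ch$stiff, ch$flex,
                   nb_policy = nb_policy)

  mk_ff <- function(state) {
    p <- paste0(fam, "_", state)
    q <- .solute_charges(p)
    eps <- ch$lj_eps; sig <- ch$lj_sigma
    if (n_solvent > 0) {
      q <- c(q, rep(sv$q, n_solvent))
      eps <- c(eps, rep(sv$eps, n_solvent))
      sig <- c(sig, rep(sv$sigma, n_solvent))
    }
    forcefield_parameters(state, bond_k, bond_r0, angle_k, angle_theta0,
                          ch$stiff_k, ch$stiff_phi0, .flex_coef_preset(p),
                          q, eps, sig)
  }
  ff <- list(S0 = mk_ff("S0"), S1 = mk_ff("S1"))

  # barrier heights of the presets are fixed by construction: assert
  v <- function(coef, d) sapply(d, function(x)
    sum(coef * cos(seq(0, 6) * deg2rad(x))))
  dd <- seq(0, 180, 0.1)
  stopifnot(
    abs(max(v(ff$S0$flex_coef["delta3", ], dd)) -
        (if (fam == "CYC") 23 else 19)) < 1e-9,
    abs((if (fam == "CYC")
           max(v(ff$S1$flex_coef["delta4", ], dd)) -
             v(ff$S1$flex_coef["delta4", ], 180)
         else max(v(ff$S1$flex_coef["delta4", ], seq(90, 180, 0.01))) -
             v(ff$S1$flex_coef["delta4", ], 180)) -
        (if (fam == "CYC") 42 else 7)) < 1e-6)

  config <- system_configuration(pos, box = box)
  structure(list(topology = topo, ff = ff, config = config, preset = preset,
                 solvent_kind = solvent_kind, n_solvent = n_solvent,
                 seed = seed),
            class = "qmdff_teacher")
}

#' @export
print.qmdff_teacher <- function(x, ...) {
  cat("teacher system:", x$preset, "+", x$n_solvent, x$solvent_kind,
      "molecules\n")
  print(x$topology)
  invisible(x)
}

# lattice placement with random orientations; solute sits at the box centre
.pack_solvent_box <- function(solute_pos, sv, n_solvent, box, seed) {
  geo <- .solvent_geometry(sv)
  centre <- rep(box / 2, 3)
  sol <- sweep(solute_pos, 2, colMeans(solute_pos)) +
    matrix(centre, nrow(solute_pos), 3, byrow = TRUE)
  set.seed(seed)
  ncell <- ceiling((n_solvent * 1.9)^(1 / 3))
  repeat {
    spacing <- box / ncell
    grid <- expand.grid(x = seq_len(ncell), y = seq_len(ncell), z = seq_len(ncell))
    sites <- (as.matrix(grid) - 0.5) * spacing
    keep <- apply(sites, 1, function(s) {
      d2 <- colSums((t(sol) - s)^2)
      min(d2) > 0.32^2
    })
    sites <- sites[keep, , drop = FALSE]
    if (nrow(sites) >= n_solvent) break
    ncell <- ncell + 1
  }
  sites <- sites[sample.int(nrow(sites), n_solvent), , drop = FALSE]
  out <- sol
  for (m in seq_len(n_solvent)) {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    out <- rbind(out, geo %*% t(R) +
                   matrix(sites[m, ], 3, 3, byrow = TRUE))
  }
  unname(out)
}

#' Per-state atomic charges of a teacher system
#'
#' The O2 charge is -0.71 e (S0) / -0.63 e (S1) for the CYC family and
#' -0.74 e / -0.66 e for PYR; the bonded carbonyl carbon compensates so
#' that the molecular charge is state-invariant.
#'
#' @param teacher a [build_teacher_system()] result.
#' @param state `"S0"` or `"S1"`.
#' @return charge vector (e) over all atoms of the system.
#' @export
generate_state_charges <- function(teacher, state = c("S0", "S1")) {
  state <- match.arg(state)
  teacher$ff[[state]]$charges
}

# solute-only (first molecule) views of topology, parameters, geometry
.solute_subsystem <- function(teacher, state = "S0") {
  topo <- teacher$topology
  keep <- topo$atoms$mol == 1L
  n <- sum(keep)
  sub_rows <- function(m) m[apply(m, 1, function(r) all(r <= n)), , drop = FALSE]
  nb <- nrow(sub_rows(topo$bonds)); na <- nrow(sub_rows(topo$angles))
  ff <- teacher$ff[[state]]
  stopifnot(!is.null(ff))
  topo_s <- topology(topo$atoms[keep, , drop = FALSE],
                     sub_rows(topo$bonds), sub_rows(topo$angles),
                     topo$stiff_dihedrals, topo$flexible_dihedrals,
                     topo$pairs,
                     topo$nb_policy["chromophore"])
  ff_s <- forcefield_parameters(
    ff$state, ff$bond_k[seq_len(nb)], ff$bond_r0[seq_len(nb)],
    ff$angle_k[seq_len(na)], ff$angle_theta0[seq_len(na)],
    ff$stiff_k, ff$stiff_phi0, ff$flex_coef,
    ff$charges[seq_len(n)], ff$lj_eps[seq_len(n)], ff$lj_sigma[seq_len(n)],
    ff$pair_eps, ff$pair_sigma, ff$wall)
  list(topo = topo_s, ff = ff_s, pos = .chromophore_def()$pos)
}

#' Optimized geometry and Hessian of the isolated teacher chromophore
#'
#' Minimizes the gas-phase chromophore on the teacher potential of the
#' requested state (to gradient RMS below `grad_rms_tol`) and computes the
#' Hessian there by central differences of the analytic forces.
#'
#' @inheritParams generate_state_charges
#' @param grad_rms_tol convergence threshold (kJ mol^-1 nm^-1).
#' @param fd_step finite-difference step (nm); the same step is used for
#'   the fit design columns so the discretization cancels in the fit
#'   residual.
#' @return list with `geometry` (12 x 3, nm), `hessian` (36 x 36,
#'   kJ mol^-1 nm^-2), `grad_rms`.
#' @export
generate_hessian <- function(teacher, state = c("S0", "S1"),
                             grad_rms_tol = 1e-6, fd_step = 1e-6) {
  state <- match.arg(state)
  sub <- .solute_subsystem(teacher, state)
  packed <- .pack_ff(sub$topo, sub$ff)
  res <- .minimize_packed(sub$pos, 0, packed)
  if (res$grad_rms > grad_rms_tol)
    stop("convergence error: minimization stalled at gradient RMS ",
         format(res$grad_rms))
  H <- .hessian_packed(res$pos, 0, packed, fd_step)
  list(geometry = res$pos, hessian = H, grad_rms = res$grad_rms)
}

# atoms rigidly rotated when the dihedral about bond j-k is driven: the
# connected component of k with the j-k edge removed
.dihedral_tail <- function(topo, quad) {
  n <- n_atoms(topo)
  adj <- vector("list", n)
  for (r in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[r, 1]; j <- topo$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  j <- quad[2]; k <- quad[3]
  adj[[j]] <- setdiff(adj[[j]], k); adj[[k]] <- setdiff(adj[[k]], j)
  seen <- rep(FALSE, n); seen[k] <- TRUE
  front <- k
  while (length(front)) {
    nxt <- unique(unlist(adj[front]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    front <- nxt
  }
  if (seen[j]) stop("structural error: dihedral bond lies on a ring")
  which(seen)
}

.rotate_about_axis <- function(pos, origin, axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
  sweep(sweep(pos, 2, origin) %*% t(R), 2, -origin)
}

# set the dihedral exactly by rigid rotation of the tail
.set_dihedral <- function(pos, quad, tail, target_deg) {
  cur <- compute_dihedral(pos, quad[1], quad[2], quad[3], quad[4])
  dl <- deg2rad(target_deg - cur)
  axis <- pos[quad[3], ] - pos[quad[2], ]
  try1 <- pos
  try1[tail, ] <- .rotate_about_axis(pos[tail, , drop = FALSE],
                                     pos[quad[2], ], axis, dl)
  got <- compute_dihedral(try1, quad[1], quad[2], quad[3], quad[4])
  if (abs(.wrap_deg(got - target_deg)) > 1e-6) {
    try1 <- pos
    try1[tail, ] <- .rotate_about_axis(pos[tail, , drop = FALSE],
                                       pos[quad[2], ], axis, -dl)
  }
  try1
}

.wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Relaxed torsional scan on a teacher potential
#'
#' At each grid point the scanned dihedral is frozen (stiff harmonic
#' restraint during minimization, then reset exactly by rigid rotation of
#' the tail group) while all remaining coordinates are minimized.  Energies
#' are shifted so the minimum over the grid is zero.
#'
#' @inheritParams generate_state_charges
#' @param dihedral label of a flexible dihedral (e.g. `"delta4"`) or an
#'   index quadruple.
#' @param grid_degrees strictly increasing scan grid (degrees).
#' @param k_freeze restraint stiffness (kJ mol^-1 rad^-2).
#' @param start optional starting geometry (defaults to the built one).
#' @return an object of class `torsion_profile` with fields `angle`,
#'   `energy` (kJ/mol, minimum 0), `geometries`, `dihedral`, `label`.
#' @export
relaxed_scan <- function(teacher, state = c("S0", "S1"), dihedral = "delta4",
                         grid_degrees = seq(0, 180, 15), k_freeze = 1e7,
                         start = NULL) {
  state <- match.arg(state)
  if (any(diff(grid_degrees) <= 0))
    stop("parameter error: grid must be strictly increasing")
  sub <- .solute_subsystem(teacher, state)
  quad <- .resolve_flexible(sub$topo, dihedral)
  tail <- .dihedral_tail(sub$topo, quad)
  packed <- .pack_ff(sub$topo, sub$ff)
  packed_frozen <- packed
  energies <- numeric(length(grid_degrees))
  geoms <- vector("list", length(grid_degrees))
  pos <- if (is.null(start)) sub$pos else as.matrix(start)
  for (g in seq_along(grid_degrees)) {
    target <- grid_degrees[g]
    pos_g <- .set_dihedral(pos, quad, tail, target)
    packed_frozen$stiff <- rbind(packed$stiff, matrix(quad - 1L, 1))
    packed_frozen$stiff_k <- c(packed$stiff_k, k_freeze)
    packed_frozen$stiff_phi0 <- c(packed$stiff_phi0, deg2rad(target))
    for (cycle in 1:2) {
      res <- tryCatch(
        .minimize_packed(pos_g, 0, packed_frozen, grad_rms_tol = 1e-5),
        error = function(e) stop("minimization failed at grid point ",
                                 target, " deg: ", conditionMessage(e)))
      pos_g <- .set_dihedral(res$pos, quad, tail, target)
    }
    energies[g] <- .energy_packed(pos_g, 0, packed)
    geoms[[g]] <- pos_g
    pos <- pos_g  # warm start for the next grid point
  }
  structure(list(angle = grid_degrees, energy = energies - min(energies),
                 geometries = geoms, dihedral = quad,
                 label = if (is.character(dihedral)) dihedral else NA_character_,
                 state = state),
            class = "torsion_profile")
}

.resolve_flexible <- function(topo, dihedral) {
  if (is.character(dihedral)) {
    r <- match(dihedral, rownames(topo$flexible_dihedrals))
    if (is.na(r)) stop("parameter error: no flexible dihedral '", dihedral, "'")
    return(topo$flexible_dihedrals[r, ])
  }
  quad <- as.integer(dihedral)
  keys <- .canon_tuples(topo$flexible_dihedrals)
  if (!.canon_tuples(matrix(quad, 1)) %in% keys)
    stop("parameter error: dihedral is not flagged flexible")
  quad
}

#' @export
print.torsion_profile <- function(x, ...) {
  cat("torsion profile", if (!is.na(x$label)) x$label else "",
      "(", length(x$angle), "points,",
      format(min(x$angle)), "to", format(max(x$angle)), "deg )\n")
  invisible(x)
}

#' Mock vertical transitions for a set of configurations
#'
#' The vertical energy is the S1-S0 teacher energy gap converted to eV plus
#' an electronic offset; the oscillator strength follows the bright planar
#' pi-pi* picture as f = f0 cos^2(delta4).
#'
#' @param configs list of [system_configuration()] matching the teacher
#'   topology (or a single configuration).
#' @param teacher a [build_teacher_system()] result.
#' @param offset_eV electronic offset added to every gap (eV).
#' @param f0 oscillator strength of the perfectly planar chromophore.
#' @param cutoff,coulomb nonbonded options passed to the energy evaluation.
#' @return data.frame with columns `snapshot`, `energy_ev`, `strength`.
#' @export
mock_vertical_transitions <- function(configs, teacher, offset_eV = 0,
                                      f0 = 1, cutoff = 0,
                                      coulomb = "cut_shift") {
  if (inherits(configs, "qmdff_configuration")) configs <- list(configs)
  quad <- .resolve_flexible(teacher$topology, "delta4")
  out <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    e0 <- evaluate_energy(cf, teacher$topology, teacher$ff$S0, cutoff, coulomb)
    e1 <- evaluate_energy(cf, teacher$topology, teacher$ff$S1, cutoff, coulomb)
    d4 <- compute_dihedral(cf$pos, quad[1], quad[2], quad[3], quad[4])
    data.frame(snapshot = i,
               energy_ev = kjmol2ev(e1$total - e0$total) + offset_eV,
               strength = f0 * cos(deg2rad(d4))^2)
  })
  do.call(rbind, out)
}

#' Bundle of synthetic QM descriptors
#'
#' Collects, for one preset and state, the optimized geometry, the Hessian
#' at that geometry, relaxed scans of every flexible dihedral and the
#' per-state solute charges.
#'
#' @inheritParams generate_state_charges
#' @param grid_degrees scan grid shared by all flexible dihedrals.
#' @return object of class `qmdff_bundle`.
#' @export
generate_descriptor_bundle <- function(teacher, state = c("S0", "S1"),
                                       grid_degrees = seq(0, 180, 15)) {
  state <- match.arg(state)
  gh <- generate_hessian(teacher, state)
  labels <- rownames(teacher$topology$flexible_dihedrals)
  profiles <- lapply(labels, function(l)
    relaxed_scan(teacher, state, l, grid_degrees))
  names(profiles) <- labels
  structure(list(geometry = gh$geometry, hessian = gh$hessian,
                 profiles = profiles,
                 charges = .solute_charges(paste0(substr(teacher$preset, 1, 3),
                                                  "_", state)),
                 state = state,
                 metadata = list(preset = teacher$preset, seed = teacher$seed,
                                 sigma_hessian = 0, sigma_scan = 0)),
            class = "qmdff_bundle")
}

#' Add reproducible Gaussian noise to a descriptor bundle
#'
#' Symmetric i.i.d. Gaussian noise (element standard deviation
#' `sigma_hessian`) is added to the Hessian, and i.i.d. noise of standard
#' deviation `sigma_scan` to every scan energy (profiles are re-shifted to
#' minimum zero).  With both sigmas zero the bundle is returned unchanged.
#'
#' @param bundle a [generate_descriptor_bundle()] result.
#' @param sigma_hessian Hessian noise SD (kJ mol^-1 nm^-2).
#' @param sigma_scan scan-energy noise SD (kJ/mol).
#' @param seed RNG seed.
#' @export
add_descriptor_noise <- function(bundle, sigma_hessian = 0, sigma_scan = 0,
                                 seed = 1) {
  if (sigma_hessian < 0 || sigma_scan < 0)
    stop("parameter error: noise sigmas must be >= 0")
  if (sigma_hessian == 0 && sigma_scan == 0) return(bundle)
  set.seed(seed)
  if (sigma_hessian > 0) {
    n <- nrow(bundle$hessian)
    E <- matrix(0, n, n)
    up <- upper.tri(E, diag = TRUE)
    E[up] <- stats::rnorm(sum(up), sd = sigma_hessian)
    E <- E + t(E) - diag(diag(E))
    bundle$hessian <- bundle$hessian + E
  }
  if (sigma_scan > 0) {
    bundle$profiles <- lapply(bundle$profiles, function(p) {
      p$energy <- p$energy + stats::rnorm(length(p$energy), sd = sigma_scan)
      p$energy <- p$energy - min(p$energy)
      p
    })
  }
  bundle$metadata$sigma_hessian <- sigma_hessian
  bundle$metadata$sigma_scan <- sigma_scan
  bundle$metadata$noise_seed <- seed
  bundle
}
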