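#' Molecular topology
#'
#' A topology describes the atoms of the system (names, elements, masses,
#' molecule membership and solute/solvent role) and its bonded structure:
#' bonds, angles, proper dihedrals (each one either "stiff", i.e. harmonic,
#' or "flexible", i.e. expanded in a cosine Fourier series), plus an
#' optional explicit intramolecular Lennard-Jones pair list used to couple
#' internal rotations.
#'
#' Nonbonded interactions between atoms of the same molecule follow a
#' per-molecule-type policy: mode `"bonded"` excludes 1-2 and 1-3 pairs,
#' scales 1-4 pairs by `fudge_lj`/`fudge_q` (default 0.5/0.5) and keeps the
#' rest at full strength; mode `"exclude_all"` removes every intramolecular
#' nonbonded interaction except the explicit pair list.  The synthetic
#' chromophore presets use `"exclude_all"`, i.e. intramolecular flexibility
#' is carried entirely by the bonded terms plus the explicit pairs.
#'
#' @param atoms data.frame with columns `name`, `element`, `mass` (amu),
#'   `mol` (1-based molecule id, contiguous), `moltype` (molecule type
#'   label) and `role` (`"solute"` or `"solvent"`).
#' @param bonds integer matrix (n x 2) of 1-based atom indices.
#' @param angles integer matrix (n x 3), central atom second.
#' @param stiff_dihedrals integer matrix (n x 4) of harmonic proper
#'   dihedrals.
#' @param flexible_dihedrals integer matrix (n x 4) of Fourier-expanded
#'   dihedrals; rownames are used as labels (e.g. `"delta3"`).
#' @param pairs optional integer matrix (n x 2) of explicit intramolecular
#'   LJ pairs.
#' @param nb_policy named list, one entry per molecule type, each a list
#'   with elements `mode` (`"bonded"` or `"exclude_all"`), `fudge_lj`,
#'   `fudge_q`.
#' @return an object of class `qmdff_topology`.
#' @export
topology <- function(atoms, bonds, angles,
                     stiff_dihedrals = matrix(integer(), 0, 4),
                     flexible_dihedrals = matrix(integer(), 0, 4),
                     pairs = matrix(integer(), 0, 2),
                     nb_policy = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "mass", "mol", "moltype", "role")
                %in% names(atoms)))
  n <- nrow(atoms)
  bonds <- .as_index_matrix(bonds, 2)
  angles <- .as_index_matrix(angles, 3)
  stiff_dihedrals <- .as_index_matrix(stiff_dihedrals, 4)
  flexible_dihedrals <- .as_index_matrix(flexible_dihedrals, 4)
  pairs <- .as_index_matrix(pairs, 2)

  idx <- c(bonds, angles, stiff_dihedrals, flexible_dihedrals, pairs)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop("structural error: bonded index outside 1..", n)
  if (anyDuplicated(.canon_tuples(bonds)))
    stop("structural error: duplicate bonds")
  keys <- c(.canon_tuples(stiff_dihedrals), .canon_tuples(flexible_dihedrals))
  if (anyDuplicated(keys))
    stop("structural error: a dihedral must be exactly one of stiff or flexible")
  if (any(diff(atoms$mol) < 0) || any(!diff(atoms$mol) %in% c(0L, 1L)))
    stop("structural error: molecule ids must be contiguous and increasing")

  if (is.null(nb_policy)) {
    nb_policy <- lapply(unique(as.character(atoms$moltype)), function(t)
      list(mode = "bonded", fudge_lj = 0.5, fudge_q = 0.5))
    names(nb_policy) <- unique(as.character(atoms$moltype))
  }
  # explicit pairs must not duplicate bonds/angles (1-2/1-3 contacts)
  if (nrow(pairs)) {
    d <- .bond_graph_distances(bonds, n)
    for (r in seq_len(nrow(pairs)))
      if (d[pairs[r, 1], pairs[r, 2]] < 3)
        stop("structural error: explicit pair ", pairs[r, 1], "-", pairs[r, 2],
             " already covered by bonds/angles")
  }
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 stiff_dihedrals = stiff_dihedrals,
                 flexible_dihedrals = flexible_dihedrals,
                 pairs = pairs, nb_policy = nb_policy),
            class = "qmdff_topology")
}

.as_index_matrix <- function(m, k) {
  if (is.null(m) || length(m) == 0) return(matrix(integer(), 0, k))
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  stopifnot(ncol(m) == k)
  m
}

# canonical string key per tuple, direction-insensitive
.canon_tuples <- function(m) {
  if (!nrow(m)) return(character())
  apply(m, 1, function(r) {
    if (r[length(r)] < r[1]) r <- rev(r)
    paste(r, collapse = "-")
  })
}

# all-pairs graph distances along bonds (capped at 4)
.bond_graph_distances <- function(bonds, n) {
  d <- matrix(9L, n, n)
  diag(d) <- 0L
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    front <- s
    for (depth in 1:3) {
      nxt <- unique(unlist(adj[front]))
      nxt <- nxt[d[s, nxt] > depth]
      if (!length(nxt)) break
      d[s, nxt] <- depth
      front <- nxt
    }
  }
  d
}

#' @export
print.qmdff_topology <- function(x, ...) {
  cat("qmdff topology:", nrow(x$atoms), "atoms,",
      max(x$atoms$mol), "molecules\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " stiff dihedrals:", nrow(x$stiff_dihedrals),
      " flexible dihedrals:", nrow(x$flexible_dihedrals),
      " pairs:", nrow(x$pairs), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param topo a `qmdff_topology`.
#' @export
n_atoms <- function(topo) nrow(topo$atoms)

#' Select atoms by name
#'
#' @param topo a `qmdff_topology`.
#' @param name atom name(s) to match.
#' @param role optionally restrict to `"solute"` or `"solvent"` atoms.
#' @return integer vector of 1-based atom indices.
#' @export
select_atoms <- function(topo, name, role = NULL) {
  sel <- topo$atoms$name %in% name
  if (!is.null(role)) sel <- sel & topo$atoms$role %in% role
  which(sel)
}

#' State-specific force-field parameters
#'
#' Houses one electronic state's complete parameter set.  Harmonic terms
#' use the 1/2 k (x - x0)^2 convention (GROMACS-compatible); flexible
#' dihedrals are V(delta) = sum_j c_j cos(j delta).  Angular reference
#' values are given in degrees at this interface and converted to radians
#' internally.
#'
#' @param state electronic-state label, `"S0"` or `"S1"`.
#' @param bond_k,bond_r0 per-bond force constants (kJ mol^-1 nm^-2) and
#'   equilibrium lengths (nm).
#' @param angle_k,angle_theta0 per-angle force constants
#'   (kJ mol^-1 rad^-2) and equilibrium angles (degrees).
#' @param stiff_k,stiff_phi0 per-stiff-dihedral constants
#'   (kJ mol^-1 rad^-2) and reference angles (degrees).
#' @param flex_coef numeric matrix, one row per flexible dihedral, columns
#'   are Fourier coefficients c_0 ... c_N (kJ/mol).
#' @param charges atomic point charges (e).
#' @param lj_eps,lj_sigma per-atom Lennard-Jones parameters (kJ/mol, nm).
#' @param pair_eps,pair_sigma parameters of the explicit intramolecular
#'   LJ pair list.
#' @param wall optional one-sided dihedral wall from
#'   [build_clockwise_restraint()].
#' @return an object of class `qmdff_forcefield`.
#' @export
forcefield_parameters <- function(state, bond_k, bond_r0,
                                  angle_k, angle_theta0,
                                  stiff_k = numeric(), stiff_phi0 = numeric(),
                                  flex_coef = matrix(0, 0, 7),
                                  charges, lj_eps, lj_sigma,
                                  pair_eps = numeric(), pair_sigma = numeric(),
                                  wall = NULL) {
  stopifnot(state %in% c("S0", "S1"))
  flex_coef <- as.matrix(flex_coef)
  if (any(bond_k < 0) || any(angle_k < 0) || any(stiff_k < 0))
    stop("parameter error: force constants must be >= 0")
  if (any(lj_sigma <= 0)) stop("parameter error: sigma must be > 0")
  if (any(lj_eps < 0)) stop("parameter error: epsilon must be >= 0")
  structure(list(state = state,
                 bond_k = bond_k, bond_r0 = bond_r0,
                 angle_k = angle_k, angle_theta0 = angle_theta0,
                 stiff_k = stiff_k, stiff_phi0 = stiff_phi0,
                 flex_coef = flex_coef,
                 charges = charges, lj_eps = lj_eps, lj_sigma = lj_sigma,
                 pair_eps = pair_eps, pair_sigma = pair_sigma,
                 wall = wall),
            class = "qmdff_forcefield")
}

#' @export
print.qmdff_forcefield <- function(x, ...) {
  cat("qmdff force field, state", x$state, "\n")
  cat("  ", length(x$bond_k), "bonds,", length(x$angle_k), "angles,",
      length(x$stiff_k), "stiff dihedrals,", nrow(x$flex_coef),
      "flexible dihedrals (order", ncol(x$flex_coef) - 1L, ")\n")
  if (!is.null(x$wall)) cat("  one-sided dihedral wall active\n")
  invisible(x)
}

#' System configuration
#'
#' Positions, velocities, cubic periodic box and simulation time for all
#' atoms.  `box = 0` means no periodicity (gas phase).
#'
#' @param pos positions, n x 3 matrix (nm).
#' @param vel velocities, n x 3 matrix (nm/ps); defaults to zero.
#' @param box cubic box edge (nm); 0 disables periodicity.
#' @param time simulation time (ps).
#' @export
system_configuration <- function(pos, vel = NULL, box = 0, time = 0) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3)
  if (!all(is.finite(pos))) stop("configuration error: non-finite coordinates")
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  vel <- as.matrix(vel)
  stopifnot(all(dim(vel) == dim(pos)))
  structure(list(pos = pos, vel = vel, box = box, time = time),
            class = "qmdff_configuration")
}

#' @export
print.qmdff_configuration <- function(x, ...) {
  cat("qmdff configuration:", nrow(x$pos), "atoms, box",
      format(x$box, digits = 4), "nm, t =", format(x$time, digits = 6), "ps\n")
  invisible(x)
}

# ---- packing: convert topology + parameters into the flat structure the
# compiled core consumes (0-based indices, radians) --------------------------

.pack_ff <- function(topo, ff, cutoff = 0, coulomb = "cut_shift",
                     lj_shift = TRUE) {
  n <- n_atoms(topo)
  stopifnot(length(ff$bond_k) == nrow(topo$bonds),
            length(ff$angle_k) == nrow(topo$angles),
            length(ff$stiff_k) == nrow(topo$stiff_dihedrals),
            nrow(ff$flex_coef) == nrow(topo$flexible_dihedrals),
            length(ff$charges) == n, length(ff$lj_eps) == n,
            length(ff$lj_sigma) == n,
            length(ff$pair_eps) == nrow(topo$pairs))
  # solvent molecules must be net neutral
  for (mid in unique(topo$atoms$mol[topo$atoms$role == "solvent"])) {
    qm <- sum(ff$charges[topo$atoms$mol == mid])
    if (abs(qm) > 1e-10)
      stop("parameter error: solvent molecule ", mid, " has net charge ", qm)
  }
  mt_levels <- unique(as.character(topo$atoms$moltype))
  mtyp <- match(as.character(topo$atoms$moltype), mt_levels) - 1L
  molid <- topo$atoms$mol - 1L
  loc <- integer(n)
  for (mid in unique(molid)) {
    w <- which(molid == mid)
    loc[w] <- seq_along(w) - 1L
  }
  sLJ <- vector("list", length(mt_levels))
  sQ <- vector("list", length(mt_levels))
  for (k in seq_along(mt_levels)) {
    pol <- topo$nb_policy[[mt_levels[k]]]
    if (is.null(pol)) pol <- list(mode = "bonded", fudge_lj = 0.5, fudge_q = 0.5)
    mid <- unique(topo$atoms$mol[mtyp == k - 1L])[1]
    members <- which(topo$atoms$mol == mid)
    nm <- length(members)
    if (pol$mode == "exclude_all") {
      sLJ[[k]] <- matrix(0, nm, nm); sQ[[k]] <- matrix(0, nm, nm)
    } else {
      keep <- topo$bonds[topo$bonds[, 1] %in% members &
                           topo$bonds[, 2] %in% members, , drop = FALSE]
      lb <- matrix(match(keep, members), ncol = 2)
      d <- .bond_graph_distances(.as_index_matrix(lb, 2), nm)
      m <- matrix(1, nm, nm)
      m[d <= 2] <- 0
      q <- m
      m[d == 3] <- pol$fudge_lj
      q[d == 3] <- pol$fudge_q
      sLJ[[k]] <- m; sQ[[k]] <- q
    }
  }
  wall <- ff$wall
  if (is.null(wall)) {
    wall_idx <- matrix(integer(), 0, 4)
    wall_phi0 <- numeric(); wall_k <- numeric()
  } else {
    wall_idx <- matrix(as.integer(wall$dihedral) - 1L, 1, 4)
    wall_phi0 <- deg2rad(wall$wall_angle)
    wall_k <- wall$k_wall
  }
  list(natoms = n,
       bonds = topo$bonds - 1L, bond_k = ff$bond_k, bond_r0 = ff$bond_r0,
       angles = topo$angles - 1L, ang_k = ff$angle_k,
       ang_t0 = deg2rad(ff$angle_theta0),
       stiff = topo$stiff_dihedrals - 1L, stiff_k = ff$stiff_k,
       stiff_phi0 = deg2rad(ff$stiff_phi0),
       flex = topo$flexible_dihedrals - 1L, flex_c = ff$flex_coef,
       wall = wall_idx, wall_phi0 = wall_phi0, wall_k = wall_k,
       pairs = topo$pairs - 1L, pair_eps = ff$pair_eps,
       pair_sigma = ff$pair_sigma,
       q = ff$charges, eps = ff$lj_eps, sigma = ff$lj_sigma,
       molid = molid, loc = loc, mtyp = mtyp, sLJ = sLJ, sQ = sQ,
       cutoff = cutoff,
       coul_scheme = match(coulomb, c("cut", "cut_shift", "reaction_field")) - 1L,
       lj_shift = lj_shift)
}

.check_box_cutoff <- function(box, cutoff) {
  if (box > 0 && cutoff > 0 && box < 2 * cutoff)
    stop("configuration error: box edge (", box,
         " nm) must exceed twice the cutoff (", cutoff, " nm)")
}
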