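#' Two-step force-field parameterization from QM descriptors
#'
#' The harmonic (stiff) part of the intramolecular potential is fitted
#' first, by linear least squares over all Cartesian Hessian elements; the
#' flexible torsions are then fitted to relaxed-scan profiles through the
#' frozen-internal-rotation residual.  Equilibrium values (r0, theta0,
#' phi0) are fixed to the values measured at the reference geometry, so the
#' model Hessian is exactly linear in the force constants and the fit is a
#' (nonnegativity-bounded) linear problem.
#'
#' @name ff_fitting
NULL

# Hessian of a single harmonic term with unit force constant, evaluated
# with the same finite-difference scheme as the reference Hessian so that
# model and target share one discretization.
.term_hessian <- function(pos, skeleton, kind, row, eq, fd_step = 1e-6) {
  p <- skeleton
  if (kind == "bond") {
    p$bonds <- skeleton$bonds[row, , drop = FALSE]
    p$bond_k <- 1; p$bond_r0 <- eq
  } else if (kind == "angle") {
    p$angles <- skeleton$angles[row, , drop = FALSE]
    p$ang_k <- 1; p$ang_t0 <- eq
  } else {
    p$stiff <- if (kind == "stiff") skeleton$stiff[row, , drop = FALSE]
               else skeleton$flex[row, , drop = FALSE]
    p$stiff_k <- 1; p$stiff_phi0 <- eq
  }
  .hessian_packed(pos, 0, p, fd_step)
}

# packed structure with every interaction stripped
.empty_packed <- function(packed) {
  packed$bonds <- packed$bonds[0, , drop = FALSE]
  packed$bond_k <- numeric(); packed$bond_r0 <- numeric()
  packed$angles <- packed$angles[0, , drop = FALSE]
  packed$ang_k <- numeric(); packed$ang_t0 <- numeric()
  packed$stiff <- packed$stiff[0, , drop = FALSE]
  packed$stiff_k <- numeric(); packed$stiff_phi0 <- numeric()
  packed$flex <- packed$flex[0, , drop = FALSE]
  packed$flex_c <- matrix(0, 0, ncol(packed$flex_c))
  packed$wall <- packed$wall[0, , drop = FALSE]
  packed$wall_phi0 <- numeric(); packed$wall_k <- numeric()
  packed$pairs <- packed$pairs[0, , drop = FALSE]
  packed$pair_eps <- numeric(); packed$pair_sigma <- numeric()
  packed$q <- packed$q * 0
  packed$eps <- packed$eps * 0
  packed
}

#' Fit harmonic force constants to a reference Hessian
#'
#' Equilibrium bond lengths, angles and stiff-dihedral values are measured
#' at the bundle geometry; all force constants are then obtained in a
#' single nonnegative linear least-squares fit of the model Hessian to the
#' reference Hessian over all 3N x 3N Cartesian elements.  Each flexible
#' dihedral contributes one auxiliary harmonic-curvature column (absorbing
#' the torsional curvature at the reference geometry) that is discarded
#' afterwards, since its potential is fitted separately from relaxed scans.
#' Nonbonded intramolecular contributions (charges, LJ, explicit pairs) are
#' taken from `nonbonded_ff` when supplied and subtracted from the
#' reference before fitting — they are transferred, never fitted.
#'
#' @param bundle a [generate_descriptor_bundle()] result (or any list with
#'   `geometry` and `hessian`).
#' @param topo solute [topology()].
#' @param nonbonded_ff optional [forcefield_parameters()] supplying
#'   charges/LJ/pair parameters to subtract.
#' @param fd_step finite-difference step (nm) for the design-column
#'   Hessians; must match the step used for the reference Hessian.
#' @param flex_ff optional [forcefield_parameters()] carrying already
#'   fitted flexible-torsion coefficients: their Hessian contribution is
#'   subtracted from the reference exactly (same functional form, same
#'   discretization) and no auxiliary curvature columns are used.  This is
#'   the second pass of the two-step refinement in [fit_qmdff()].
#' @return object of class `qmdff_fit`: `ff` (partial parameters, flexible
#'   coefficients zero), `sd` (RMS residual over Hessian elements,
#'   kJ mol^-1 nm^-2), `residuals`, `condition_number`,
#'   `aux_flex_curvature`.
#' @export
fit_harmonic_parameters <- function(bundle, topo, nonbonded_ff = NULL,
                                    fd_step = 1e-6, flex_ff = NULL) {
  pos <- bundle$geometry
  n <- n_atoms(topo)
  stopifnot(nrow(pos) == n, nrow(bundle$hessian) == 3 * n)

  # equilibrium values measured at the reference geometry
  r0 <- apply(topo$bonds, 1, function(b)
    sqrt(sum((pos[b[1], ] - pos[b[2], ])^2)))
  th0 <- apply(topo$angles, 1, function(a) {
    u <- pos[a[1], ] - pos[a[2], ]; v <- pos[a[3], ] - pos[a[2], ]
    rad2deg(acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))
  })
  phi0 <- if (nrow(topo$stiff_dihedrals)) apply(topo$stiff_dihedrals, 1,
    function(d) compute_dihedral(pos, d[1], d[2], d[3], d[4])) else numeric()
  delta0 <- if (nrow(topo$flexible_dihedrals)) apply(topo$flexible_dihedrals,
    1, function(d) compute_dihedral(pos, d[1], d[2], d[3], d[4])) else numeric()

  zero_ff <- forcefield_parameters(
    bundle$state %||% "S0",
    rep(0, nrow(topo$bonds)), r0, rep(0, nrow(topo$angles)), th0,
    rep(0, nrow(topo$stiff_dihedrals)), phi0,
    matrix(0, nrow(topo$flexible_dihedrals), 7),
    rep(0, n), rep(0, n), rep(0.1, n))
  skeleton <- .pack_ff(topo, zero_ff)

  cols <- list(); kinds <- character(); labels <- character()
  for (r in seq_len(nrow(topo$bonds))) {
    cols[[length(cols) + 1]] <- .term_hessian(pos, skeleton, "bond", r, r0[r], fd_step)
    kinds <- c(kinds, "bond")
    labels <- c(labels, paste0("bond_", paste(topo$bonds[r, ], collapse = "-")))
  }
  for (r in seq_len(nrow(topo$angles))) {
    cols[[length(cols) + 1]] <- .term_hessian(pos, skeleton, "angle", r,
                                              deg2rad(th0[r]), fd_step)
    kinds <- c(kinds, "angle")
    labels <- c(labels, paste0("angle_", paste(topo$angles[r, ], collapse = "-")))
  }
  for (r in seq_len(nrow(topo$stiff_dihedrals))) {
    cols[[length(cols) + 1]] <- .term_hessian(pos, skeleton, "stiff", r,
                                              deg2rad(phi0[r]), fd_step)
    kinds <- c(kinds, "stiff")
    labels <- c(labels, paste0("dihedral_",
                               paste(topo$stiff_dihedrals[r, ], collapse = "-")))
  }
  n_aux <- 0L
  if (is.null(flex_ff)) {
    for (r in seq_len(nrow(topo$flexible_dihedrals))) {
      cols[[length(cols) + 1]] <- .term_hessian(pos, skeleton, "flex", r,
                                                deg2rad(delta0[r]), fd_step)
      kinds <- c(kinds, "aux_flex")
      labels <- c(labels, paste0("aux_",
                                 rownames(topo$flexible_dihedrals)[r] %||% r))
      n_aux <- n_aux + 1L
    }
  }
  A <- vapply(cols, as.vector, numeric((3 * n)^2))
  target <- as.vector(bundle$hessian)
  if (!is.null(nonbonded_ff)) {
    pn <- .pack_ff(topo, nonbonded_ff)
    pn <- .strip_bonded(pn)
    target <- target - as.vector(.hessian_packed(pos, 0, pn, fd_step))
  }
  if (!is.null(flex_ff)) {
    pf <- skeleton
    pf$flex <- topo$flexible_dihedrals - 1L
    pf$flex_c <- flex_ff$flex_coef
    target <- target - as.vector(.hessian_packed(pos, 0, pf, fd_step))
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv)) {
    g <- qr(A)
    bad <- labels[setdiff(seq_len(ncol(A)), g$pivot[seq_len(g$rank)])]
    stop("rank-deficient design matrix; unidentifiable terms: ",
         paste(bad, collapse = ", "))
  }
  fit <- pracma::lsqnonneg(A, target)
  k <- fit$x
  res <- target - A %*% k
  sdfit <- sqrt(sum(res^2) / length(target))

  nb <- nrow(topo$bonds); na <- nrow(topo$angles); nd <- nrow(topo$stiff_dihedrals)
  ff <- forcefield_parameters(
    bundle$state %||% "S0",
    k[seq_len(nb)], r0,
    k[nb + seq_len(na)], th0,
    k[nb + na + seq_len(nd)], phi0,
    matrix(0, nrow(topo$flexible_dihedrals), 7),
    charges = bundle$charges %||% rep(0, n),
    lj_eps = if (!is.null(nonbonded_ff)) nonbonded_ff$lj_eps else rep(0, n),
    lj_sigma = if (!is.null(nonbonded_ff)) nonbonded_ff$lj_sigma else rep(0.1, n),
    pair_eps = if (!is.null(nonbonded_ff)) nonbonded_ff$pair_eps else numeric(),
    pair_sigma = if (!is.null(nonbonded_ff)) nonbonded_ff$pair_sigma else numeric())
  structure(list(ff = ff, sd = sdfit, residuals = as.vector(res),
                 condition_number = max(sv) / min(sv),
                 aux_flex_curvature = if (n_aux) k[nb + na + nd +
                   seq_len(n_aux)] else numeric(),
                 term_labels = labels),
            class = "qmdff_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.strip_bonded <- function(packed) {
  packed$bonds <- packed$bonds[0, , drop = FALSE]
  packed$bond_k <- numeric(); packed$bond_r0 <- numeric()
  packed$angles <- packed$angles[0, , drop = FALSE]
  packed$ang_k <- numeric(); packed$ang_t0 <- numeric()
  packed$stiff <- packed$stiff[0, , drop = FALSE]
  packed$stiff_k <- numeric(); packed$stiff_phi0 <- numeric()
  packed$flex <- packed$flex[0, , drop = FALSE]
  packed$flex_c <- matrix(0, 0, ncol(packed$flex_c))
  packed
}

#' @export
print.qmdff_fit <- function(x, ...) {
  cat("harmonic fit: sd =", format(x$sd, digits = 6),
      "(descriptor units), condition number",
      format(x$condition_number, digits = 4), "\n")
  invisible(x)
}

#' Fit a flexible torsion through the frozen-internal-rotation residual
#'
#' At each scan geometry x_i the residual E_res(delta_i) = E_ref(delta_i) -
#' E_FF,other(x_i) is formed, where E_FF,other is the partial force-field
#' energy with this dihedral's own term removed (harmonic terms from the
#' Hessian fit plus any transferred nonbonded parameters).  The cosine
#' coefficients then solve a linear least squares of
#' sum_j c_j cos(j delta_i) against E_res.
#'
#' @param profile a [relaxed_scan()] result carrying scan geometries.
#' @param topo solute topology.
#' @param partial_ff parameters from [fit_harmonic_parameters()] (flexible
#'   rows may be zero or previously fitted; the fitted dihedral's row is
#'   ignored).
#' @param dihedral label or quadruple of the dihedral being fitted.
#' @param order Fourier order N (coefficients c_0..c_N).
#' @return list with `coef`, `residual_rms`, and `profile_fn` (vectorized
#'   fitted potential, degrees in, kJ/mol out).
#' @export
fit_torsional_fourier <- function(profile, topo, partial_ff, dihedral,
                                  order = 6) {
  if (order + 1 >= length(profile$angle))
    stop("overdetermination error: order must be < number of grid points")
  quad <- .resolve_flexible(topo, dihedral)
  ridx <- which(.canon_tuples(topo$flexible_dihedrals) ==
                  .canon_tuples(matrix(quad, 1)))
  ff_other <- partial_ff
  if (ncol(ff_other$flex_coef) == 0)
    ff_other$flex_coef <- matrix(0, nrow(topo$flexible_dihedrals), order + 1)
  ff_other$flex_coef[ridx, ] <- 0
  packed <- .pack_ff(topo, ff_other)
  e_other <- vapply(profile$geometries, function(g)
    .energy_packed(g, 0, packed), numeric(1))
  e_res <- profile$energy - e_other
  X <- outer(deg2rad(profile$angle), 0:order, function(d, j) cos(j * d))
  cf <- qr.solve(X, e_res)
  res <- e_res - X %*% cf
  list(coef = as.vector(cf),
       residual_rms = sqrt(mean(res^2)),
       profile_fn = function(deg)
         as.vector(outer(deg2rad(deg), 0:order, function(d, j) cos(j * d)) %*% cf))
}

#' Mirror a torsional profile about a symmetry axis
#'
#' Adds mirrored points at 2*axis - delta; points that coincide after
#' mirroring are averaged and the output grid is sorted.
#'
#' @param profile a `torsion_profile` (geometries are dropped).
#' @param axis_degrees mirror axis.
#' @export
symmetrize_profile <- function(profile, axis_degrees = 90) {
  if (!length(profile$angle)) stop("structural error: empty profile")
  ang <- c(profile$angle, 2 * axis_degrees - profile$angle)
  en <- c(profile$energy, profile$energy)
  key <- round(ang, 9)
  agg <- tapply(en, key, mean)
  ang_out <- as.numeric(names(agg))
  ord <- order(ang_out)
  structure(list(angle = ang_out[ord], energy = as.numeric(agg[ord]),
                 geometries = NULL, dihedral = profile$dihedral,
                 label = profile$label, state = profile$state),
            class = "torsion_profile")
}

#' Import a high-level torsional profile as Fourier coefficients
#'
#' For torsions whose reference method fails (e.g. near a conical
#' intersection) the profile computed at a higher level of theory on a
#' coarse grid replaces the reference: the table energies are fitted
#' directly (no force-field subtraction), and the resulting coefficients
#' are assigned to the dihedral, which is then excluded from later fits.
#'
#' @param table a `torsion_profile` covering 0..180 degrees at <= 15 degree
#'   spacing (symmetrize first if needed).
#' @param order Fourier order.
#' @return list with `coef` and `residual_rms`.
#' @export
import_highlevel_torsion <- function(table, order = 6) {
  ang <- table$angle
  if (min(ang) > 1e-9 || max(ang) < 180 - 1e-9 || max(diff(ang)) > 15 + 1e-9)
    stop("coverage error: table must span [0, 180] degrees at <= 15 degree spacing")
  if (order + 1 >= length(ang))
    stop("overdetermination error: order must be < number of grid points")
  X <- outer(deg2rad(ang), 0:order, function(d, j) cos(j * d))
  cf <- qr.solve(X, table$energy)
  res <- table$energy - X %*% cf
  list(coef = as.vector(cf), residual_rms = sqrt(mean(res^2)))
}

#' One-sided harmonic wall restricting a dihedral to clockwise rotation
#'
#' V = 1/2 k (delta - wall)^2 for delta below the wall angle and zero
#' otherwise; energy and force are continuous at the wall.  Intended for
#' the excited-state isomerizable dihedral, whose cosine expansion is
#' symmetric: the wall breaks the tie so rotation out of the Franck-Condon
#' well proceeds in a single direction.
#'
#' @param dihedral index quadruple of the restrained dihedral.
#' @param wall_angle_degrees wall position (default 0).
#' @param k_wall stiffness (kJ mol^-1 rad^-2).
#' @return a restraint description accepted by the `wall` field of
#'   [forcefield_parameters()] (see also [apply_wall()]).
#' @export
build_clockwise_restraint <- function(dihedral, wall_angle_degrees = 0,
                                      k_wall = 500) {
  list(dihedral = as.integer(dihedral), wall_angle = wall_angle_degrees,
       k_wall = k_wall)
}

#' Evaluate a one-sided wall restraint at a dihedral value
#' @param restraint a [build_clockwise_restraint()] result.
#' @param delta_degrees dihedral value(s), degrees.
#' @return wall energy (kJ/mol).
#' @export
wall_energy <- function(restraint, delta_degrees) {
  dp <- deg2rad(delta_degrees - restraint$wall_angle)
  ifelse(dp < 0, 0.5 * restraint$k_wall * dp^2, 0)
}

#' Attach a wall restraint to a force field
#' @param ff a [forcefield_parameters()] object.
#' @inheritParams wall_energy
#' @export
apply_wall <- function(ff, restraint) {
  ff$wall <- list(dihedral = restraint$dihedral,
                  wall_angle = restraint$wall_angle,
                  k_wall = restraint$k_wall)
  ff
}

#' Compare harmonic frequencies of a fitted force field with a reference
#'
#' Both Hessians are evaluated at their own minima: the fitted force field
#' is re-minimized from the bundle geometry, the reference Hessian comes
#' from the bundle itself.  Near-zero (rigid-body) modes below 1 cm^-1 are
#' removed and the remaining frequencies paired in ascending order.
#'
#' @param fitted_ff complete [forcefield_parameters()] (flexible torsions
#'   included).
#' @param bundle reference descriptor bundle.
#' @param topo solute topology.
#' @param fd_step finite-difference step (nm), matching the reference
#'   Hessian's discretization.
#' @return data.frame with `reference`, `fitted`, `abs_dev`, `rel_dev`
#'   (cm^-1).
#' @export
validate_frequencies <- function(fitted_ff, bundle, topo, fd_step = 1e-6) {
  masses <- topo$atoms$mass
  packed <- .pack_ff(topo, fitted_ff)
  mn <- .minimize_packed(bundle$geometry, 0, packed)
  Hf <- .hessian_packed(mn$pos, 0, packed, fd_step)
  nm_f <- normal_modes(Hf, masses, mn$pos)
  nm_r <- normal_modes(bundle$hessian, masses, bundle$geometry)
  keep <- function(f) f[abs(f) >= 1]
  fr <- keep(nm_r$frequencies); ffq <- keep(nm_f$frequencies)
  if (length(fr) != length(ffq))
    stop("structural error: mode count mismatch (", length(fr), " vs ",
         length(ffq), ")")
  data.frame(reference = fr, fitted = ffq, abs_dev = abs(ffq - fr),
             rel_dev = abs(ffq - fr) / abs(fr))
}

#' Complete two-step parameterization against a descriptor bundle
#'
#' Convenience wrapper: harmonic fit from the Hessian, then a FIRA Fourier
#' fit for every flexible dihedral (or an imported high-level table for
#' dihedrals named in `highlevel`).
#'
#' @inheritParams fit_harmonic_parameters
#' @param order Fourier order for all torsions.
#' @param highlevel optional named list of `torsion_profile` tables fitted
#'   via [import_highlevel_torsion()] instead of the FIRA residual.
#' @return list with `ff` (complete parameters), `harmonic_fit`,
#'   `torsion_fits`.
#' @export
fit_qmdff <- function(bundle, topo, nonbonded_ff = NULL, order = 6,
                      highlevel = list()) {
  hfit <- fit_harmonic_parameters(bundle, topo, nonbonded_ff)
  ff <- hfit$ff
  ff$flex_coef <- matrix(0, nrow(topo$flexible_dihedrals), order + 1)
  rownames(ff$flex_coef) <- rownames(topo$flexible_dihedrals)
  tfits <- list()
  for (lab in rownames(topo$flexible_dihedrals)) {
    if (lab %in% names(highlevel)) {
      tf <- import_highlevel_torsion(highlevel[[lab]], order)
    } else {
      tf <- fit_torsional_fourier(bundle$profiles[[lab]], topo, ff, lab, order)
    }
    ff$flex_coef[lab, ] <- tf$coef
    tfits[[lab]] <- tf
  }
  # refinement pass: with the torsional potentials known, their Hessian
  # contribution is subtracted exactly and the harmonic constants refitted
  # without auxiliary curvature columns
  hfit2 <- fit_harmonic_parameters(bundle, topo, nonbonded_ff, flex_ff = ff)
  flex <- ff$flex_coef
  ff <- hfit2$ff
  ff$flex_coef <- flex
  list(ff = ff, harmonic_fit = hfit2, harmonic_fit_first_pass = hfit,
       torsion_fits = tfits)
}
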