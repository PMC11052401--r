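#' Coordinate and topology file I/O
#'
#' GRO files follow the fixed-width GROMACS convention (positions in nm,
#' optional velocities, cubic box on the last line).  XYZ files use
#' Angstrom, as customary for that format.  The topology dialect is a
#' plain-text sectioned format (`[ atoms ]`, `[ bonds ]`, `[ angles ]`,
#' `[ dihedrals ]`, `[ pairs ]`) mirroring the fields of [topology()] and
#' [forcefield_parameters()].
#'
#' @name qmdff_io
NULL

#' @rdname qmdff_io
#' @param config a [system_configuration()].
#' @param topo a [topology()].
#' @param file path.
#' @param title header line.
#' @export
write_gro <- function(config, topo, file, title = "qmdff configuration") {
  n <- nrow(config$pos)
  lines <- c(title, sprintf("%5d", n))
  has_vel <- any(config$vel != 0)
  for (i in seq_len(n)) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    topo$atoms$mol[i] %% 100000,
                    substr(topo$atoms$moltype[i], 1, 5),
                    substr(topo$atoms$name[i], 1, 5), i %% 100000,
                    config$pos[i, 1], config$pos[i, 2], config$pos[i, 3])
    if (has_vel)
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                   config$vel[i, 1], config$vel[i, 2],
                                   config$vel[i, 3]))
    lines <- c(lines, base)
  }
  b <- if (config$box > 0) config$box else 0
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", b, b, b))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname qmdff_io
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[2])
  pos <- matrix(0, n, 3)
  vel <- matrix(0, n, 3)
  names <- character(n)
  for (i in seq_len(n)) {
    l <- lines[2 + i]
    names[i] <- trimws(substr(l, 11, 15))
    pos[i, ] <- as.numeric(c(substr(l, 21, 28), substr(l, 29, 36),
                             substr(l, 37, 44)))
    if (nchar(l) >= 68)
      vel[i, ] <- as.numeric(c(substr(l, 45, 52), substr(l, 53, 60),
                               substr(l, 61, 68)))
  }
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1]
  list(config = system_configuration(pos, vel, box), names = names)
}

#' @rdname qmdff_io
#' @param atom_names element/name labels for the XYZ records.
#' @param comment second header line.
#' @export
write_xyz <- function(config, atom_names, file, comment = "") {
  n <- nrow(config$pos)
  a <- nm2angstrom(config$pos)
  lines <- c(as.character(n), comment,
             sprintf("%-4s %12.6f %12.6f %12.6f", atom_names,
                     a[, 1], a[, 2], a[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname qmdff_io
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  names <- vapply(toks, `[`, character(1), 1)
  pos <- angstrom2nm(t(vapply(toks, function(t)
    as.numeric(t[2:4]), numeric(3))))
  list(config = system_configuration(pos), names = names)
}

#' @rdname qmdff_io
#' @param ff a [forcefield_parameters()] set consistent with `topo`.
#' @export
write_topology <- function(topo, ff, file) {
  fmt_rows <- function(idx, ...) {
    extra <- list(...)
    apply(cbind(idx, do.call(cbind, extra)), 1, function(r)
      paste(c(sprintf("%6d", r[seq_len(ncol(idx))]),
              sprintf("%14.7g", r[-seq_len(ncol(idx))])), collapse = " "))
  }
  a <- topo$atoms
  lines <- c("; qmdff topology + parameters, state " , "")
  lines <- c(paste0("; qmdff state ", ff$state),
             "[ atoms ]",
             sprintf("%6d %-6s %-3s %10.5f %4d %-12s %-8s %10.6f %10.6f %10.6f",
                     seq_len(nrow(a)), a$name, a$element, a$mass, a$mol,
                     a$moltype, a$role, ff$charges, ff$lj_eps, ff$lj_sigma),
             "[ bonds ]",
             fmt_rows(topo$bonds, ff$bond_k, ff$bond_r0),
             "[ angles ]",
             fmt_rows(topo$angles, ff$angle_k, ff$angle_theta0))
  if (nrow(topo$stiff_dihedrals))
    lines <- c(lines, "[ dihedrals ]",
               fmt_rows(topo$stiff_dihedrals, ff$stiff_k, ff$stiff_phi0))
  if (nrow(topo$flexible_dihedrals))
    lines <- c(lines, "[ flexible_dihedrals ]",
               paste(fmt_rows(topo$flexible_dihedrals),
                     apply(ff$flex_coef, 1, function(cc)
                       paste(sprintf("%14.7g", cc), collapse = " "))))
  if (nrow(topo$pairs))
    lines <- c(lines, "[ pairs ]",
               fmt_rows(topo$pairs, ff$pair_eps, ff$pair_sigma))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname qmdff_io
#' @param traj a [run_md()] trajectory.
#' @export
write_energy_tsv <- function(traj, file) {
  utils::write.table(traj$log, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname qmdff_io
#' @param profile a `torsion_profile`.
#' @export
write_profile_tsv <- function(profile, file) {
  utils::write.table(
    data.frame(angle_deg = profile$angle, energy_kjmol = profile$energy),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname qmdff_io
#' @export
read_profile_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t")
  structure(list(angle = d[[1]], energy = d[[2]], geometries = NULL,
                 dihedral = NA, label = NA_character_, state = NA_character_),
            class = "torsion_profile")
}
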