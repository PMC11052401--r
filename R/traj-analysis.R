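#' Time-windowed, swarm-averaged radial distribution functions
#'
#' For each closed-open time window, frames from all swarm members whose
#' times fall inside the window are pooled and the a-b minimum-image
#' distance histogram is normalized by shell volume 4 pi r^2 dr, pooled
#' frame count, the number of a sites and the mean number density of b
#' sites (instantaneous box volume per frame).  Per-bin standard errors use
#' the Poisson approximation sqrt(C + 1)/norm.
#'
#' @param swarm a `trajectory_swarm` (or a [run_md()] trajectory, coerced
#'   through [as_swarm()] into a single-window analysis).
#' @param sel_a,sel_b integer atom indices (1-based), e.g. from
#'   [select_atoms()].
#' @param windows list of `c(start, end)` pairs (ps, closed-open); default
#'   a single window covering everything.
#' @param r_max histogram range (nm); must not exceed half the box.
#' @param bin_width radial bin (nm).
#' @return object of class `time_resolved_rdf`: `r` (bin centres), `g`
#'   (bins x windows), `se`, `counts`, `frames_per_window`, `windows`.
#' @export
time_windowed_rdf <- function(swarm, sel_a, sel_b, windows = NULL,
                              r_max = 1.0, bin_width = 0.01) {
  if (inherits(swarm, "qmdff_trajectory")) swarm <- as_swarm(swarm)
  if (!length(sel_a) || !length(sel_b))
    stop("parameter error: empty selection")
  if (is.null(windows))
    windows <- list(c(-Inf, Inf))
  wm <- do.call(rbind, windows)
  if (any(wm[, 2] <= wm[, 1])) stop("parameter error: empty window")
  nbins <- round(r_max / bin_width)
  nw <- nrow(wm)
  counts <- matrix(0, nbins, nw)
  nframes <- integer(nw)
  dens_sum <- numeric(nw)
  sel_a0 <- as.integer(sel_a - 1L); sel_b0 <- as.integer(sel_b - 1L)
  for (mem in swarm$members) {
    if (is.null(mem)) next
    for (w in seq_len(nw)) {
      inw <- which(mem$times >= wm[w, 1] & mem$times < wm[w, 2])
      if (!length(inw)) next
      boxes <- mem$boxes[inw]
      if (any(boxes > 0 & boxes < 2 * r_max))
        stop("geometry error: r_max exceeds half the box edge")
      counts[, w] <- counts[, w] +
        .rdf_counts_cpp(mem$frames[inw], boxes, sel_a0, sel_b0, r_max, nbins)
      nframes[w] <- nframes[w] + length(inw)
      dens_sum[w] <- dens_sum[w] + sum(length(sel_b) / boxes^3)
    }
  }
  r_mid <- (seq_len(nbins) - 0.5) * bin_width
  g <- matrix(NA_real_, nbins, nw)
  se <- matrix(NA_real_, nbins, nw)
  for (w in seq_len(nw)) {
    if (nframes[w] == 0) next  # empty window: flagged by NA, not fatal
    rho_b <- dens_sum[w] / nframes[w]
    norm <- nframes[w] * length(sel_a) * 4 * pi * r_mid^2 * bin_width * rho_b
    g[, w] <- counts[, w] / norm
    se[, w] <- sqrt(counts[, w] + 1) / norm
  }
  structure(list(r = r_mid, g = g, se = se, counts = counts,
                 frames_per_window = nframes, windows = wm,
                 n_a = length(sel_a), n_b = length(sel_b)),
            class = "time_resolved_rdf")
}

#' @export
print.time_resolved_rdf <- function(x, ...) {
  cat("time-resolved RDF:", length(x$r), "bins x", ncol(x$g), "windows,",
      sum(x$frames_per_window), "pooled frames\n")
  invisible(x)
}

#' Centred 3-point (or wider) running average
#'
#' Endpoints use truncated windows; output length equals input length and
#' width 1 is the identity.
#'
#' @param values numeric vector.
#' @param width odd window width.
#' @export
smooth_running_average <- function(values, width = 3) {
  if (width %% 2 != 1 || width < 1)
    stop("parameter error: width must be odd and >= 1")
  n <- length(values)
  half <- (width - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(values[lo:hi])
  }, numeric(1))
}

#' Dihedral population histogram over a trajectory
#'
#' @param traj a [run_md()] trajectory.
#' @param dihedral 1-based index quadruple.
#' @param bin_width_degrees histogram bin (degrees).
#' @return list with `mid` (bin centres, degrees over (-180, 180]) and
#'   `p` (probabilities summing to 1).
#' @export
dihedral_population <- function(traj, dihedral, bin_width_degrees = 5) {
  if (!length(traj$frames)) stop("structural error: trajectory has no frames")
  vals <- vapply(traj$frames, function(fr)
    compute_dihedral(fr, dihedral[1], dihedral[2], dihedral[3], dihedral[4]),
    numeric(1))
  breaks <- seq(-180, 180, by = bin_width_degrees)
  h <- hist(vals, breaks = breaks, plot = FALSE)
  list(mid = h$mids, p = h$counts / sum(h$counts), values = vals)
}

#' Relaxation time from a time-windowed RDF peak height
#'
#' The observable is the maximum of the smoothed g(r) inside
#' `peak_window_nm` for each time window; the long-time reference is the
#' mean over the final 10% of windows; the relaxation time tau is the left
#' edge of the earliest window after which the observable stays within
#' epsilon of its total excursion for all later windows.
#'
#' @param rdf a [time_windowed_rdf()] result with >= 4 windows.
#' @param peak_window_nm `c(min, max)` radial range of the tracked peak.
#' @param epsilon convergence band as a fraction of |h(0) - h(inf)|.
#' @param smooth_width running-average width applied to g(r).
#' @return object of class `relaxation_estimate`: `tau` (ps or NA),
#'   `converged`, `h` (per-window peak heights), `h_inf`, `detectable`.
#' @export
estimate_relaxation_time <- function(rdf, peak_window_nm, epsilon = 0.2,
                                     smooth_width = 3) {
  nw <- ncol(rdf$g)
  if (nw < 4) stop("need at least 4 time windows")
  sel <- rdf$r >= peak_window_nm[1] & rdf$r <= peak_window_nm[2]
  h <- vapply(seq_len(nw), function(w)
    max(smooth_running_average(rdf$g[, w], smooth_width)[sel]), numeric(1))
  ntail <- max(1, ceiling(0.1 * nw))
  h_inf <- mean(h[(nw - ntail + 1):nw])
  excursion <- abs(h[1] - h_inf)
  noise <- stats::median(rdf$se[sel, nw], na.rm = TRUE)
  detectable <- excursion > 3 * noise
  ok <- abs(h - h_inf) <= epsilon * excursion
  tau <- NA_real_
  converged <- FALSE
  for (w in seq_len(nw)) {
    if (all(ok[w:nw])) {
      tau <- rdf$windows[w, 1]
      converged <- TRUE
      break
    }
  }
  structure(list(tau = tau, converged = converged, h = h, h_inf = h_inf,
                 epsilon = epsilon, detectable = detectable,
                 windows = rdf$windows),
            class = "relaxation_estimate")
}

#' @export
print.relaxation_estimate <- function(x, ...) {
  if (!x$detectable) cat("no detectable response\n")
  else if (!x$converged) cat("not converged\n")
  else cat("relaxation time:", format(x$tau, digits = 4), "ps\n")
  invisible(x)
}

#' Coordination number from pooled RDF counts
#'
#' Mean number of b sites within `r_limit` of an a site, per window.
#'
#' @param rdf a [time_windowed_rdf()] result.
#' @param r_limit integration limit (nm), typically the first g(r) minimum.
#' @return list with `n` (per window) and `se` (Poisson standard error).
#' @export
coordination_number <- function(rdf, r_limit) {
  sel <- rdf$r < r_limit
  tot <- colSums(rdf$counts[sel, , drop = FALSE])
  denom <- rdf$frames_per_window * rdf$n_a
  list(n = tot / denom, se = sqrt(tot + 1) / denom)
}

#' Extract the explicit solvation shell around the chromophore
#'
#' Selects whole solvent molecules having any atom within `r_com` of the
#' solute centre of mass or within `r_sites` of any named solute site
#' (union, no duplicates), for export together with the solute as input to
#' per-snapshot excitation calculations.
#'
#' @param config a [system_configuration()].
#' @param topo a [topology()].
#' @param r_com centre-of-mass radius (nm), default 0.4 (4 Angstrom).
#' @param r_sites site radius (nm), default 0.25 (2.5 Angstrom).
#' @param site_names solute atom names defining the site criterion.
#' @return list with `atoms` (sorted indices: solute plus shell),
#'   `molecules` (selected solvent molecule ids).
#' @export
extract_solvent_shell <- function(config, topo, r_com = 0.4, r_sites = 0.25,
                                  site_names = c("Oh", "Oa", "O2", "Ho")) {
  solute <- which(topo$atoms$role == "solute")
  sites <- select_atoms(topo, site_names, role = "solute")
  if (!all(site_names %in% topo$atoms$name[solute]))
    stop("parameter error: unknown site name(s): ",
         paste(setdiff(site_names, topo$atoms$name[solute]), collapse = ", "))
  m <- topo$atoms$mass[solute]
  com <- colSums(config$pos[solute, , drop = FALSE] * m) / sum(m)
  box <- config$box
  mind2 <- function(p, q) {
    d <- p - q
    if (box > 0) d <- d - box * round(d / box)
    sum(d^2)
  }
  solvent_mols <- unique(topo$atoms$mol[topo$atoms$role == "solvent"])
  selected <- vapply(solvent_mols, function(mid) {
    idx <- which(topo$atoms$mol == mid)
    for (a in idx) {
      if (mind2(config$pos[a, ], com) < r_com^2) return(TRUE)
      for (s in sites)
        if (mind2(config$pos[a, ], config$pos[s, ]) < r_sites^2) return(TRUE)
    }
    FALSE
  }, logical(1))
  mols <- solvent_mols[selected]
  atoms <- sort(c(solute, which(topo$atoms$mol %in% mols)))
  list(atoms = atoms, molecules = mols)
}

#' First and second solvation-shell peaks of a g(r) curve
#'
#' Local maxima above 1.0 located by discrete neighborhood comparison;
#' the first two are reported.
#'
#' @param r bin centres (nm).
#' @param g smoothed g(r) values.
#' @return data.frame with up to two rows (`position`, `height`); zero
#'   rows when no structured peak exists.
#' @export
shell_peak_metrics <- function(r, g) {
  if (length(g) < 3) stop("structural error: need at least 3 bins")
  is_peak <- vapply(2:(length(g) - 1), function(i)
    g[i] > 1.0 && g[i] >= g[i - 1] && g[i] >= g[i + 1] &&
      (g[i] > g[i - 1] || g[i] > g[i + 1]), logical(1))
  idx <- which(is_peak) + 1L
  # collapse plateau neighbours
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 1)]
  idx <- utils::head(idx, 2)
  data.frame(position = r[idx], height = g[idx])
}
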