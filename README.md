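# qmdff

State-specific, quantum-mechanically derived force fields (QMD-FFs) and
non-equilibrium solvation dynamics, at desk scale, in R.

## What problem this solves, and for whom

Photoactive molecules in solution respond to light in two very different
steps: an essentially instantaneous electronic rearrangement, then a slow
nuclear one — intramolecular relaxation, possibly photoisomerization, and
reorganization of the solvent shells around sites whose partial charges
changed.  A standard classical strategy for simulating this is:

1. fit a **separate classical force field for each electronic state** of
   the chromophore against QM descriptors (the Hessian at the optimized
   geometry for stiff modes, relaxed torsional scans for soft ones,
   per-state charges),
2. equilibrate the chromophore in explicit solvent on the ground-state
   surface and harvest uncorrelated snapshots with velocities,
3. mimic vertical excitation by **switching the chromophore's parameters
   and charges to the excited-state set** at fixed positions and
   velocities, then propagate a **swarm of independent non-equilibrium
   trajectories**,
4. quantify the solvent response with **time-windowed, swarm-averaged
   radial distribution functions** and build **ensemble-averaged
   absorption spectra** from per-snapshot vertical transitions.

`qmdff` implements that whole pipeline for computational chemists who want
a tested, inspectable, single-machine version of it.  Electronic-structure
calculations are out of scope; a synthetic backend generates every QM
descriptor from analytically defined *teacher* potentials with known
parameters, so each stage can be validated against exact ground truth.

## The core models

The potential is harmonic bonds/angles/stiff dihedrals (½k(x−x₀)²,
GROMACS convention), cosine Fourier series Σⱼ cⱼ cos(jδ) for flexible
torsions, plus 12-6 Lennard-Jones and truncated Coulomb (minimum image,
spherical cutoff, optional reaction-field correction).  Fitting is the
classic two-step scheme: force constants by nonnegative linear least
squares over all Cartesian Hessian elements (equilibrium values fixed at
the reference geometry, so the problem is exactly linear), then each
flexible torsion from the frozen-internal-rotation residual
E_res(δᵢ) = E_ref(δᵢ) − E_FF,other(xᵢ) of its relaxed scan.  Torsions that
the reference method cannot describe (e.g. near a conical intersection)
are imported directly from a higher-level table on a ≤15° grid, with
optional symmetrization about 90° and a one-sided wall restraint that
commits the isomerization to a single rotation direction.

Dynamics is velocity Verlet (0.1 fs default, no constraints) with a
stochastic velocity-rescaling thermostat and an isotropic weak-coupling
barostat; spectra use unit-area pseudo-Voigt (75% Gaussian / 25%
Lorentzian) or pure Gaussian broadening on the energy axis.

The teacher chromophore is a planar 12-atom toy with a hydroxyl donor, two
carbonyl acceptors, one flexible aryl torsion and one isomerizable double
bond.  Its presets encode two contrasting excited-state fates: a CYC-like
state with a high 42 kJ/mol isomerization barrier, and a PYR-like state
that reaches a conical-intersection funnel over only 7 kJ/mol; ground-state
aryl barriers are 23 and 19 kJ/mol, and excitation lowers the carbonyl
oxygen charge magnitude (−0.71→−0.63 e and −0.74→−0.66 e), weakening its
hydrogen bonds to the solvent.

## A worked example

Build the CYC-like excited-state teacher, run a relaxed scan of the
isomerizable torsion on a 15° grid, fit a cosine series, and read off the
barrier:

```r
library(qmdff)

teacher <- build_teacher_system("CYC_S1")
scan    <- relaxed_scan(teacher, "S1", "delta4", seq(0, 180, 15))
fit     <- import_highlevel_torsion(scan, order = 6)
round(fit$coef, 6)
#> [1]  21   0 -21   0   0   0   0

delta <- seq(0, 180, 0.02)
V <- sapply(delta, function(d) sum(fit$coef * cos(0:6 * deg2rad(d))))
cat("fitted barrier:", max(V) - V[length(V)], "kJ/mol\n")
#> fitted barrier: 42 kJ/mol
```

The fitted coefficients `c0 = 21, c2 = −21` are the exact cosine
representation of the teacher's 42·sin²δ potential (sin²δ = (1−cos2δ)/2),
and the barrier separating the trans minimum from the 90° twist comes out
at 42 kJ/mol — the signature of a slow, inefficient photoisomerization.
The same teacher provides vertical transitions and spectra:

```r
gap <- vertical_gap(teacher$config, teacher$topology,
                    teacher$ff$S0, teacher$ff$S1, offset_eV = 3.2)
sp <- build_spectrum(data.frame(snapshot = 1, energy_ev = gap, strength = 1),
                     shape = "pseudo_voigt", hwhm_eV = 0.15)
sp
#> spectrum ( pseudo_voigt , hwhm 0.15 eV ): peak at 3.2 eV = 387.5 nm
```

For the full non-equilibrium workflow — `run_equilibrium_protocol()`,
`sample_uncorrelated_snapshots()`, `switch_state()`, `run_swarm()`,
`time_windowed_rdf()`, `estimate_relaxation_time()` — see the methods
vignette (`vignettes/qmdff-methods.Rmd`) and the test suite, which runs
the complete pipeline at desk scale (24–64 solvent molecules, 100-member
swarms).

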