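---
title: "State-specific force fields and non-equilibrium solvation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-specific force fields and non-equilibrium solvation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmdff)
```

## The problem this package addresses

When a solvated chromophore absorbs a photon, its electronic density
rearranges essentially instantaneously while the nuclei — its own and the
solvent's — are still frozen in a ground-state configuration.  What follows
is a cascade of relaxation: intramolecular geometry change, possibly
photoisomerization about a double bond, and reorganization of the solvation
shells around sites whose partial charges changed upon excitation.
`qmdff` implements a classical, desk-scale version of the workflow used to
study this cascade:

1. **Parameterize** a state-specific classical force field against
   quantum-mechanical descriptors — the Hessian at the optimized geometry
   for the stiff modes, relaxed torsional scans for the soft ones, and
   per-state atomic charges.
2. **Equilibrate** the chromophore in an explicit solvent box on the
   ground-state surface and harvest uncorrelated snapshots with velocities.
3. **Switch** the chromophore's intramolecular parameters and charges to
   the excited-state set at fixed positions and velocities (a
   Franck–Condon excitation) and propagate a swarm of independent
   non-equilibrium trajectories.
4. **Analyze** the solvent response through time-windowed, swarm-averaged
   radial distribution functions, and build ensemble-averaged absorption
   spectra from per-snapshot vertical transitions.

Because the electronic-structure layer itself is out of scope, the package
ships a synthetic backend (`build_teacher_system()`) in which every
descriptor is generated from an analytically defined *teacher* potential
with known parameters.  Every stage of the pipeline can therefore be tested
against exact ground truth: a fit is correct when it recovers the teacher,
an estimator is correct when it reproduces a closed form.

## The potential-energy model

All interfaces use kJ/mol, nm, ps, amu and degrees (radians internally).
The potential is

$$
V = \sum_{\text{bonds}} \tfrac12 k_b (r - r_0)^2
  + \sum_{\text{angles}} \tfrac12 k_\theta (\theta - \theta_0)^2
  + \sum_{\text{stiff dih.}} \tfrac12 k_\phi\, \Delta\phi^2
  + \sum_{\text{flex dih.}} \sum_{j=0}^{N} c_j \cos(j\delta)
  + V_{\text{LJ}} + V_{\text{Coul}},
$$

with $\Delta\phi$ wrapped to $(-180°, 180°]$.  The $\tfrac12 k (x-x_0)^2$
convention matches GROMACS, so exported parameters can be read in that
dialect without conversion.  The cosine order defaults to $N = 6$ and is
configurable.  Nonbonded interactions are 12–6 Lennard-Jones
(Lorentz–Berthelot combination) plus point-charge Coulomb with prefactor
$f = 138.935458$ kJ mol⁻¹ nm e⁻², evaluated under the minimum-image
convention with a spherical cutoff.

Three truncation schemes are exposed: plain cutoff, cutoff with potential
shift (continuous energy; the `evaluate_energy()` default), and a
reaction-field correction with infinite external dielectric, which makes
the pair *force* continuous at the cutoff as well.  The reaction-field
variant is the default for dynamics: with plain or shifted truncation,
pairs crossing the cutoff kick the integrator and microcanonical energy
conservation degrades.  No Ewald summation is implemented; for the small
boxes this package targets, reaction-field truncation is the appropriate
level.

Intramolecular nonbonded policy is set per molecule type.  Generic
topologies default to the common convention (1-2/1-3 excluded, 1-4 scaled
by 0.5/0.5, all configurable).  The synthetic chromophore instead uses
`exclude_all`: its intramolecular flexibility is carried entirely by the
bonded terms plus an explicit, user-supplied LJ pair list — the reading
appropriate for force fields whose torsional potentials are fitted to
reproduce full QM scans (any residual intramolecular nonbonded term would
be double counting).

A one-sided harmonic wall (`build_clockwise_restraint()`) can be attached
to the excited-state isomerizable dihedral: cosine series are even in
$\delta$, so both rotation directions are otherwise equivalent; the wall
($V = \tfrac12 k_w(\delta - \delta_w)^2$ for $\delta < \delta_w$,
continuous at the wall) commits the isomerization to one sense of rotation.
The wall does not wrap: the $\pm180°$ seam acts as a hard barrier against
the reverse rotation, which is its purpose.

## The synthetic teacher systems

The toy chromophore has 12 atoms in a planar chain carrying the motifs
that matter for solvation dynamics: a hydroxyl donor Oh–Ho, two carbonyl
acceptors (Cd=Oa and C2=O2), a flexible aryl-type torsion `delta3` and an
isomerizable double-bond torsion `delta4`.  Three improper-style stiff
dihedrals restrain out-of-plane motion at the three-coordinate sp²
centres; without them pyramidalization is only quartic (three angle terms
at 120° sum to 360° at planarity) and the Hessian acquires spurious
near-zero modes.

The preset torsional potentials encode the physics being studied:

| preset | `delta3` (aryl) | `delta4` (isomerizable) |
|---|---|---|
| `CYC_S0` | $23\sin^2\delta$ | $150\sin^2\delta$ |
| `PYR_S0` | $19\sin^2\delta$ | $150\sin^2\delta$ |
| `CYC_S1` | as S0 | $42\sin^2\delta$ — high barrier, slow photoisomerization |
| `PYR_S1` | as S0 | $c_0 + c_2\cos2\delta + c_4\cos4\delta$ — 7 kJ/mol barrier into a −20 kJ/mol funnel at 90° |

The PYR excited-state coefficients are solved from three constraints:
$V(180°) = 0$, $V(90°) = -20$ kJ/mol (the depth of the
conical-intersection funnel — a free modeling choice, any negative value
preserving the 7 kJ/mol barrier would do), and a local maximum 7 kJ/mol
above the trans minimum.  This gives $c_2 = 10$,
$c_4 = -(17+\sqrt{189})/4$, $c_0 = -10 - c_4$.  The ground-state double
bond uses a generic stiff $150\sin^2\delta$, large enough that thermal
isomerization never occurs at 300 K.

Excitation changes the carbonyl charge: O2 carries −0.71 e (S0) → −0.63 e
(S1) in the CYC family and −0.74 → −0.66 e in PYR, with the bonded carbon
compensating so the molecular charge is state-invariant.  This weakens
hydrogen bonding to O2 upon excitation, which is the driving force for the
solvent-shell response the swarm machinery measures.

Solvents are flexible 3-site models (stiff harmonic bonds and angle, no
constraints): water with TIP3P charges and LJ, an ethanol-like model
(united ethyl site, hydroxyl O–H) and an acetonitrile-like model with a
negative nitrogen-analog site.  The acetonitrile analogue uses a 170°
equilibrium bend rather than strict linearity because the harmonic angle
gradient is singular at 180°.  Boxes are built on a lattice at the
solvent's liquid number density with seeded random orientations.

What the teacher systems deliberately do *not* emulate: real CYC/PYR
geometries and charge distributions beyond the four quoted oxygen values,
polarizability, Ewald electrostatics, bond constraints, and solvent models
of publishable accuracy.  A green test suite here demonstrates that the
*pipeline* is correct — fits recover known parameters, estimators
reproduce closed forms, ensembles are sampled canonically — not that the
toy reproduces experimental solvation-shell structure.

## Descriptor generation and the two-step fit

`generate_hessian()` minimizes the gas-phase chromophore (L-BFGS-B on the
analytic gradient, then damped Newton polishing with rigid-body null space
removed) to a gradient RMS below 10⁻⁶ kJ mol⁻¹ nm⁻¹ and evaluates the
Hessian by central differences of the analytic forces.  `relaxed_scan()`
freezes the scanned dihedral — a stiff restraint (10⁷ kJ mol⁻¹ rad⁻²)
during Cartesian minimization, followed by an exact reset through rigid
rotation of the tail group — and relaxes everything else; energies are
reported relative to the grid minimum.

The fit is the classical two-step scheme:

1. **Harmonic terms from the Hessian.**  Equilibrium values are fixed to
   the values measured at the reference geometry, so the model Hessian is
   exactly linear in the force constants; these solve a nonnegative linear
   least-squares problem over all $3N \times 3N$ Cartesian Hessian elements
   (`pracma::lsqnonneg`; nonnegativity keeps the resulting dynamics
   stable).  Each flexible dihedral contributes one auxiliary
   harmonic-curvature column that absorbs its local curvature and is then
   discarded.  Hessian elements enter with uniform unit weight; weighting
   and internal-coordinate variants are intentionally out of scope.
2. **Flexible torsions from relaxed scans.**  The frozen-internal-rotation
   residual $E_{\text{res}}(\delta_i) = E_{\text{ref}}(\delta_i) -
   E_{\text{FF,other}}(x_i)$ subtracts, at each scan geometry, every
   force-field term except the dihedral being fitted (transferred
   nonbonded parameters included); the cosine coefficients then solve an
   ordinary linear least squares.  `fit_qmdff()` finishes with a
   refinement pass: once the torsion coefficients are known, their Hessian
   contribution is subtracted exactly and the harmonic constants refitted
   without auxiliary columns.

Two numerical choices deserve a note.  First, the descriptor Hessian and
the fit's design columns share one finite-difference step (10⁻⁶ nm,
tighter than the 10⁻⁵ nm default of the general-purpose `ff_hessian()`):
with matched discretization the truncation error cancels term by term and
zero-noise recovery reaches a residual RMS of ~10⁻¹¹ in descriptor units.
Second, scan profiles are normalized to minimum zero, so the constant
$c_0$ is determined only up to the scan's energy origin; barriers and all
$c_{j\ge1}$ are origin-free.

For torsions whose reference method fails — the canonical case is a
$\pi\pi^*$ state near a conical intersection — `import_highlevel_torsion()`
fits a table computed at a higher level on a coarse (≤15°) grid *directly*,
replacing rather than supplementing the reference for that coordinate, and
`symmetrize_profile()` extends a half-range scan by its mirror image when
symmetry about 90° is assumed.

`validate_frequencies()` compares harmonic frequencies (mass-weighted
modes, Eckart-projected, near-zero modes below 1 cm⁻¹ removed) between the
fitted force field at its own minimum and the reference Hessian.

## Dynamics

Velocity Verlet with no constraint algorithms; the reference protocol's
0.1 fs step is the default and is what makes unconstrained flexible
solvent stable.  The thermostat is stochastic velocity rescaling
(canonical-sampling rescaling with the exact propagation formula: an
exponential relaxation of the kinetic energy toward
$\tfrac12 N_f k_B T$ plus the appropriate Wiener term; the
$\chi^2_{N_f-1}$ partial sum is drawn from a Gamma distribution).  Tests
verify the mean temperature, the canonical kinetic-energy variance
$N_f (k_B T)^2/2$ and a Maxwell–Boltzmann goodness of fit on pooled speeds.

Pressure control is an isotropic weak-coupling barostat acting on molecule
centres of mass (internal geometry untouched), a documented stand-in for
extended-Lagrangian barostats: only the mean density matters for the
analyses downstream, not cell-fluctuation statistics.  The instantaneous
pressure uses the pairwise virial for nonbonded terms and the
translation-invariant atomic virial for bonded terms (molecules are kept
whole under periodic wrapping, which makes that form exact).  Centre-of-mass
motion is removed every 100 steps by default.

The equilibration protocol mirrors the reference three-step strategy:
(1) solvent relaxation with the solute position-restrained
(k = 1000 kJ mol⁻¹ nm⁻²), (2) NVT, (3) NPT equilibration, then (4) NPT
production with coordinates *and velocities* saved.
`sample_uncorrelated_snapshots()` takes uniformly spaced frames ending at
the last one — the committed reading of "uncorrelated" given that no
decorrelation criterion is stated for the source protocol.

Determinism: given identical inputs and seeds, trajectories are
bit-identical on one platform (the compiled core uses its own
`mt19937_64` stream per run).  Swarm members propagate independently, so
results are independent of execution order, and a member whose dynamics
blows up is flagged and skipped without aborting the swarm.

## Non-equilibrium swarms and observables

`switch_state()` is deliberately trivial — it validates that the two
parameter sets share a topology and identical solvent parameters and
returns the same configuration with the S1 set active — because the
physics of a Franck–Condon excitation *is* that nothing happens to the
nuclei.  `vertical_gap()` gives $E_{S1}-E_{S0}$ at fixed coordinates plus
an electronic offset; the synthetic `mock_vertical_transitions()` adds an
oscillator strength $f = f_0\cos^2\delta_4$, the smooth caricature of a
bright planar π–π* transition that darkens toward the 90° twist.

`time_windowed_rdf()` pools frames from all members per closed-open time
window and normalizes the minimum-image distance histogram by shell volume
$4\pi r^2\Delta r$, pooled frame count, source-site count and the mean
number density of target sites (instantaneous box volume per frame, so NPT
trajectories are handled correctly).  Standard errors use the Poisson
approximation $\sqrt{C+1}/\text{norm}$; the +1 regularization keeps empty
bins from claiming zero uncertainty.  Default windows densify toward the
switch, mirroring a response that is sub-picosecond in water but can take
over 100 ps in alcohols.  The relaxation-time estimator tracks the
smoothed first-shell peak height per window and reports the left edge of
the earliest window after which the observable stays within an
$\varepsilon$-band (default 0.2) of its total excursion for *all* later
windows; with desk-scale statistics the band should be widened (the mass-
scaling regression test uses 0.4) or the member count raised, otherwise
per-window noise pushes the estimate toward the horizon.

`extract_solvent_shell()` implements the explicit-shell rule for
per-snapshot excitation calculations: whole solvent molecules with any
atom within 0.4 nm of the solute centre of mass or 0.25 nm of a named
polar site (union, no duplicates), exported with the solute as XYZ.

## Spectra

`build_spectrum()` convolutes every vertical transition with a unit-area
profile and divides by the snapshot count, so duplicating an ensemble
changes nothing.  Both broadening conventions of the reference workflow
are implemented — pseudo-Voigt with 75% Gaussian / 25% Lorentzian sharing
one HWHM, and pure Gaussian with HWHM 0.15 eV — with pseudo-Voigt
(η = 0.25) as the default; which of the two produced a given published
figure is ambiguous, so the choice is a parameter.  Broadening happens on
the energy axis; the wavelength view is $\lambda = 1239.84198/E$ with no
Jacobian reweighting (the display convention), and an optional display
shift in nm (14 nm in the reference figures) affects only that view and is
recorded in the metadata.  A true pseudo-Voigt has Lorentzian tails: its
integral over ±50 HWHM is ≈ 0.9968, so unit-area checks must integrate
the full line.

## Desk-scale study conditions

The test suite and worked examples run at sizes chosen once for a single
CPU: chromophore + 24 flexible waters (box ≈ 1.04 nm, cutoff 0.45 nm) for
the swarm analyses, 100 members × 10 ps with 0.5 fs steps for the
non-equilibrium ensembles, 64 waters at the reference 0.1 fs step for the
microcanonical conservation check, and a 125-atom LJ fluid for thermostat
statistics.  The full-scale protocol (≈1000 solvent molecules, 1.2 nm
cutoff, 50 ns production, 500 × 20 ns swarms) is expressible through the
same interfaces but is not what the tests exercise.

## Known limitations

* No Ewald/PME; truncated (reaction-field) electrostatics only.
* Weak-coupling barostat: densities are right, cell fluctuations are not.
* The wall restraint's ±180° seam is intentionally impassable.
* Poisson standard errors ignore frame-to-frame correlation; windows much
  shorter than the solvent correlation time overstate independence.
* The toy chromophore's absolute frequencies, charges and LJ parameters
  are generic, not fitted to any real molecule.
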