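---
title: "Force-field model, calibration and simulation protocols in co2mea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field model, calibration and simulation protocols in co2mea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`co2mea` is a self-contained classical molecular-mechanics toolkit for one
specific chemistry: carbon dioxide interacting with monoethanolamine
(MEA, HOCH2CH2NH2), the workhorse amine solvent for CO2 scrubbing. This
vignette is the package's own account of the model, the choices behind it,
and what its tests do and do not establish.

## The potential energy model

The potential is an MM3-flavored valence force field with three bonded and
two nonbonded terms, in units of Angstrom, kcal/mol, Debye and degrees:

* **Stretch**: `E = ks (r - r0)^2` per bond. Note the convention: `ks`
  absorbs the conventional 1/2, so a bond displaced by 0.1 A with
  `ks = 300` stores 3.0 kcal/mol.
* **Bend**: `E = kb (theta - theta0)^2` per angle, `kb` per rad^2.
* **Torsion**: a three-term cosine series
  `sum_n Vn/2 (1 + cos(n phi - gamma_n))` with `gamma = (0, 180, 0)` deg,
  applied to rotatable bonds of MEA through wildcard classes on the central
  bond; CO2 has none.
* **Lennard-Jones 6-12** in minimum-position form
  `eps_ij ((rm/r)^12 - 2 (rm/r)^6)`, with the arithmetic rule on the
  minimum-distance radius (`rm = rv_i + rv_j`) and the geometric rule on
  the well depth. This form is used precisely so that the arithmetic
  combining rule applies to the position of the minimum.
* **Bond-centered dipole-dipole electrostatics**: every polar bond (C=O of
  CO2, O-H, N-H, C-O, C-N) carries one point dipole at its geometric
  midpoint, oriented along the bond axis. Two dipoles interact by the
  classical orientation formula
  `E = K mu1 mu2 (cos chi - 3 cos a1 cos a2) / (D r^3)`. The conversion
  constant `K = 14.3933 kcal A^3 mol^-1 D^-2` is re-derived from CODATA
  values (`332.06371 kcal/mol` per `e^2/A` and `1 D = 0.2081943 e A`)
  rather than copied from any code base. The dielectric `D` defaults to 1:
  electrostatics are deliberately unattenuated, and the historical 1.5 of
  MM3-lineage programs is exposed only as a parameter-file knob.

There are no atomic partial charges, no polarization and no charge
transfer; this is a deliberate scope boundary of the model (bond dipoles
are the entire electrostatic description), and the known cost is accuracy
at short CO2-amine approach where real charge redistribution sets in.

**Why plain harmonic bonded terms and not MM3's anharmonic corrections?**
The calibrated CO2 frequencies themselves decide this: the tabulated
antisymmetric/symmetric stretch ratio 2374/1240 = 1.9145 equals the
harmonic two-bond mass identity `sqrt(1 + 2 mO/mC) = 1.9142` to four
figures, which is the signature of an uncoupled harmonic model. Harmonic
terms reproduce the reference data; anharmonic corrections would add
parameters the data cannot pin.

**Cutoffs and tapers.** Van der Waals interactions cut off at 10 A, dipoles
at 12 A. Each nonbonded term is multiplied by a C^1 polynomial switching
function over the final 1.0 A before its cutoff; abrupt truncation would
inject energy into dynamics. Under a periodic cell the minimum-image
convention applies; cells must exceed twice the vdW cutoff, and the
effective dipole cutoff is clamped to half the shortest edge when the cell
is smaller than 24 A. The clamp is needed because the bulk MEA systems of
interest ((MEA)128 at 1.01 g/cm^3 is a 23.4 A cube) are legitimately
smaller than twice the nominal dipole cutoff.

**Exclusions.** Atom pairs separated by one or two bonds carry no LJ or
dipole interaction; 1-4 and beyond count at full strength (no scaling).
Dipole pairs whose bonds share an atom are excluded; all other
same-molecule dipole pairs interact — this intramolecular term is what
makes the gauche MEA conformer's internal O-H...N hydrogen bond a feature
of the model rather than an artifact.

## Calibration

The paper trail for this force field is a set of printed observables, not a
parameter table, so the package treats calibration as a parameter-recovery
problem against the shipped reference set
(`inst/extdata/reference_observables.tsv`, every entry carrying its
provenance): the three characteristic (CO2)2 interaction energies
(-1.23 / +0.16 / -0.92 kcal/mol) with their dipole-dipole and LJ
components, the CO2 monomer frequencies (629 / 1240 / 2374 cm^-1), the NHN
and OHO (MEA)2 totals (-4.16 / -6.15) with components, the two CO2
binding-motif energies (5.50 amino / 5.05 hydroxyl), and the 2.7 A
physisorption distance. Quantum-chemistry reference columns are kept in the
file with weight zero, as context only.

The binding-motif energies and the physisorption distance are included as
fitted observables deliberately: they are the only printed numbers that
constrain the CO2-MEA cross interaction, which combining rules alone would
otherwise leave to chance.

Fitting proceeds in three deterministic stages:

1. **Closed-form CO2 intramolecular inversion.** For a harmonic linear
   triatomic the normal modes factorize, so
   `ks = mO omega_s^2 / 2` from the symmetric stretch and
   `kb = omega_b^2 r0^2 / (4 (1/mO + 2/mC))` from the bend; the
   antisymmetric stretch is then a parameter-free prediction
   (`nu_s sqrt(1 + 2 mO/mC)` = 2373.6 cm^-1), and its agreement with the
   tabulated 2374 cm^-1 is a consistency check, not a fit.
2. **CO2 nonbonded block**: the C=O bond-dipole magnitude and the C/O LJ
   radii and depths (5 parameters) against the nine (CO2)2 observables by
   weighted Levenberg-Marquardt (`minpack.lm::nls.lm`).
3. **MEA and cross block**: the four MEA bond-dipole magnitudes and the
   N/O(hydroxyl) LJ parameters (8 parameters) against the six (MEA)2
   observables, the two motif energies and the scan minimum, with the CO2
   block frozen.

Each LM stage starts from a fixed, documented three-entry multi-start list
and keeps the best deviance, so the calibration needs no random seed.
Least squares is Levenberg-Marquardt with a finite-difference Jacobian;
the `epsfcn` step is set to 1e-6 because every residual is itself the
output of an inner constrained minimization with tolerance near 1e-8 —
a machine-precision Jacobian step would differentiate optimizer noise.
The inner constrained relaxations impose constraints by stiff harmonic
restraints escalated 1e3 -> 1e6 kcal/mol per unit^2 over four warm-started
stages; restraint energy is excluded from every reported number, and the
residual constraint deviation is verified below 1e-3 (A or deg).

Each dimer observable is evaluated exactly as tabulated: relax the dimer
under its arrangement constraints, then take
`Eint = E(complex) - E(fragment A) - E(fragment B)` with both fragments
frozen at their in-complex geometry — the interaction energy in the
quantum-chemistry sense, the quantity that sits next to
counterpoise-corrected binding energies in the reference tables. With this
reference the dipole-dipole and LJ components of the decomposition are
purely intermolecular sums and monomer deformation is excluded. (Choosing
the relaxed-monomer reference instead shifts the CO2 dimers by under
0.004 kcal/mol but caps the CO2-amino motif well below its tabulated
value; the frozen-fragment reading is both the standard one and the one
the data are consistent with.) The parallel (CO2)2 keeps its C-C
distance at 4.0 A and both axis angles at 90 deg (the printed +0.16
kcal/mol identifies this as the genuinely repulsive side-by-side
arrangement, not a slipped relaxation). The binding motifs are built on the
gauche (intraHB) MEA conformer with the carbon-to-site distance frozen at
the 2.7 A physisorption distance, which keeps the amino and hydroxyl
arrangements in distinct basins for any parameter vector the optimizer
visits; at the calibrated parameters the free minima coincide with these
constrained ones to within the scan's grid resolution.

## Geometry machinery

Minimization is L-BFGS-B on analytic forces. The analytic gradient of every
term (including the four-center bond-dipole term and the cutoff tapers) is
validated against central finite differences at relative error 1e-5 in the
test suite. Normal modes come from a central-finite-difference Hessian of
the analytic forces (step 1e-3 A), symmetrized, mass-weighted and
diagonalized; rigid-body modes are identified by a |nu| < 15 cm^-1
threshold rather than projection, which is adequate at these force
constants and is exposed as an argument. The CO2-MEA scan freezes the
C(CO2)-N(MEA) distance on a 2.0-4.0 A grid in 0.1 A steps (the profile's
natural resolution; the source grid is not recorded anywhere) and relaxes
everything else, warm-starting each point from its neighbor.

## Dynamics

Velocity-Verlet at a 0.5 fs default time step; Berendsen weak-coupling
thermostat (tau = 0.1 ps) for NVT; Berendsen-style isotropic pressure
coupling on the atomic virial for constant pressure. The NPH protocol is
realized as pressure coupling with the thermostat off — the enthalpy is
then conserved only approximately, which matches the weak-coupling spirit
of the reference protocol; a true extended-Lagrangian NPH piston is out of
scope. Default barostat settings are tau_P = 1 ps with compressibility
4.6e-5 atm^-1. Temperatures use 3N-3 degrees of freedom (net momentum is
removed at initialization and the integrator conserves it). Spherical
confinement is a one-sided harmonic wall `E = kw (r - R)^2` outside radius
R with kw = 100 kcal mol^-1 A^-2 per atom; the wall term is excluded from
the virial and from the potential energy used in heat-capacity estimates.

The pairwise virial accumulates `sum_a f_a . r_a` per interaction in a
local minimum-image-consistent frame, which is well-defined because every
term is translation invariant; with all interactions switched off the
measured pressure reduces to the ideal-gas law (tested).

Neighbor lists are plain Verlet lists with a 1.0 A skin rebuilt every 10
steps, built in deterministic sweep order so that summation order — and
hence every trajectory — is bitwise reproducible; beyond-cutoff entries
contribute exactly nothing, so neighbor-listed and brute-force energies are
identical, not merely close (tested as an invariant). A restarted run
continues a longer run bitwise because the integrator itself consumes no
random numbers.

## Analyses

Heat capacity uses the canonical fluctuation estimator
`Cv = (<U^2> - <U>^2) / (NA kB T^2)` with population moments and U in
kcal/mol, so `NA kB` is the gas constant 1.9872e-3 kcal mol^-1 K^-1 and Cv
comes out in kcal mol^-1 K^-1 per system; peaks are read as the grid
argmax after optional 3-point smoothing. Radial distribution functions are
standard intermolecular pair histograms normalized by the ideal-gas shell
count at the mean cell density; for the early non-periodic interface
stages the instantaneous primary-cell density is the documented
approximation. The time evolution g(3.65 A) series evaluates sequential
frame windows. The intramolecular hydrogen-bond histogram measures each
selected MEA's amine-N to hydroxyl-H distance over 10 molecules x 200
snapshots with the 2.2 A criterion.

## Structure builders and the interfacial protocol

All structures are generated programmatically: monomers from z-matrix
construction at force-field equilibrium values (two MEA conformers, anti
and gauche-intraHB), dimers by explicit arrangement geometry, clusters and
liquid boxes by jittered-lattice packing with minimum-distance rejection
(dense liquids are not reachable by naive random insertion), everything
deterministic per seed. The interfacial composite follows the study
recipe: equilibrate a spherically confined CO2 cluster (NVT), equilibrate
a periodic MEA box (NVT), remove every MEA whose center of mass lies
within the cavity radius of the cell center, place the cluster in the
cavity carrying velocities from both parents, and run NPH. At full scale
that is (CO2)44 at radius 9.1257 A inside an (MEA)864-derived box at
1.01 g/cm^3 and 400 K with 7415 atm external pressure for 250 ps; the
package defaults run the identical pipeline at a reduced configuration
(a (CO2)10 cluster, a 150-MEA box, 20 ps NPH) chosen so that the full
workflow — including the 10% hydroxyl-dipole control obtained via
`scale_bond_dipole` — executes at desk scale. The stated sphere density of
1.01 g/cm^3 for the CO2 cluster is honored literally through the
count/radius combination at build time; it is an unusually dense gas
reference, and is flagged here rather than silently adjusted.

## Problem sizes used by the shipped checks

The test suite and the acceptance analyses run reduced problem sizes,
chosen once. The (CO2)13 heat-capacity scan samples 88-97 K at 0.05 ns
equilibration plus 0.25 ns production per point, starting every
temperature from the same crystalline cluster prepared by
`pack_cluster_annealed` (a best-of-8 pack-and-minimize basin search
followed by heat-quench cycles); starting from a single packed glass
instead buries the solid-solid transition entirely, and even from the
deep minimum the reduced sampling leaves the Cv curve visibly noisier
than a 100 ns one, with the transition spike appearing a couple of
kelvin above where a converged curve would put it. The MEA melting scan runs the full (MEA)128 cell at
1.01 g/cm^3 over 280-420 K at picoseconds per point — two to three orders
of magnitude below what a converged melting Cv needs — so it exercises
the protocol and the estimator, not a resolved transition. The
interfacial checks use the reduced pipeline above and assert directions
(first-peak decay of g_CcCc(3.7), more intraHB geometries than bulk,
higher late-time g(3.65) under 10% muOH), not magnitudes. Passing these checks shows the
machinery reproduces the study's qualitative physics under its stated
conditions at reduced sampling; it does not certify the model against
real CO2/MEA thermophysics, for which the model's known idealizations
(no polarization, bond dipoles only, harmonic bonds) are the limiting
factor.

## Known limitations

* No chemistry: proton transfer and zwitterion formation are outside the
  model by construction.
* No Ewald summation; electrostatics are short-ranged by the tapered
  12 A dipole cutoff, a fair approximation for neutral bond dipoles but
  not for ionic systems.
* The Berendsen couplings do not sample a rigorous canonical or
  isoenthalpic ensemble; fluctuation-based Cv from Berendsen-NVT carries a
  known mild suppression, partially absorbed by the calibration of peak
  positions rather than peak heights.
* Conformer coverage of MEA is the two shipped conformers; no conformer
  search is attempted.
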