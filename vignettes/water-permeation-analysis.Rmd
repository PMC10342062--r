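---
title: "Quantifying water permeation and domain motion in membrane transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying water permeation and domain motion in membrane transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Secondary active transporters of the LeuT fold — the sodium-glucose
cotransporter SGLT1 is the motivating case — conduct water passively while
cycling between inward-facing and outward-facing conformations.  Two
questions drive the analyses in this package: *how much* water crosses the
protein at equilibrium (permeabilities), and *what controls the rate* —
the instantaneous channel opening, the local water diffusion in the
constriction, and the protein's intrinsic domain motion of the
"rocking-bundle" type.  All quantities are computed from equilibrium
molecular-dynamics trajectories (coordinates per frame plus a topology with
masses, charges and Lennard-Jones parameters); because production
trajectories of this kind are rarely redistributable, the package ships
Brownian-dynamics and harmonic-network generators with known ground truth
so that every stage of the pipeline is testable end to end.

Conventions used throughout: the membrane normal is z; the origin is the
per-frame protein centre of mass (use `center_on_group()`); a water
molecule is tracked by its oxygen position; internal units are Angstrom,
ps, amu, kcal/mol and elementary charges; boxes are orthorhombic.

## Permeation events

Two detection planes at `z = +/- Delta/2` (`Delta` = 25 A) are backed by
entry/exit compartments of thickness `delta` = 5 A, so `Delta + delta` =
30 A is the membrane span a permeating water crosses.  A molecule
completes an event when it is seen in one compartment and later in the
opposite one; `t*` is its last frame in the source compartment and `tau`
the time to its first frame in the destination compartment.  If every
intermediate frame stays strictly between the planes the event is flagged
`confined` and `tau` is exactly the time needed to permeate the distance
`Delta`; otherwise `tau` is an upper bound.

The state machine that implements this (identically in the compiled scan
and in the brute-force test oracle) classifies each frame into five zones
— outer bulk, lower compartment, inter-plane region, upper compartment,
outer bulk — and arms a molecule on a compartment visit.  Two details are
deliberate:

* entering the bulk zone on the *opposite* side disarms the molecule.
  This is what excludes apparent crossings that wrap through the periodic
  boundary without traversing the protein;
* completion requires an actual frame inside the destination compartment
  ("detected in the outer compartment", taken literally).  A transit whose
  compartment visit falls between two saved frames is not counted, so the
  frame stride must resolve the 5 A compartments; at the default 2 ps
  stride a bulk water moves ~1.7 A r.m.s., which is sufficient.

A molecule must fully exit into a compartment before a new event can start
for it, which prevents double counting; the completed event re-arms the
molecule on its new side, so a genuine back-crossing is counted again.

## Permeabilities

The diffusion permeability is computed from the bidirectional event count
`Nw` over a duration `T` as `pd = (Nw / 2T) vw` — the *unidirectional*
event rate times the volume of one water molecule.  The default
`vw = 3.018e-23` cm^3 (30.18 A^3) is configurable.

The osmotic permeability uses the collective-diffusion route: the
coordinate n(t) accumulates, per frame pair and per water, the
displacement clipped to the inter-plane region divided by its length
`L = Delta`.  This makes a full transit contribute exactly +/-1, a
same-side excursion 0, and a periodic wrap through the bulk 0, with exact
telescoping (the minimum-image step is used, so wrapped trajectories are
handled without unwrapping).  `pf = vw Dn`, with `Dn` half the slope of
the time-origin-averaged MSD of n(t), fitted by least squares over lag
times in `[fit_window/5, fit_window]` (default window 100-200 ps; the
intercept absorbs the bounded short-time component).  No fitting protocol
is standard for this estimator; time-origin averaging with a linear fit
over a decade of lags is the package's choice.

For single-file transport holding N waters the ratio `pf/pd` approaches
`N + 1`; values below 2 indicate non-single-file transport.
`permeability_summary()` reports the ratio and the regime flag.

## What the synthetic generators emulate — and what they do not

`simulate_channel_water()` integrates overdamped (position) Langevin
dynamics: free lateral diffusion in two ~10 A bulk reservoirs, an
impenetrable membrane slab pierced by a cylindrical channel, an optional
tabulated axial potential U(z) (e.g. `gaussian_barrier()`, default height
4 kcal/mol as typical of an inward-facing constriction), periodic
boundaries in all three directions.  Inertia is irrelevant at the 2 ps
analysis stride, which is why position Langevin suffices.  A stability
guard rejects timesteps for which the deterministic step
`|U'| D dt / kBT` would exceed 0.5 A.

Single-file mode realizes the site-hopping picture of a tight pore — the
model for which the `N + 1` law is derived: the N in-channel waters occupy
evenly spaced solvation sites (spacing `a = span/N`) and advance by
concerted one-site hops, driven by an internal continuous column
coordinate performing overdamped Brownian motion with collective diffusion
`D/N` (additive friction).  When the column accumulates a full site
spacing, the file shifts: the leading water exits into its reservoir and
the reservoir water nearest the opposite mouth is admitted at the trailing
site, keeping the occupancy at exactly N at every step.  Each occupant
jitters around its site with a bounded sub-Angstrom Ornstein-Uhlenbeck
term, so waters never pass each other and in-channel waters never reach
the detection compartments between hops.  Under this model the entry
statistics are exactly the gambler's-ruin chain (crossing probability
`1/(N+1)`) and `Dn = (D/N)/a^2`, so `pf/pd -> N+1` is an emergent
prediction, not an assertion.

`sample_bead_network()` draws independent frames from a prescribed
covariance about a reference structure, optionally superposing a rigid
rotation about the centre of mass, and removes the mass-weighted CoM
translation exactly from every frame.  Because the CoM removal is a
projection, covariances supplied for testing should live in the subspace
with zero mass-weighted net translation; helper patterns in the test suite
are built that way.  Frames are uncorrelated in time — adequate for
recovering spectra and weights, but carrying no kinetic information.

Neither generator models explicit three-site water geometry, hydrogen
bonding, electrostatics during generation, or lipid dynamics; charges and
LJ parameters are static labels consumed by the energy-profile stage.
Passing tests on these systems therefore validate the estimators and their
bookkeeping, not force-field realism.

## Density and per-transit profiles

`density_profile()` is a time-averaged z histogram normalised to number
density with the lateral box area; the channel opening `dmin` is the
profile minimum within the 30 A membrane span, with ties broken toward
z = 0 and an explicit degenerate flag for all-zero profiles.  Default bins
are 1 A (1 A x 1 A for the layered 2D maps over six 5 A slabs).

`transit_profiles()` uses confined events only.  The residence-time
density credits each frame-to-next interval to the bin holding the
molecule and divides by the number of events, so the integral over the
span equals the mean transit time *exactly* (endpoint frames sitting in
the compartments just outside the span are clamped into the edge bins to
preserve this identity).  Mobility is the mean 3D displacement over a 2 ps
lag per z bin.  Interaction energies are plain truncated Lennard-Jones
(CHARMM Rmin/2 convention, Lorentz-Berthelot combining) plus Coulomb
(332.0636 kcal A / (mol e^2)) at a 12 A cutoff — analysis energies for
per-molecule profiles, not simulation forces; the cutoff discontinuity is
negligible for binned profiles, and plain truncation keeps the closed-form
spot values (-33.206 kcal/mol for unit opposite charges at 10 A; -eps at
the LJ minimum) exact.  The force profile `|dU/ds|` uses centred finite
differences of the per-molecule energy along its own 3D path length — `ds`
is taken as path length because the increment is a displacement along the
transit.  The "total" energy sums all non-self atoms (protein, membrane
and other waters); the protein-only term is reported separately.

## PCA, vibrational weights and softness

`four_bead_reduction()` builds two beads per domain (bundle, hash): the
centres of mass of the lower and upper halves, split at the domain's own
CoM z in the time-mean structure so the atom assignment is stable across
frames.  `bead_pca()` computes the covariance of the centred (optionally
mass-weighted, `q = sqrt(m) r`) coordinates and its eigendecomposition;
mode stiffness is `kappa_i = kBT/lambda_i` by equipartition, and the
mass-weighted branch yields quasi-harmonic frequencies
`omega_i = sqrt(kBT/lambda_i)` (in ps^-1, using 1 kcal/mol = 418.4 amu
A^2/ps^2).  Rigid-body translation is removed exactly; rotation is *not*
removed but handled statistically through the vibrational weight:
`W_tot = 1/2 sum_k m_k |e_k|^2`, `Gamma = sum_k m_k r_k x e_k` (the
angular momentum of the displacement field about the CoM — the standard
rigid-rotation kinetic energy, which resolves the ambiguity between
squaring the vector sum and summing squares in favour of the former),
`W_R = |Gamma|^2 / 2J` with J the moment of inertia about the Gamma axis,
and `wv = (W_tot - W_R)/W_tot` clamped to [0, 1].  A pure two-bead stretch
gives wv = 1 exactly; a rigid rotation about a principal axis gives
wv = 0.

The headline softness is `sigma = sum_i lambda_i wv_i`, reported in A^2 to
match how such values are quoted (e.g. ~0.01-0.03 A^2 for coarse domain
models of a transporter); the per-kBT reading `sigma/kBT` (the sum of
reciprocal mode stiffnesses) is attached as an attribute so both unit
conventions of the defining relation are available.

Projected softness uses the *squared* projection,
`sigma_P = sum_i lambda_i wv_i (P . e_i)^2`.  A linear projection would be
sign-indeterminate (eigenvector signs are arbitrary — the package fixes
them only by convention) and could go negative, contradicting sigma_P's
role as an intensity; the squared form is also what makes
`sum_basis sigma_P = sigma` hold over any orthonormal basis and
`sigma_P <= sigma` for any single P.  `rocking_bundle_vectors()` supplies
the two reference patterns that modulate the bundle-hash separation
(symmetric separation, and rocking — upper beads converge while lower
beads diverge), CoM-free and mutually orthogonalised.

The atom set behind the "selected channel residues" softness is a user
selection, not hard-coded — pathway residues differ between systems — and
the same weight/softness machinery is applied per selection.

## Windows and correlations

`window_stats()` splits the trajectory into consecutive windows (default
100 ns; the trailing remainder is dropped) and computes per window: the
permeation rate `nw`, the opening `dmin`, the four-bead softness, the
selected-residue softness, the rocking-bundle projected softness (sum over
the two patterns), and the local constriction diffusion `D/L`.  The
constriction is a 5 A slab centred at the window's *own* density minimum,
since the constriction is tied to the profile minimum; D comes from the 3D
MSD of waters over lag times 2-10 ps using only path segments that stay
inside the region (a 1D z-only variant is available), and L = 30 A.
Pearson correlation with a least-squares line is the default (the panels
are linear fits); Spearman is available.  Windows with `dmin = 0` have an
undefined `nw/dmin` and are dropped listwise; degenerate panels surface an
explicit error rather than a silent NA.

`make_window_fixture()` provides ground truth for the sign structure: one
effect scale modulates either the constriction barrier (`"opening"` — the
opening/flux panel), or the water diffusion plus the domain-fluctuation
amplitude at fixed barrier (`"dynamics"` — the softness and D/L panels),
or both.  Windows are generated as independent segments, so events
spanning a window boundary are lost by construction — a deliberate
simplification.

## Problem sizes and reproducibility

All randomness is seeded explicitly; a given generator spec is
bit-reproducible.  The sizes used by the shipped tests and the acceptance
script are the package's study conditions: the single-file law runs N = 4
with 2e6 Brownian steps at dt = 0.5 ps (1 microsecond — the scale of
production simulations in this field; ~400 events, ~5% counting error,
15% agreement band on N + 1); the wide-channel control uses 80 independent
waters over 100 ns; oracle equivalence uses twenty ensembles of 200
random-walk waters over 5e4 frames; PCA recovery uses 5e4 frames (>100
frames per degree of freedom, 5% bands); the correlation fixtures use
eight 5 ns windows.

## Known limitations

Orthorhombic boxes only; no trajectory alignment by rotation (by design —
wv handles residual rotation); no PME electrostatics or free-energy
estimation; DCD and PDB/PSF/CSV are the supported formats (no XTC reader
exists in this R stack); statistical inference on the correlations is
limited to a permutation sanity check — no autocorrelation-aware
time-series inference.  Single-water volume vw enters pf and pd as a
multiplicative constant; comparisons of ratios are independent of it.

## A worked example

```{r example}
library(aquaperm)

spec <- channel_spec(n_waters = 30, n_steps = 2e6, dt = 0.5, save_every = 10,
                     single_file = TRUE, single_file_occupancy = 4,
                     channel_radius = 2, seed = 42)
traj <- simulate_channel_water(spec)
waters <- select_atoms(traj, segment = "water")
permeability_summary(traj, waters, fit_window = 200)
```
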