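---
title: "Methods: continuum-electrostatics titration and Monte Carlo protonation sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuum-electrostatics titration and Monte Carlo protonation sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkasim)
```

## The model

A protein with $N$ titratable sites occupies one of $\prod_i m_i$
protonation/tautomer microstates. Writing $x_i \in \{0,1\}$ for the
protonation count of the state $s_i$ chosen at site $i$, the package
uses the standard microstate energy in pK units,

$$E(\mathbf{s}) \;=\; \sum_i \big[\, x_i(\mathrm{pH} - \mathrm{p}K^{mod}_{i,s_i})
  + (\mathrm{p}K^{mod}_{i,s_i} - \mathrm{p}K^{int}_{i,s_i}) \,\big]
  \;+\; \sum_{i<j} W(s_i, s_j),$$

which reduces to the familiar
$\sum_i x_i(\mathrm{pH}-\mathrm{p}K^{int}_i) + \sum_{i<j}W$ when every
non-reference state is protonated; the extra term carries the transfer
free energy of deprotonated tautomers. Multiplying by $kT\ln 10$
(1.418 kcal/mol at 310 K) converts to energy units. The all-reference
microstate has $E = 0$ by construction, and a single site with
$\mathrm{pH} = \mathrm{p}K^{int}$ is half-protonated — this
Henderson–Hasselbalch identity fixes the sign convention and is
asserted in the tests.

$\mathrm{p}K^{int}$ (the *intrinsic* pKa: the site in the protein
environment with all other sites in their reference states) is obtained
from two continuum-electrostatics charging calculations,

$$\mathrm{p}K^{int}_{i,s} = \mathrm{p}K^{mod}_{i,s} -
  \frac{\Delta\Delta G_{i,s}}{kT\ln 10}, \qquad
  \Delta\Delta G_{i,s} = \Delta G^{protein}_{s\to ref} -
  \Delta G^{model}_{s\to ref},$$

where the *model compound* is the site's fragment (here: its
side-chain bead set) alone in solvent. $\mathrm{p}K^{mod}$ anchors the
calculation to experiment: it is the calibrated pKa of that fragment,
referenced to the alanine-pentapeptide scale shipped in
`inst/extdata/pentapeptide_reference_pka.tsv`.

$W$ couples pairs of sites. It is read off the protein-context
potential of one site's state charges at the other site's atoms,
double-difference corrected against the reference states (so reference
rows are zero) and symmetrized by averaging with its transpose; the
largest residual asymmetry before averaging is a grid-discretization
effect.

## Poisson–Boltzmann numerics

The linear PB equation
$\nabla\!\cdot\!(\varepsilon\nabla u) - \varepsilon_s\kappa^2\lambda u
= -4\pi C \rho$ (potential $u$ in kT/e, lengths in nm, charges in e,
$C = e^2/4\pi\varepsilon_0 kT$) is discretized on a cubic grid with the
7-point stencil and solved by red–black successive over-relaxation with
the optimal-$\omega$ estimate $2/(1+\sin(\pi/n))$. Iteration stops when
the largest node update falls below `convergence_tol` (default
0.01 kT/e, the production threshold); non-convergence within
`max_iter` = 20,000 sweeps is an error.

Choices that matter for accuracy:

* **Dielectric boundary.** The dielectric is sampled on grid *edges* as
  the harmonic mean of $\varepsilon_{in}$ (default 2) and
  $\varepsilon_{out}$ (default 80) weighted by the fraction of the edge
  inside the van der Waals union of atom spheres (optionally inflated
  by `probe_radius`). The fractional weighting places the boundary with
  sub-grid resolution; with the default grids the focused Born-sphere
  energy is within ~0.1% of the analytic value, and the error decreases
  monotonically under grid refinement (asserted).
* **Charges** are spread to the eight surrounding nodes with trilinear
  weights, conserving total charge exactly (asserted to 1e-12 e).
* **Focusing.** A coarse solve (0.1 nm spacing, analytic Debye-screened
  Coulomb boundary values, box auto-inflated with a warning when the
  default 81-node box does not cover the solute) supplies boundary
  values, interpolated trilinearly, for a fine solve (0.025 nm) centered
  on the titratable group. Both grids use 81 nodes per side by default.
  Background atoms outside the inner region of the fine grid take their
  potential from the coarse solution.
* **Grid self-energy.** The singular self term of an on-grid charge is
  large but identical between the protein and model-compound contexts
  because both use the *same fine grid* centered on the site, so it
  cancels in $\Delta\Delta G$; an isolated model compound gives
  $\mathrm{p}K^{int} = \mathrm{p}K^{mod}$ exactly, and a node-count
  doubling moves a buried toy site's $\mathrm{p}K^{int}$ by < 0.004 pK.
* **Ionic strength.** Not part of the printed production settings;
  the default is 0.1 mol/L (1:1), a common continuum-electrostatics
  choice, with $\lambda = 0$ inside the solute. All analytic oracles
  are evaluated at 0 M where the closed forms are exact.
* **Known anisotropy.** The discrete Green's function deviates from
  $1/r$ by ~4% at three grid spacings on-axis, decaying quadratically;
  energies are therefore always evaluated through the focusing
  machinery rather than raw near-source potentials.

## Atomic radii from Lennard-Jones parameters

The continuum radius of an atom is derived from its 12-6 interaction
with a water-oxygen probe (defaults $\sigma = 0.3166$ nm,
$\varepsilon = 0.6502$ kJ/mol): the distance $r^*$ on the repulsive
branch where the combined potential equals $+2RT$ (T = 310 K default),
located by root bracketing below the potential minimum. A pair
potential yields a contact *distance*; how it maps to a per-atom radius
is genuinely open, so both conventions are implemented:
`subtract_probe = TRUE` (default) subtracts the probe's own contact
radius $r^*_{probe,probe}/2$, keeping radii pairwise additive and the
water radius self-consistent; `FALSE` returns the full contact
distance. The full attractive-plus-repulsive pair is used (not the
repulsive term alone). Force-field hydrogens with $\varepsilon = 0$
have no repulsive wall and receive a fixed small radius (default
0.05 nm) instead of failing.

## Monte Carlo sampling

One cycle is a randomized sweep over all single-site moves plus one
joint move for every *coupled pair* — pairs whose largest
$|W|$ over state combinations exceeds `pair_threshold` (default 2 pK).
A single move proposes a uniform alternative state; a pair move draws an
independent uniform state for each member; both accept with
$\min(1, 10^{-\Delta E})$. Each individual kernel satisfies detailed
balance, so the stationary distribution is Boltzmann regardless of the
sweep composition; the tests verify stationary occupancies and net-flux
antisymmetry against exact enumeration and show the documented failure
mode that motivates pair moves (a $W = -6$ pK frustrated pair mixes
> 5× slower without them). Defaults are $10^5$ cycles with optional
burn-in; the RNG is R's Mersenne-Twister seeded explicitly, and the
seed is recorded in every result object, making runs bit-reproducible.

`enumerate_exact()` sums the Boltzmann weights over all microstates
(refused above $10^6$ states) and is the correctness oracle throughout;
`sample_assignment()` returns the *final* microstate of a run, which is
what the stochastic-titration cycle hands to the conformational
sampler.

## Titration analysis

Replicate occupancy series are aggregated after discarding the first
`burn_in_fraction` (default 0.2, mirroring the use of the 10–50 ns
segment of 50 ns production runs) with the SEM across replicates;
optional fixed-width sliding windows produce per-window curves for
convergence analysis. Per-site mean curves (not pooled replicate
points — a deliberate choice, since the replicate mean is what the SEM
describes) are fitted to
$f(\mathrm{pH}) = 1/(1+10^{\,n(\mathrm{pH}-\mathrm{p}K_a)})$ by
Levenberg–Marquardt least squares, started at $n = 1$ and the pH
nearest half-protonation, with $n \in (0, 5]$ and pKa unbounded. A fit
is flagged unconverged — never an error — when fewer than 3 points lie
strictly inside (0,1), when the optimizer fails, when the fitted pKa
falls outside $[\min(\mathrm{pH})-2, \max(\mathrm{pH})+2]$ (curves
titrating outside the simulated range, e.g. tyrosines extrapolating
past pH 12), or when $n \le 0.05$ (a collapsed slope: nothing titrates
in range). Errors are leave-one-replicate-out jackknife values,
$\sqrt{\tfrac{m-1}{m}\sum_k (\mathrm{p}K_{a,(-k)} - \overline{\mathrm{p}K_a})^2}$,
with failing combinations dropped and counted.

Total charge curves weight each site's formal charges by its
protonation fraction plus a fixed background; the isoelectric point is
the root of the linear interpolation (smallest root with a warning if
the curve crosses zero repeatedly). Benchmarks report RMSE, MAE, mean
error (predicted − experimental, so positive means overestimation) and
maximum deviation, globally and per residue type, with excluded
residues listed; the *null model* replaces every prediction by the
residue-type reference pKa and is evaluated on the identical residue
set.

## Calibration

`calibrate()` iterates
$\mathrm{p}K^{mod} \leftarrow \mathrm{p}K^{mod} +
(\mathrm{p}K_a^{exp} - \mathrm{p}K_a^{sim}(\mathrm{p}K^{mod}))$
until agreement within `tolerance` (default 0.05 pK) or `max_rounds`.
A single shift-and-correct pass is the classical procedure and is
available (`single_pass = TRUE`); the iterated loop is the default
because sampling noise in $\mathrm{p}K_a^{sim}$ can leave residual bias
after one pass. The desk-scale engine titrates a bead-model
Ala₂-X-Ala₂ pentapeptide (capped termini unless the terminus itself is
calibrated, in which case an all-Ala peptide is used) over a pH grid of
±1.5 units around the current guess by exact enumeration or Monte
Carlo.

## The desk-scale pipeline and what the tests do (and do not) show

The MD segment of the stochastic-titration cycle is a pluggable
provider (`advance`, optional `relax` hook standing in for the brief
frozen-solute solvent relaxation, `conformation_id`). Three providers
ship: rigid, ensemble-cycling, and Gaussian jitter. Segment lengths are
expressed in provider steps; in the full method they correspond to
τ = 20 ps of dynamics and a 0.2 ps relaxation. Providers that revisit
identical conformations advertise cacheability and their energy tables
are reused — an exact optimization.

Counterion estimation takes per-pH solute charge series, neutralizes
the mean with the nearest integer number of opposite-sign monovalent
ions (a half-integer tie breaks toward *fewer* ions: minimal
perturbation), and the restart rule flags any pH whose running mean
drifts more than 1 protonic unit (strict, with a 1e-9 float guard) from
the estimate, recomputing its count.

The synthetic generators (Born spheres, two-site rods, bead
pentapeptides, random n-site energy tables with attached ground truth)
emulate the *algorithmic* content of the method: continuum energetics,
coupled sampling, titration statistics. They do not emulate explicit
solvent, force-field charge distributions, conformational coupling or
real protein geometry — so passing tests demonstrate correctness of
the machinery and its statistics, not real-protein pKa accuracy, which
requires cluster-scale dynamics outside this package's scope.

Problem sizes used by the test suite and the acceptance script (chosen
as the smallest sizes that leave the oracles' tolerances
well-separated from the observed errors): 33–41-node grids for most PB
unit tests and 81-node production grids for the Born/Coulomb/identity
checks; $10^4$–$10^5$ Monte Carlo cycles; 8-site enumeration oracles;
100-seed Hill-recovery sweeps.

## Known limitations

* Union-of-spheres dielectric boundary (optionally probe-inflated), not
  a solvent-excluded molecular surface; for tightly packed solutes the
  two differ.
* The model-compound context uses the site's fragment atoms only;
  backbone cap atoms are not included in its dielectric.
* Linear PB only; no nonlinear response, no periodic electrostatics.
* The coupled-pair proposal is a simple independent redraw — equivalent
  in stationary distribution to more elaborate double-move schemes, but
  not move-by-move identical to them.
* Bead fixtures titrate one site per residue and carry single-bead
  side chains; multi-atom charge sets are exercised (`GL2`) but real
  rotamer-resolved tautomer geometry is not represented.
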