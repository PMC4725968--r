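---
title: "Rigidity analysis of protein constraint networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity analysis of protein constraint networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rignet)
```

## The model

rignet treats a protein as a *body-bar constraint network*. Every heavy atom
is a rigid body with six degrees of freedom (hydrogens are merged into their
parent atom, terminal single-bonded atoms such as the carbonyl oxygen into
their neighbor); interactions are bars that remove relative degrees of
freedom between body pairs:

| source                 | bars | diluted? |
|------------------------|------|----------|
| locked covalent bond (peptide, resonance, ring) | 6 | no |
| rotatable covalent bond | 5 | no |
| hydrogen bond           | 5 | yes, at its energy |
| salt bridge             | 5 | yes, at a fixed energy (default −10 kcal/mol) |
| hydrophobic tether      | 2 | no |

Generic rigidity of such a multigraph is decided combinatorially: a bar
multiset is independent exactly when every sub-multiset spanning $n'$ bodies
contains at most $6n' - 6$ bars. The *(6,6) pebble game* maintains this
count in near-linear time: each body holds six pebbles, a bar is accepted
when seven pebbles can be gathered on its endpoints, and an accepted bar
pins one pebble. The internal degrees of freedom are the free pebbles
($\mathrm{DOF} = 6n - \#\text{independent bars} \ge 6$), and the rigid
clusters are read off by gathering a seed body's six pebbles and collecting
all bodies that cannot reach any other free pebble. Because bodies carry all
six degrees of freedom, mutual rigidity is transitive and the clusters
partition the bodies; we label them by decreasing size (ties broken by the
smallest contained body index) so outputs diff cleanly. A brute-force
count-matroid oracle (`brute_force_decomposition()`, exponential, $n \le 8$)
validates the game on hundreds of random multigraphs in the test suite.

## Interaction detection

Hydrogen bonds are scored with a 10–12 potential
$E = V_0\,[5(d_0/d)^{12} - 6(d_0/d)^{10}]\,F$, where $d$ is the
donor–acceptor distance and $F \in [0,1]$ multiplies squared-cosine
penalties on the deviation of the D–H···A angle from linearity and of the
antecedent–acceptor–hydrogen angle from an ideal value (120° by default;
the acceptor term can be disabled). Defaults: $V_0 = 8$ kcal/mol,
$d_0 = 2.8$ Å, donor–acceptor cutoff 3.6 Å, hydrogen–acceptor cutoff
2.6 Å, D–H···A ≥ 100°, acceptance threshold −0.1 kcal/mol. All constants
sit in `hbond_params()` because different force-field lineages use slightly
different values; the H···A screen is what discards the bent i→i+3
approaches inside an α-helix, leaving the canonical i→i+4 ladder. Salt
bridges (charged-group N/O pairs within 4 Å) enter the dilution with a fixed
−10 kcal/mol so they persist to high temperature; hydrophobic tethers
(C/S pairs within van der Waals contact + 0.25 Å) are never diluted.
Missing amide hydrogens are placed in-plane, bisecting the C–N–CA angle,
since crystal structures rarely include them.

## Thermal unfolding and $T_p$

Thermal unfolding is simulated by *constraint dilution*: hydrogen-bond-class
constraints are removed in order of increasing strength. The default grid
puts one state just below each distinct bond energy (energies agreeing to
10⁻⁶ kcal/mol share a step; the offset is 10⁻⁵ kcal/mol), so separation
energies are exact and no step-size artifacts arise; a fixed-step grid is
available. Each cutoff maps to a temperature through the linear relation
$T = a\,E_\mathrm{cut} + b$ with defaults $a = -20$ K·mol/kcal, $b = 300$ K.
These defaults are placeholders for an empirically calibrated relation;
every rank order, correlation, and $R^2$ the package reports is invariant to
the choice of any fixed negative-slope map, and the tests exploit exactly
that invariance.

The order parameter $P_\infty$ is the fraction of bodies in the largest
rigid cluster. It is non-increasing along the trajectory, and the cluster
count non-decreasing (bar removal can only lose rank). The phase-transition
temperature $T_p$ is, by default, the temperature of the state with the
largest single-step drop of $P_\infty$ (ties resolve to the lowest
temperature — the first time the network loses that much structure); a
two-state logistic fit (`sigmoid_fit`) is offered because a "melting point"
is conventionally a midpoint. Trajectories with fewer than three states or
an overall drop below 0.2 are flagged as transition-free rather than given
a number.

From the same trajectory the *rigid-contact stability map* records, for
every residue pair that shares a cluster initially (residues are judged at
their CA bodies), the cutoff $E_{rc}$ at which they first separate; pairs
co-rigid to the end are marked persistent. Summing $E_{rc}$ over interchain
residue pairs within 5 Å gives the interface rigidity energy (more negative
= a more stable interface); summing over pairs that cross an
secondary-structure element's boundary and dividing by the element length
gives per-element stabilities with a standard error over per-residue sums.

## Ensembles and correlation with growth temperature

`ensemble_tp()` runs the full pipeline per ensemble member and reports the
mean, sample SD ($n-1$; the error-bar convention is not standardized, so
sample SD is the defensible default), SEM and skewness of the $T_p$
distribution, excluding (and counting) members without a transition.
`correlate_tp_torg()` regresses mean $T_p$ on the source organism's optimal
growth temperature by ordinary least squares on the Kelvin scale
(unweighted by default; a $1/\mathrm{SEM}^2$-weighted fit is available).
Ensemble diagnostics follow standard essential-dynamics practice: Kabsch
superposition for CA RMSD, unweighted CA radius of gyration, and RMSIP over
the first ten principal components of the CA covariance computed after a
two-pass superposition on the 80% least-fluctuating residues (mass
weighting is deliberately omitted; only CA atoms enter).

## What the generators emulate

The synthetic module defines the study conditions:

* `make_helix(n)` — an ideal poly-alanine α-helix (φ = −57°, ψ = −47°,
  ω = 180°, standard bond geometry, amide H bisecting C–N–CA). It carries
  exactly $n-4$ backbone hydrogen bonds, so detector counts have a known
  ground truth.
* `make_toy_dimer()` — two copies of that helix with *planted* interface
  features: interchain hydrogen bonds realized at target energies (the
  donor–acceptor distance is solved on the 10–12 well, capped at 3.3 Å so
  the detector screens pass, with any remaining weakening expressed as an
  acceptor-angle deviation; the rigid-body placement of chain B is then
  optimized numerically and verified at detector level to 0.2 kcal/mol),
  Cβ–Cβ pairs at target distances (to 0.01 Å), and salt-bridge stubs. A
  small seeded jitter (0.01 Å) breaks the energy degeneracy of the ideal
  geometry so dilution proceeds in many small steps, as in real structures;
  planted bonds sit near opposite chain ends so the contact region stays
  small and no accidental interchain tether network forms. Unrealizable
  plants are rejected with a diagnostic rather than silently distorted.
* `make_ensemble()` — i.i.d. isotropic Gaussian coordinate noise per atom.
  The absence of covariance gives PCA/RMSIP tests an analytic null; it does
  *not* emulate the collective modes of a physical ensemble, so passing
  tests demonstrate correctness of the estimators, not realism of the
  fluctuations.
* `random_body_bar_graph()` / `make_two_block_network()` — abstract
  networks for the rigidity oracle and for planted two-state transitions.
  In a two-block network with $k \ge 2$ equal-energy bridges at $E^*$, the
  union is rigid until dilution passes $E^*$, so
  $T_p = a(E^* - \varepsilon) + b$ exactly; drawing $E^*$ per member from
  $\mathcal N(-3, 0.2)$ kcal/mol yields ensembles whose mean $T_p$ must
  recover $a\cdot(-3)+b = 360$ K within sampling error.

Because the planted two-helix dimers really do pack a few interchain
carbons within van der Waals contact, a planted interface of $k$ bridges
splits once fewer than $6 - 2t$ bar-equivalents remain, where $t \le 2$ is
the number of residual tethers — the generators keep $t$ small by
construction, and the monotonicity and discrimination tests assert the
behavior that matters.

## Numerical choices and degenerate inputs

* Altloc records resolve to the highest-occupancy conformer (ties:
  alphabetical) so parsing is deterministic; HETATM entities are kept but
  excluded from interaction detection by default.
* Secondary structure uses HELIX/SHEET records when present and a
  dihedral-window heuristic otherwise (helix φ ∈ [−100°, −30°],
  ψ ∈ [−80°, −5°], ≥ 4 consecutive; strand φ ∈ [−180°, −40°],
  ψ ∈ [60°, 180°] ∪ [−180°, −170°], ≥ 3); terminal residues qualify on
  their one defined dihedral. No hydrogen-bond-pattern (DSSP-style) logic
  is attempted.
* Relative B-factors are z-scored per chain (population SD); all-equal
  B-factors are an error, not a silent zero.
* The disulfide screen window 3.83 ± 0.18 Å is a closed interval; prolines
  are excluded, glycine by default lacks a Cβ and is skipped unless a
  virtual Cβ is reconstructed from N/CA/C.
* The pebble game result is insertion-order independent (a matroid
  property, asserted by shuffle tests); cluster labels are canonicalized by
  size then smallest body index.
* A free amino acid keeps three backbone bodies (N, CA, C) joined by
  rotatable bonds — backbone atoms are never merged away, so chain
  connectivity and CA-based residue reporting survive even in fragments.

## Problem sizes

The shipped tests and the acceptance script run on 8–12-residue helices and
dimers (40–150 atoms, 24–72 bodies), 200 random multigraphs with up to six
bodies, and two-block ensembles of 50 members × 5 seeds. These sizes give
exact combinatorial ground truths (oracle enumeration, planted transitions)
while a full dilution of a toy dimer takes well under a second; the same
code path accepts crystallographic dimers of several hundred residues,
where a single dilution trajectory is minutes rather than seconds in pure R.

## Known limitations

* Absolute $T_p$ values depend on the uncalibrated energy-to-temperature
  map and on system size; only differences, orderings and correlations are
  meaningful.
* The hydrogen-bond angular form is a pragmatic squared-cosine family, not
  a fit to any quantum-chemical benchmark; constants are exposed rather
  than asserted.
* No π-stacking, cation-π or metal coordination; electrostatics beyond the
  fixed-energy salt-bridge rule is out of scope, as are mmCIF input and
  DSSP-grade secondary structure.
* `make_toy_dimer`'s placement is an optimization, not a closed form;
  pathological plant combinations (e.g. bonds on opposite helix faces) are
  rejected as unrealizable rather than approximated.
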