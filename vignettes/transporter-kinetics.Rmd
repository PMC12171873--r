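---
title: "Non-Markovian state models and SOM pathway detection: methods"
author: "igmepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Markovian state models and SOM pathway detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igmepath)
```

# Scope

`igmepath` analyses molecular-dynamics trajectories of membrane
transporters along two legs that share featurization and I/O:

1. a **state-model leg**: geometric features (chi1 dihedrals,
   inter-helix distances) are projected by time-lagged independent
   component analysis (tICA), discretized by k-means, lumped into
   metastable macrostates by PCCA+, and propagated by an integrative
   generalized master equation (IGME) whose quality is checked by a
   Chapman–Kolmogorov (CK) test and summarized as mean first passage
   times (MFPT) and transition-path-theory (TPT) net-flux pathways;
2. a **pathway leg**: capped ligand–residue distances train a sheet
   self-organizing map (SOM); neurons are clustered by silhouette-guided
   Ward clustering, and ligand egress routes are read off the neuron
   transition network between the bound and unbound endpoint clusters.

Every stage is exercised end-to-end on seeded synthetic generators with
analytic ground truth, so the package is testable without any simulation
data.  Internally, lengths are ångström, times nanoseconds, angles
degrees, energies kcal/mol; residue numbers are 1-based as in the source
PDB, and frame and state indices are 1-based as is idiomatic in R.

# The state-model leg

## Featurization and tICA

Chi1 is the N–CA–CB–γ torsion with the standard γ-atom table (CG by
default; OG for Ser, OG1 for Thr, SG for Cys, CG1 for Ile/Val); residues
lacking a γ atom are skipped with a warning.  Rotamer classes follow the
convention trans (180°), gauche(+) (−60°), gauche(−) (+60°), with bin
edges at 0° and ±120°; some texts swap the gauche labels, and the
convention here matches the transporter literature this package serves.
Because dihedrals wrap at ±180°, `expand_circular()` maps each angle to
a (cos, sin) pair before tICA, which expects Euclidean coordinates.

`fit_tica()` solves the symmetrized generalized eigenproblem
C(τ)v = λC(0)v.  Covariances are accumulated **per trajectory** (a
lagged pair never straddles a trajectory boundary — boundaries are not
physical transitions), the instantaneous covariance averages the leading
and trailing windows (reversible estimation, which guarantees a real
spectrum; whether the original analyses used reversible estimation is
not documented, so this is recorded as a package choice), and a ridge
term `reg = 1e-6 · tr(C0)/d` keeps redundant features from making C(0)
singular.  Eigenvalues are clamped to [−1, 1]: finite sampling can push
them marginally outside the physical range.

## Microstates, macrostates

`fit_kmeans()` uses k-means++ initialization under an explicit seed
followed by Lloyd iterations, making microstate assignments
bit-reproducible.  Transition counts use a sliding window by default;
the transition matrix is estimated on the largest strongly connected
component (standard ergodic trimming — disconnected states are dropped,
not merged).  Two estimates are kept: the raw row-normalized matrix
(what the dynamics actually did — the input to the IGME) and a
symmetrized one (reversible, hence a real spectrum — the input to
PCCA+).

`pcca_lump()` implements the inner-simplex PCCA+ construction: the rows
of the top-m right eigenvectors lie near an (m−1)-simplex whose vertices
are the most metastable microstates; mapping those vertices to unit
vectors gives fuzzy memberships, clipped to [0, 1] and row-normalized.
For exactly decoupled blocks the transition matrix is reducible; a
vanishing (1e-9) uniform teleportation then defines the stationary
weighting without perturbing the structure.  The number of macrostates
is a user choice; the eigenvalue spectrum returned with the model is the
spectral-gap evidence to guide it.

## The IGME

A lumped observation of a Markov process is not Markov: implied
timescales estimated at short lags are biased fast, and the bias decays
only slowly with the lag.  The IGME repairs this with the integrated
memory-kernel form

T(t) ≈ A · T̂^t,

valid once t exceeds the memory relaxation time τk.  `fit_igme()` fits
this form in log-matrix space — ln T(t) ≈ ln A + t · ln T̂, elementwise
ordinary least squares over the window t ∈ {τk+1, …, τk+L} — and
recovers A (the integrated memory correction) and T̂ (the corrected
long-time propagator, row-normalized by clipping negatives and
renormalizing, since least squares does not preserve stochasticity).
The matrix logarithm is the principal one computed by
eigendecomposition; complex eigenvalues in conjugate pairs are fine,
while eigenvalues on the closed negative real axis or a near-defective
eigenbasis trigger a fallback to direct nonlinear least squares on
T(t) itself, initialized from the log-space solution on the usable
lags.  With L = 1 the single lag point is interpolated exactly with
A = I.

`scan_igme()` fits every feasible (τk, L) pair on a grid and selects by
RMSE between predicted and estimated transition matrices over **all**
lags beyond τk — fit window plus extrapolation — with ties resolved
toward the smallest τk, then the smallest L (parsimony).  The exact grid
used for a given system is configuration, not dogma.

Downstream quantities deliberately use T̂ only:

* **MFPT** solves (I − T_B)m = Δt·1 with the target state removed.  For
  a non-Markovian process the short-time correction A changes nothing
  about the long-time first-passage behavior that T̂ encodes, and MFPT
  from the row-normalized propagator is the documented convention.
  (The MFPT of a lumped process is not perfectly consistent with any
  single-matrix description; see the validation section.)
* **TPT** computes the forward committor (q(source) = 0, q(sink) = 1),
  the backward committor on the time-reversed chain, the gross flux
  f_ij = π_i q⁻_i T_ij q⁺_j, and the net flux max(0, f_ij − f_ji).
  Pathways are peeled off by iterative bottleneck (widest-path)
  decomposition until less than 1% of the total flux remains.  Source
  and sink default to the highest- and lowest-free-energy states, with
  ΔG_i = −k_B·T·ln(π_i/π_max) at 310 K (so the most populated state sits
  at 0 kcal/mol); k_B = 0.0019872 kcal/mol/K.

## The CK test

`ck_test()` compares the model-propagated matrix at each test lag
against the matrix re-estimated directly at that lag.  Uncertainty comes
from a seeded bootstrap over whole trajectories: per-trajectory count
matrices are computed once and resampled with replacement (200 draws by
default), which makes the bootstrap cheap and exactly reproducible.  The
model passes when its prediction falls inside the interval for at least
95% of matrix elements at every lag.  Two caveats the tests make
explicit: the interval covers **data** uncertainty only, so a model
estimated independently of the data (even the exact one) sits inside a
95% interval only about 95% of the time per element; and for a 2-state
system "95% of elements" means all of them, leaving the binary verdict
no slack.  The package therefore reports the per-lag pass fractions
alongside the verdict, and the discrimination claim (IGME passes where
the lag-1 MSM fails) is validated at a data volume — 40 trajectories of
10^5 frames — where the MSM's bias is several times the interval width.

# The pathway leg

## Features and SOM

The feature vector of a frame is the minimum-atom-pair distance from the
ligand to each tunnel residue, capped at 12 Å: beyond the cap a residue
carries no information about the ligand other than "far", and the cap
makes fully dissociated frames identical regardless of exit route.

`train_som()` is an online SOM on a non-periodic 10 × 10 sheet (corner
neurons have 3 lattice neighbors).  Per training cycle every frame is
presented once in a seeded random order; the best-matching unit and its
Gaussian lattice neighborhood move toward the frame.  The schedule
(learning rate linear 0.05 → 0.01; radius linear from half the grid
diagonal to 1; codebook initialized from per-feature quantiles at seeded
uniform levels) follows the defaults of the tool family this
reimplements; the original schedule is not documented, so these are
package defaults, not claimed fidelity.  Training is 5000 cycles by
default; for large frame counts a seeded subsample
(`max_training_frames`) trains the codebook and **all** frames are then
assigned BMUs, which is the quantity every downstream step consumes.

## Neuron clusters, network, pathways

Non-empty neurons are clustered by Ward's method on codebook vectors
with the cluster count chosen by maximum mean silhouette over a
candidate range (2–8 by default); empty neurons carry no conformations
and are excluded.  The neuron transition network counts
consecutive-frame BMU transitions, never across trajectory boundaries;
self-loops (dwelling) are recorded but excluded from pathway search —
dwelling is not transition.  At the cluster level, the **unbound**
endpoint is the cluster with the largest mean capped distance (cap
saturation) and the **bound** endpoint the smallest-mean cluster sitting
at an edge (degree ≤ 2) of the condensed network.  Pathways are simple
paths from bound to unbound ranked by bottleneck weight — robust to
dwell-time inflation, unlike total-weight ranking — and each pathway's
support is the number of trajectories whose run-collapsed cluster
sequence contains it as a subsequence.  A trajectory is assigned to the
pathway matched **latest** in its sequence: a molecule may probe one
branch and leave through the other, and the final match is the route it
actually took.

# Synthetic generators and what they do (and do not) show

## Lumped hidden chains

`two_pair_chain_spec()` builds a 4-state reversible chain — two
fast-exchanging pairs (exchange probability 0.2 per step) bridged by a
slow hop (0.01 per step), observed through a 2-state lumping at 0.1
ns/frame.  The defaults were fixed by exact linear algebra before any
sampled test: they give a 50-fold timescale separation, a lag-1 implied
timescale biased ~2.5% fast, and lumping memory that the IGME absorbs to
within a fraction of a percent.  Ground truth is exact: stationary
probabilities by eigenvector, macro MFPTs via the hidden chain with the
target macro set absorbing (started from the stationary distribution
restricted to the source lump), and slow timescales by eigenvalue.

Two honest limitations surfaced by the exact analysis.  First, the
macro MFPT of this family is a near-tie between estimators: the lag-1
MSM underestimates it by ~1.2% and the IGME's rate-based T̂
overestimates it by ~1.3%, so both are accurate and neither is reliably
closer; the discriminating observable is the slow implied timescale,
where the IGME is 1–2 orders of magnitude more accurate.  Second, at
10^6 frames the IGME timescale estimator's sampling spread (~2%) is
comparable to the MSM's bias (~2.5%), so on a minority of seeds the
MSM's error happens to cancel; the validation suite uses a fixed seed
and the acceptance script reports both errors as computed.

## The branching channel

`channel_spec()` defines a 2-D potential in which an overdamped Langevin
ligand (Euler–Maruyama, x ← x − D∇U·Δt/kT + √(2DΔt)·ξ) leaves a 3-kT
binding basin, climbs a confining stem, and chooses between two branch
arms (quartic bistable confinement, 8 kT inter-branch barrier) dotted
with 2-kT Gaussian wells at the pseudo-residue anchor sites — the
discrete interaction sites a real ligand hops between, and the feature
that makes neuron clusters discrete rather than a continuous glide.
Absorbing exits sit more than one distance cap beyond the last anchors,
so exit frames saturate every feature and the two routes merge into a
single unbound state, as for a ligand entering bulk solvent.  The toy
emulates branch topology, metastable stops, and cap saturation; it does
not emulate all-atom geometry, a membrane, or force-field physics, so
passing tests certify the detector's logic, not its behavior on any
particular transporter.

## Rotamer toys and geometric oracles

`generate_rotamer_toy()` places ideal four-atom sidechain fragments at
prescribed chi1 values (internal-to-Cartesian construction), giving the
dihedral code an oracle exact to numerical precision.  SASA uses
Shrake–Rupley with a deterministic Fibonacci sphere (960 points by
default; a 10,000-point run is the quadrature oracle in the tests, with
closed-form checks on isolated and caged atoms).  Contact residence uses
the strict rules of the field: contact below 4 Å, "consistent" above 50%
occupancy, both strict inequalities.

# Numerical choices and degenerate inputs

* Row-stochasticity is enforced to 1e-10 on input matrices and restored
  by clip-and-renormalize after least squares; predicted matrices are
  clamped to [0, 1] before reporting.
* Ties break deterministically everywhere: lowest frame index for
  representative frames, lowest state index for free-energy endpoints
  (with a warning), smallest (τk, L) in the scan, higher-ranked pathway
  on equal match positions.
* Degenerate inputs fail loudly: reducible chains, empty selections,
  flat free-energy landscapes, all-identical codebooks, windows
  exceeding the available lags, atom-count mismatches (naming the
  frame).
* Problem sizes in the validation suite — 10^6 frames for recovery,
  40 × 10^5 frames for CK discrimination, 200 egress trajectories with a
  3000-frame SOM training subsample — were chosen as the smallest sizes
  at which the respective contrasts are decisively resolved.

# Known limitations

* tICA has no kinetic-map or commute-map scaling.
* MSM estimation symmetrizes counts rather than maximizing reversible
  likelihood; no Bayesian error bars.
* The quasi-MSM (differential memory-kernel) route is intentionally
  absent; the integrated form is the whole point.
* SOM topologies are non-periodic sheets only.
* Trajectory formats are PDB and plain xyz text; binary formats (DCD,
  XTC) are out of scope.
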