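---
title: "Conformational switching and free-energy-guided enzyme design with confswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational switching and free-energy-guided enzyme design with confswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confswitch)
```

## Scope

`confswitch` implements the desk-scale analysis chain used to study how a
Ca^2+^-dependent O-methyltransferase recognises its coenzyme-A substrate,
and to design low-activity variants of it: conformational clustering of
molecular-dynamics snapshots, principal-component free-energy landscapes,
MM/PBSA component algebra with per-residue decomposition, solvated
interaction energy (SIE) scoring, segmented-Jarzynski and WHAM
potential-of-mean-force estimation, pore-radius profiling of the substrate
entry channel, and a dual free-energy-criterion mutant screen. The MD
engine, Poisson–Boltzmann and boundary-element solvers, normal-mode
entropy, and folding-stability predictors are *not* reimplemented: their
outputs (energy-component tables, reaction-field terms, TΔS values,
ΔΔG~folding~ values) are consumed as inputs. A seeded synthetic-data module
generates inputs with the statistical structure each stage assumes, so the
whole chain is testable without any trajectory download.

Units are fixed throughout: lengths in Å, energies in kcal·mol^−1^,
temperatures in K, with k~B~ = 1.9872×10^−3^ kcal·mol^−1^·K^−1^ and the
Coulomb prefactor 332.0637 kcal·Å·mol^−1^·e^−2^. Conversions (e.g. nm from
other toolchains) belong at I/O boundaries.

## Structures, trajectories and RMSD primitives

Structures and multi-model PDB trajectories are read and written through
bio3d; a plain CSV xyz-table dialect (`frame,atom,x,y,z`) is accepted for
synthetic data. The analysis selection defaults to Cα atoms whenever the
atom table names any.

Superposition is the Kabsch algorithm: SVD of the 3×3 cross-covariance
with a determinant correction so a reflection is never returned. Pairwise
RMSDs for the all-against-all matrix recompute the fitted residuals
explicitly rather than using the trace identity, which cancels
catastrophically (≈10^−7^ Å noise) for near-identical frames. RMSD, RMSF
and PCA are mass-unweighted — the upstream protocols leave weighting
unstated, and unweighted Cα fluctuations are the common default. RMSF
first superposes every frame onto an iteratively refined mean structure
(two refinement passes), so a common drift of all atoms contributes
nothing.

## Conformational clustering

`daura_cluster()` applies the greedy neighbour-count procedure: two
snapshots are neighbours when their pairwise RMSD is at or below the
cutoff; the unassigned snapshot with the most unassigned neighbours seeds
each cluster. Two choices the original formulation leaves open are pinned
down here and matter for reproducibility:

* the membership comparison is **inclusive** (≤), following the displayed
  indicator function rather than the accompanying prose "less than";
* neighbour-count ties break to the **lowest snapshot index**, making the
  partition deterministic. Cluster membership is then invariant to
  snapshot relabelling up to this tie rule.

The default 1.7 Å cutoff separates functionally distinct states of a
folded protein on Cα RMSD while tolerating the fluctuation of its rigid
core. Each cluster's representative is its lowest-potential-energy member,
ties again to the lowest index.

## Free-energy landscapes

`pca_project()` eigen-decomposes the Cartesian covariance of the selected
atoms after superposition; PC1/PC2 projections serve as reaction
coordinates. `free_energy_landscape()` bins them (default 50×50 over the
projection range) and inverts the normalised histogram through
ΔG = −k~B~T ln P at a default 300 K, shifting the lowest occupied bin
to zero. Empty bins are masked (`NA`), never assigned +∞, so grids stay
serialisable; a masked bin means "unvisited", not "infinitely high".
`find_basins()` takes local minima under 8-neighbour connectivity and
assigns every occupied bin by steepest descent; exact ties resolve by
linear bin index, so a perfectly flat grid returns its lowest-indexed
bins.

One caveat the landscape inherits from its estimator: with finitely many
samples the depth of a rarely visited bin is noisy, so basin *depths*
carry sampling error of order k~B~T/√(bin count) even when basin
*locations* are stable.

## MM/PBSA component algebra

A component row carries ELE~IN~, VDW~IN~, ELE~PB~, VDW~SA~, H and TΔS.
The Delta row is the field-wise `complex − receptor − ligand` difference,
and the binding estimate is ΔH = ELE~IN~+VDW~IN~+ELE~PB~+VDW~SA~ with
ΔG = ΔH − TΔS, TΔS stored exactly as printed tables carry it (positive
per system, negative in the Delta).

An important semantic point: the identity "H equals the four-component
sum" holds (to the 0.02 kcal·mol^−1^ slack of printed rounding) only for
the **Delta** row. Per-system H values are total enthalpies containing
internal bonded terms that cancel in the difference, so the row
constructor records consistency as an attribute by default and enforces
it (`strict = TRUE`) only where the identity is definitional — on Delta
rows. Published tables of this kind also contain genuine internal
inconsistencies; the package computes the formula and lets the caller
compare, rather than special-casing any printed number.

Per-residue decomposition rows (E~VDW~, E~ELE~, E~GB~, E~GBSUR~, total)
are ranked by ascending total, most favourable contributors first.
`vacuum_interaction_energy()` and `sasa()` (Shrake–Rupley counting on a
960-point golden-spiral lattice; ≤0.5% drift when refined to 4000 points)
exist to build physically coherent synthetic decomposition fixtures, not
to replace a production energy pipeline.

## SIE scoring

`sie_score()` evaluates
ΔG~bind~ = α·(E~c~ + ΔG^R^~bind~ + E~vdw~ + γ·ΔMSA) + C with the
calibrated defaults α = 0.1048, D~in~ = 2.25, ρ = 1.1,
γ = 0.0129 kcal·mol^−1^·Å^−2^, C = −2.89 kcal·mol^−1^. The reaction-field
term is a solver input; D~in~ and ρ are carried as parameters because the
input components are defined with respect to them. The function is affine
in each component (slopes α, α, α, α·γ), which the tests verify by finite
differences — a useful integrity check when wiring in external component
tables.

## Steered-work bookkeeping and PMF estimation

The harmonic guiding potential is U = ½k[vt − (X(t)−X(0))·n]², force
magnitude k·|lag| along the pulling direction; conventional slow-pulling
settings (k = 2.5 kcal·mol^−1^·Å^−2^, v = 1 Å·ns^−1^) are the defaults.

`jarzynski_segment()` computes −(1/β)·ln⟨e^−βW^⟩ through a log-sum-exp
reduction; the naive average underflows once βW exceeds a few hundred,
which real work values reach easily. `asmd_stitch()` closes each
reaction-coordinate segment with this exponential average, selects as
seed the trajectory whose final work lies closest to the segment estimate
(ties to the lowest index — the standard adaptive-steering contraction),
and accumulates segment estimates so the profile is continuous across
boundaries; the seed curve supplies the within-segment shape, with a
linear ramp absorbing its (small) final-work mismatch.

`wham_1d()` iterates the self-consistent unbiasing equations for
overlapping harmonic windows on a shared bin grid until the largest
window free-energy change falls below `tol` (default 10^−6^ kcal·mol^−1^,
cap 10^5^ iterations), then returns −k~B~T ln P shifted to zero minimum.
Windows that share no occupied bin with their neighbour trigger a
coverage warning — and a practical rule follows from the tests: read the
profile only where windows bracket it; a one-sided edge window anchors
its neighbourhood poorly.

Both estimators are provided because the upstream protocol invokes both
exponential work averaging and umbrella-sampling/WHAM without specifying
their combination; on matched planted double-wells they agree within
0.3 kcal·mol^−1^, which is also the honest scale of their sampling error.

### Statistical accuracy of the 25-track protocol

For Gaussian work with spread σ, the exponential average obeys
ΔG = μ − βσ²/2 exactly, which makes planted-truth recovery testable. At
the production-like protocol of 5 segments × 25 tracks with
σ = 0.5 kcal·mol^−1^, the total estimate carries ≈0.2 kcal·mol^−1^
sampling error (SD ≈ 0.27), so roughly a fifth of random ensembles miss a
±0.3 band. The test suite and the acceptance script therefore assert the
**mean** absolute recovery error over 15 replicate ensembles — a stable
statement about the protocol — rather than one lucky draw.

## Pore-radius profiling

`pore_radius_profile()` is a planar variant of the classic channel
profiler: at stations along a straight user-supplied axis, the radius is
max over in-plane centres of min~i~(|c−x~i~|−r~i~), optimised by a coarse
grid (default 0.5 Å) then a refined local grid (default 0.02 Å) within a
search disc (default 15 Å). Negative optima flag the station blocked.
The axis is a required input — no physically meaningful default exists
for an arbitrary structure. Two practical notes: for an isolated
synthetic ring stack the exterior is open space, so the search disc must
stay inside the rings; and a per-ring "radius − vdW" analytic profile is
only exact when ring spacing is large relative to the taper, otherwise
adjacent rings dominate the three-dimensional clearance.

## The mutant screen

`enumerate_mutants()` expands each site into its 19 substitutions plus a
flagged wild-type reference entry — 20 per site, 200 for the ten
binding-site residues, a count only reachable if the wild-type reference
entries are included. The screen keeps
substitutions with |ΔΔG~folding~| ≤ 2 kcal·mol^−1^ (stability), then
those with ΔΔG~bind~ = ΔG~bind~ − ΔG~bind~^WT^ ≥ 2 kcal·mol^−1^
(weakened affinity); both comparisons inclusive, as printed. The
finalist per passing site is the weakest binder (highest ΔG~bind~), exact
ties to the alphabetically first target — resolving the ambiguous "six
mutants for each residue" phrasing as one finalist per each of six
passing sites, which is the only reading consistent with six named
mutants. The wild-type reference ΔG~bind~ defaults to −10.17 kcal·mol^−1^
and is configurable. Stability and affinity providers are pluggable
tables; no folding-energy predictor is executed.

## What the synthetic generators emulate — and what they do not

* `gen_multibasin_trajectory()` draws frames from isotropic Gaussians
  about planted centre conformations. Centres must differ *internally*:
  a translated or rotated copy of a structure has zero Kabsch RMSD to it
  by construction, so "separated basins" means separated after
  superposition. It emulates metastable hopping, not barrier kinetics or
  correlated backbone motion.
* `gen_work_ensemble()` plants Gaussian final works at mean
  ΔG + βσ²/2 so the Jarzynski identity holds exactly in expectation, with
  linear within-segment accumulation. Real work distributions are skewed;
  the Gaussian model is chosen precisely because it makes the recovery
  target analytic.
* `gen_mmpbsa_tables()` plants a Delta over fluctuating
  complex/receptor/ligand snapshot rows with baselines of realistic
  magnitude for a solvated ~250-residue enzyme and a coenzyme-sized
  ligand.
* `gen_channel_structure()` builds ring stacks with known inscribed
  radii; `gen_umbrella_samples()` rejection-samples biased Boltzmann
  densities of a known 1-d potential.
* `gen_screen_providers()` plants per-site stability-pass counts and a
  designated weakest binder per site, with provider values for *all*
  mutants so the screen remains well-defined when its cutoffs are varied.

Every generator takes an explicit seed and restores the caller's RNG
state; outputs are bit-reproducible per (spec, seed). Passing tests on
these inputs validates the estimators' algebra and statistics; it cannot
validate force fields, sampling convergence of real trajectories, or any
biology — those live upstream of this package by design.

## Problem sizes and numerical choices in the shipped tests

The suite validates on sizes chosen to make sampling error small relative
to each tolerance while keeping the full run in a few minutes: 5 000
frames for PCA eigenstructure (ratio tolerance 15%), 10^4^ frames for the
closed-form RMSF check (3%), 200–300 frames for exact 3-basin recovery,
15 replicate 5×25 work ensembles for mean-error bounds, 17–21 umbrella
windows × 5 000 samples for barrier recovery (±0.3 kcal·mol^−1^), and
20 000 samples/window over 56 bins for the flat-potential flatness check
(±0.1 kcal·mol^−1^, dominated by per-bin counting noise). Brute-force
oracles cover clustering (N ≤ 12), superposition (quaternion method) and
pore radii (exhaustive 0.02 Å grid).

## Known limitations

* No 2-d WHAM, no time-lagged embedding, no curved pore axes, no
  multi-site combinatorial mutants.
* The Daura threshold-monotonicity property (coarser cutoff, no more
  clusters) is verified empirically on RMSD matrices from point clouds;
  it is not a theorem for arbitrary symmetric matrices.
* Printed reference tables of this analysis family can be internally
  inconsistent (a binding energy that differs from its own component
  recombination; an enthalpy that differs from the component sum by one
  printed digit). The package always computes the stated formula from the
  stated inputs and surfaces both numbers instead of adjudicating.
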