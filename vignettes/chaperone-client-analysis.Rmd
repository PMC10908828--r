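---
title: "Energetics, solvation and cavity analysis of chaperone-client complexes"
author: "ChaperoneDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics, solvation and cavity analysis of chaperone-client complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChaperoneDynamics)
```

# Scope and model

ChaperoneDynamics is a post-hoc analysis layer for molecular-dynamics
trajectories and cryo-EM models of chaperone-client assemblies. The
archetype is an HSP90 dimer whose two protomers enclose an interfacial
(luminal) cavity through which an unfolded client segment threads, with a
cochaperone bridging chaperone and client. The package quantifies five
things: which residue pairs interact and how strongly; the binding free
energy of a partner against the rest of the complex; how much each region
fluctuates and along which collective modes; the cavity's volume and the
client's occupancy of it; and how similar two chains or two conformational
states are. It deliberately does not integrate equations of motion,
prepare structures (protonation, missing atoms), or derive force-field
parameters: trajectories and a per-atom parameter table are inputs.

# Pairwise interaction energetics

For two disjoint atom groups the per-frame interaction energy of every
atom pair is the point-charge Coulomb term
$E_{coul} = k_e\,q_i q_j/(\varepsilon_{in} r_{ij})$ with
$k_e = 332.0637$ kcal·Å·mol$^{-1}$e$^{-2}$, plus the 12-6 Lennard-Jones
term with arithmetic-mean $\sigma$ and geometric-mean $\varepsilon$.
Pairs at 1-2/1-3 bond distance are excluded and 1-4 pairs scaled by 1/1.2
(electrostatic) and 1/2 (Lennard-Jones), the convention of the Amber
force-field family whose parameters the loader expects. Three choices
deserve comment:

* **No distance cutoff.** Decomposition here is analysis, not dynamics;
  summing all pairs makes the conservation identity exact (the
  residue-pair matrix sums to the directly computed inter-group energy to
  better than $10^{-6}$ kcal/mol, and the test suite holds it to
  $10^{-8}$ against a brute-force double loop).
* **$\varepsilon_{in} = 1$ (gas-phase) by default.** Published
  residue-pair salt-bridge energies of the magnitude seen in
  chaperone-client studies (tens to above a hundred kcal/mol) are
  gas-phase Coulomb sums; whether solvent screening should be layered on
  is a presentation choice, so the dielectric is a parameter.
* **Sign convention**: negative is favorable, matching the blue/red
  rendering of interaction heatmaps. `exportHeatmapTable()` writes the
  full-precision TSV and returns a copy clamped to ±1 kcal/mol (the usual
  colour threshold) for rendering only.

Replica statistics follow the multi-replica simulation convention: the
main matrix is the mean of per-replica frame averages; the stats layer
carries the per-replica means, the SD of those means, and
SEM = SD/$\sqrt{R}$. With one replica, SD and SEM are reported missing
rather than zero.

# MM-GBSA binding energetics

`mmgbsaBinding()` implements the single-trajectory protocol: receptor and
ligand coordinates are sub-selections of the complex frames, so internal
bonded terms cancel and the per-frame binding energy is
$\Delta E_{vdw} + \Delta E_{coul} + \Delta G_{GB} + \Delta G_{np}$.

The polar term uses the generalized-Born model with OBC-II rescaling:
pairwise Hawkins-Cramer-Truhlar descreening integrals over neighbours'
screened spheres give $I_i$, then
$R_i^{-1} = \tilde\rho_i^{-1} - \rho_i^{-1}\tanh(\alpha\Psi - \beta\Psi^2
+ \gamma\Psi^3)$ with $\Psi = I_i\tilde\rho_i$,
$\tilde\rho_i = \rho_i - 0.09$ Å and $(\alpha,\beta,\gamma) =
(1.0, 0.8, 4.85)$. The energy is
$E_{GB} = -\tfrac{k_e}{2}(1/\varepsilon_{in} - 1/\varepsilon_{out})
\sum_{ij} q_i q_j / f_{GB}$ with the standard smoothed interpolation
$f_{GB} = \sqrt{r^2 + R_iR_j\exp(-r^2/4R_iR_j)}$ and self terms
$f_{GB} = R_i$. Effective radii are recomputed for each subsystem in
isolation, which is what makes desolvation appear on complexation. The
descreening term is verified against an independent numerical quadrature
of the $1/r^4$ integral in the tests, and the single-ion limit reproduces
the Born expression to $10^{-6}$ relative error.

The nonpolar term is $\gamma_{np}\,\mathrm{SASA} + b$ with
$\gamma_{np} = 0.0072$ kcal·mol$^{-1}$Å$^{-2}$ and $b = 0$, on
Shrake-Rupley areas sampled with a deterministic golden-angle point set
(960 points, <1 % error on an isolated sphere; the point set is fixed, so
results are bit-reproducible). SASA radii default to the Lennard-Jones
$R_{min}/2$ of each atom.

Declared limits: interior dielectric 1, solvent 78.5, zero salt (no
Debye screening), no entropy term, single-trajectory only. These are the
de-facto defaults of widespread MM-GBSA tooling; published tables
computed with a different GB flavour or salt model will differ by design,
which is one reason study-scale reference energies are annotations here,
not targets. Per-residue decomposition assigns self/SASA terms to their
own atoms and splits every cross term half to each partner, so residue
contributions sum exactly to the per-frame total.

# Fluctuations and essential dynamics

`fitFrames()` removes rigid-body motion with a Kabsch fit per frame,
either onto the first frame or (default) onto an iteratively refined mean
(at most 10 rounds, mean-shift tolerance $10^{-6}$ Å; in practice planted
Gaussian trajectories converge in fewer than 5). RMSF is then the
root-mean-square deviation about the per-atom mean, and
$B = (8\pi^2/3)\,\mathrm{RMSF}^2$ converts to a crystallographic
temperature factor, exportable into the PDB B-factor column for
visualization.

To compare fluctuation maps across systems (e.g. a closed client-bound
state vs ligand-free semi-open dimers) the raw B profiles are normalized
jointly: all profiles divide by the pooled maximum and scale to 0-100.
This joint-max convention is the package's own choice of "normalized such
that states can be compared directly": it preserves within-system ratios
exactly and cross-system ordering, which is what side-by-side structure
colouring needs.

PCA operates on the population (1/F) covariance of mean-centred, fitted
Cα coordinates, mass-unweighted — backbone-level collective motion is the
object of interest, and the 1/F normalization makes the eigenvalues sum
exactly to the total coordinate variance (asserted to $10^{-8}$).
Rank-deficient covariances are legitimate (F < 3N): trailing eigenvalues
are zero and over-requests truncate with a warning. `exportModeTrajectory()`
writes mean ± amplitude·$\sqrt{\lambda_k}$ interpolations as multi-model
PDB for animation.

A subtlety the synthetic generator enforces: a planted fluctuation
direction must be orthogonal to the six rigid-body modes, because the
superposition step absorbs any rigid component. `makePlantedModes()`
projects random directions out of the rigid subspace before
orthonormalization; with that, PC1 recovers a planted mode with
$|\cos| > 0.99$ at 5000 frames and two planted variances at 4:1 are
recovered within 10 %.

# Luminal-cavity volumetrics

The cavity is measured on a cubic voxel grid (default h = 0.5 Å) in a
two-grid scheme. A probe-inflated grid (atom radii + 1.4 Å) is
flood-filled from the boundary to label the exterior: gaps narrower than
the probe cannot leak, which is what makes an interfacial cavity with
molecular-scale wall texture well defined. The cavity itself is the flood
fill from a seed point over the free voxels of the plain grid,
intersected with the non-exterior region; volume is voxel count × h³.
A seed whose region reaches the exterior at that probe radius means the
"cavity" is open to solvent, and the function says so rather than
returning an arbitrary number. Wall selection is the analyst's: for a
chaperone dimer the two protomer chains only, with client and cochaperone
excluded, so the client's own volume does not carve the cavity.

Client occupancy marks voxels inside the client's vdW radii (no
inflation) and intersects them with the cavity set; the fraction is
client volume / cavity volume, in [0, 1] by construction and monotone in
the client selection. On analytic phantoms the error is O(h): the
10×10×10 Å hollow-cube phantom measures 1000 ų at h = 0.5 (the
generator places the innermost wall layer exactly one vdW radius outside
the void so sphere surfaces are tangent to its faces), and a 100 ų
client block reads 10 % occupancy within grid tolerance. 6-connectivity
and the deterministic point ordering make the whole computation
reproducible bit for bit.

# Comparative analysis

Structure comparison is sequence-guided: a global Needleman-Wunsch
alignment (BLOSUM62, affine gaps, default open 10 / extend 0.5, `X`
scored 0) produces the residue correspondence, and one named atom per
matched residue (Cα by default) enters a Kabsch superposition. The
rotation is asserted proper-orthonormal on every call; RMSD is exact zero
(< $10^{-10}$ Å) on rigid copies and symmetric under argument swap.
Traceback tie-breaking is fixed (diagonal, then up, then left), so
alignments are deterministic; the DP is validated against exhaustive
enumeration for short sequences and against an independent aligner's
scores. Secondary-structure-based superposition methods used in
structural-biology practice select a different matched set, so RMSD
values between distantly related conformations carry a method tolerance
of a few tenths of an Å; sequence-guided matching was chosen because it
is fully specifiable and reproducible.

Percent identity divides identical pairs by aligned columns excluding
terminal overhangs (the alternative identical/shorter-length value is
reported alongside); similarity counts pairs with positive BLOSUM62
score, the package's operational definition where the literature leaves
"similarity" vague. `protomerAsymmetry()` wraps self-comparison of the
two protomer chains and returns the per-residue deviation profile, which
localizes displaced loops precisely (the tests plant one and find it).

Client-segment descriptors: GRAVY is the mean Kyte-Doolittle index;
percent hydrophobic counts A,V,L,I,M,F,W,C,P; pI solves
$Z(\mathrm{pH}) = \sum_{basic}(1+10^{\mathrm{pH}-pK_a})^{-1} -
\sum_{acidic}(1+10^{pK_a-\mathrm{pH}})^{-1} = 0$ (termini included) by
bisection to $|Z| < 10^{-4}$. $Z$ is strictly decreasing, so the root is
unique; the EMBOSS pKa set is the default and is configurable because
web peptide calculators differ in their internal sets and rarely
document them. Both hydrophobicity measures are emitted since published
client-segment tables rarely state which scale they used.

# The synthetic-data generator

Every stage is testable offline because the generator builds the study
conditions at toy scale, deterministically under a single seed (replica
sub-seeds are master + replica index; all output files are fixed-precision
text, so equal seeds give byte-identical files):

* `makeToyComplex()` — multi-chain pseudo-protein (two atoms per residue,
  single Lennard-Jones class, alternating or custom charges, full bond
  list), small enough that brute-force oracles run instantly.
* `makeGaussianTrajectory()` — frames = mean + planted orthonormal modes ×
  Gaussian amplitudes + isotropic noise, in replica blocks; this is
  exactly the statistical structure RMSF and PCA assume.
* `makeCavityPhantom()` — a sealed rectangular shell with tangent inner
  wall layer enclosing an analytic void, optional client block; rejects
  wall specifications thinner than the probe diameter.
* `makeThreadedDimer()` — the end-to-end scene: two protomer half-shells
  that are exact two-fold images of each other sealing an 8×4×4 Å
  channel, a 9-residue client threaded along the axis, one planted
  strongest salt bridge (+1/−1 across the wall) and one planted strongest
  vdW pair (deep wells near the Lennard-Jones optimum), plus region
  labels and a short multi-replica jitter trajectory. The documented
  ground truth (pair identities, channel volume, zero protomer-asymmetry
  RMSD) is recovered by the full pipeline; `plant = FALSE` produces the
  energetically inert control scene, against which the planted scene
  binds more favorably by construction.

What the generator does *not* emulate — solvent molecules, bonded-term
dynamics, realistic protein geometry, force-field heterogeneity —
delimits what passing tests show: they certify the analysis mathematics
and bookkeeping, not the physics of any particular force field. Results
on real systems inherit whatever approximations produced the trajectory.

# Numerical choices and degenerate inputs

Problem sizes in the shipped tests and acceptance script were chosen so
statistical checks are tight but quick: $10^4$ frames for RMSF recovery
(±2 %), 5000 for PCA (cosine ≥ 0.99, variance ratio ±10 %), 960 SASA
points (±1 %), h = 0.5 Å grids (±5 % on the 1000 ų phantom), a 96-atom
complex for the brute-force energy oracle ($10^{-8}$ kcal/mol).

Degenerate inputs are contracts, not surprises: interatomic distances
below 0.1 Å abort as corrupt frames; fewer than three non-collinear fit
atoms abort superposition; empty or overlapping selections abort the
energy routines; a selection naming an absent chain yields an empty set
with a warning (so one pipeline configuration ports across structure
dialects); altloc conformers collapse to the highest-occupancy copy;
insertion codes are appended to the residue key; single-replica
statistics report SD/SEM as missing; an all-zero pooled B-factor maximum
normalizes to zeros.

# Known limitations

* The GB flavour is fixed to OBC-II and salt to zero; Poisson-Boltzmann
  polar terms and entropy corrections are out of scope.
* Trajectory input is multi-model PDB or the plain frames format; binary
  MD formats and mmCIF are not read.
* Cavity analysis is single-structure; time-resolved cavity dynamics are
  not computed.
* RMSD against secondary-structure-matching superposition carries the
  method tolerance discussed above.
* Study-scale reference energies (microsecond, four-replica averages)
  are documented as annotations; they cannot be recomputed from the
  package's synthetic inputs.
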