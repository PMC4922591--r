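---
title: "Iterative elastic-network conformer generation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative elastic-network conformer generation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmexplore)
```

## The problem

Receptor proteins with hinge-bending domains can differ by 4–15 Å
Cα RMSD between their ligand-free (apo) and ligand-bound (holo)
states. Docking against the apo crystal alone fails for such targets,
and the holo structure is exactly what one does not have. `enmexplore`
generates an ensemble of conformers *accessible from the apo state*,
without using any information about a bound structure, so that docking
can be attempted against close-to-bound and intermediate states and
their full parent lineage.

## The model

**Elastic network.** Each residue is a node at its heavy-atom centroid.
Nodes $i, j$ are joined by a harmonic spring whose force constant is
proportional to the number of heavy-atom pairs (one atom from each
residue) within a 10 Å cutoff. This contact-weighted anisotropic
network concentrates stiffness at packed interfaces, which matters for
getting hinge mechanics right; the classical uniform-spring model
treats a loose crystal contact and a buried interface alike. The base
force constant is 1: only relative stiffness matters because
deformation amplitudes are renormalised below.

**Slow modes.** The $3N \times 3N$ Hessian is assembled from the usual
super-elements $H_{ij} = -k_{ij}\, \mathbf{d}\mathbf{d}^T / |\mathbf{d}|^2$
and diagonalised; the six near-zero rigid-body eigenvalues (relative
threshold $10^{-8}$) are discarded and the next $M$ eigenpairs
$(\mathbf{u}_j, \lambda_j)$ retained, $M = 3$ by default. Eigenvector
signs are fixed (first significant component positive) so runs are
reproducible; the coefficient alphabet is symmetric, so the sign
convention cannot bias sampling.

**Deformations.** Direction vectors are all combinations
$$\mathbf{V} = \sum_{j=1}^{M} a_j\, \mathbf{u}_j / \lambda_j^{1/2},
\qquad a_j \in \{-1, 0, +1\},$$
excluding the all-zero tuple — $3^M - 1 = 26$ directions for three
modes. The $1/\lambda^{1/2}$ weighting gives softer modes larger
amplitude, mirroring equipartition. Each direction is rescaled to
$|\mathbf{v}| = \mathrm{DF}\cdot\sqrt{N}$ so the per-node RMS
displacement equals the deformation RMSD DF exactly (2 Å by default;
3 Å is appropriate for transitions in the 15 Å class). The node
displacement is applied rigidly to every atom of the residue, so local
geometry survives and the raw Cα displacement RMSD from the parent is
DF by construction (superposed RMSD can only be smaller).

**Relaxation.** Deformed structures are repaired by energy
minimization through a pluggable backend. The physical backend
contract is implicit-solvent minimization (generalized Born with
Debye–Hückel salt screening at 0.1 M, 16 Å nonbonded cutoff, 500
steepest-descent cycles then conjugate gradient to a 0.01 kcal/mol/Å
gradient); bind an engine with `register_relax_backend()`. The
package ships a fully specified surrogate backend (`fallback`) used by
all tests: harmonic pseudo-bonds between sequential Cα atoms at their
parent-structure distances ($k = 10$ energy/Å²) plus one-sided
quadratic soft-sphere repulsion ($\sigma = 3$ Å, $k = 10$) between
heavy atoms of residues at least two apart in sequence. It is
minimized with L-BFGS (gradient tolerance 0.01) and exists for clash
relief and testability, not physical fidelity; its energies are on
their own scale and are never mixed with another backend's.
Non-convergent relaxations are discarded, mirroring what happens to
irreparably distorted structures under a physical force field.

**Clustering and iteration.** All relaxed children of a generation are
pooled with every ancestor conformer and clustered by mutual
superposed Cα RMSD using a fixed-radius k-means: a structure joins the
nearest centroid within the radius (set to DF) or founds a new
cluster; centroids are member averages after superposition onto the
cluster representative, and the representative — always a real
member, never the average — is the member closest to the centroid.
Representatives of clusters containing *no* ancestor become the
parents of the next generation, so each generation is forced outward
into unvisited territory. This is the fixed-radius interpretation of
cluster-count-free k-means used by structure-clustering tools; radius
semantics follow from setting the cluster RMSD cutoff to DF.

**Selection modes and termination.** Blind search iterates to a
user-set generation cap (the honest stop criterion: nothing in the run
knows the target). Energy-based search additionally requires a
representative's energy to be below the minimized starting structure's
to become a parent, and stops when none qualifies. With the surrogate
backend the relaxed apo sits essentially at energy zero and children
cannot go below it, so energy-based runs terminate after one
generation — the same behaviour a physical backend shows on proteins
whose first-generation conformers are all uphill from the apo.

**Filters and the docking chain.** After the run, conformers with
radius of gyration (Cα-based) above the starting structure's are
discarded — hinge closure compacts a chain, so expansion is noise for
this purpose. The boundary is inclusive: only strictly larger RG is
discarded. For multimers the filter can be applied per chain (keep if
any chain, or all chains, compacted). The docking ensemble is the
lineage chain: the lowest-RG surviving conformer (ties to the lowest
id), then its parents up to the apo root, written as a multi-MODEL
PDB.

**Re-seeding with a bound ligand.** For transitions that complete only
with a ligand present, a second stage runs the identical engine on a
docked complex: ligand residues become network nodes and deform with
the receptor, the reference energy is the minimized complex energy
(logged as such), and receptor-only RMSD/RG are reported separately
from whole-complex metrics.

## The synthetic hinge fixture

Real benchmark pairs require structure downloads and a molecular
mechanics engine, so the package carries a generator for a
two-domain hinge protein with known open and closed reference states:

```{r fixture}
hf <- make_hinge(n_per_domain = 28, target_rmsd = 5.0, seed = 1)
rmsd_ca(hf$open, hf$closed)
```

Each domain is a spherical-spiral Cα trace (flattened along z,
elongated along the inter-domain axis) dressed with a reduced
5-atom residue (N, CA, C, O, CB); a 4-residue linker, bowed so its
nodes stay in contact range of both domains, joins them across a short
gap that puts the facing caps in direct contact. The geometry was
designed so that the slowest network mode *is* hinge bending:
the cap contact stiffens inter-domain twist, the z-flattening splits
the two bending directions, and the elongation lengthens the bending
lever so that the 5 Å closing rotation stays moderate (≈56°). The
closed state is a rigid rotation of the distal domain about the hinge
axis through the linker, with the angle solved numerically so the
superposed Cα RMSD hits the target; both states are polished to
surrogate energy zero. The slowest-mode overlap with the open→closed
displacement is ≈0.92 across seeds — asserted in the test suite,
because it is the load-bearing assumption that makes closed-state
recovery a fair test of a 3-mode algorithm.

What the fixture does *not* emulate: side-chain chemistry, secondary
structure, anharmonic unfolding of the transition (the true path here
is a single rigid rotation), or attractive receptor–ligand forces.
Consequences: recovery tests demonstrate that the mode-combination
iteration can walk a hinge closure, not that any particular protein's
transition will be recovered; and because the surrogate potential is
purely repulsive, ligand-induced *further* closure (an induced-fit
effect driven by attraction) does not occur under the fallback
backend — the re-seeding machinery is therefore tested on its
mechanical contracts only.

## Numerical choices

* Problem sizes: tests and the acceptance script use the 60-residue
  fixture (5 Å transition), DF = 1.0 Å scaled to the fixture, at most
  5 generations, five seeds — about 30 s per run, chosen as the
  smallest system on which hinge recovery is a meaningful claim.
* Superposition is the quaternion least-squares fit (compiled); a
  base-R SVD implementation is kept and cross-checked in tests, with
  degenerate/reflection cases handled by the quaternion formulation.
* Rigid-body modes are removed by eigenvalue threshold, not
  projection; more than six near-zeros is treated as a disconnected
  network and refused (the builder warns at construction time).
* The deformation magnitude contract is on raw displacement (no
  re-superposition), which makes it exact rather than approximate.
* Clustering ties (representative selection, lowest-RG chain leaf) are
  broken by conformer id, so reruns are bitwise identical.
* altLoc resolution keeps the highest occupancy, ties by label order;
  HETATM records are dropped by default; hydrogens are read but
  excluded from centroids, contact counts and the surrogate potential.
* Residue pairing for RMSD uses the common author-numbered set within
  chains, with no sequence alignment: the intended inputs are
  conformer pairs of one sequence; for crystal pairs the common
  resolved set is used and its size is reported by the accession
  script.

## Design choices that were genuinely open

* *Pool all ancestors or only the previous generation into
  clustering?* All ancestors (default): it prevents a later generation
  from re-discovering territory two generations back. A
  `ancestor_scope = "previous"` switch exposes the cheaper variant.
* *Cluster centroids: coordinate averages or medoids?* Averages for
  distances (members superposed onto the representative first), with
  the emitted representative always a real member — the average
  structure never leaves the clustering.
* *Is the RG filter a per-generation pruning step?* No — it is a
  post-filter on the final set. Pruning during the run would bias the
  search, and the run's own stop criteria do not depend on RG.
* *Reference energy for re-seeded runs:* the minimized complex energy
  (receptor-only would mix energy scales across topologies).
* *Step order:* deformed children are relaxed before clustering, so
  cluster geometry reflects repaired structures; the alternative
  (cluster raw children, relax only representatives) is cheaper per
  generation but clusters unphysical coordinates.

## Limitations

* The fallback backend cannot rank conformer stability; energy-based
  selection is only meaningful with a physical backend attached.
* Dense eigendecomposition is used throughout; systems beyond ~1000
  residues would want a sparse/iterative solver.
* No missing-loop modelling, protonation, or sequence alignment; the
  engine assumes a chemically complete, single-conformation input.
* The generation count in blind mode is genuinely user-dependent;
  the package reports per-generation summaries rather than pretending
  to an automatic stopping rule.
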