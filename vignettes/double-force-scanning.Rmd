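---
title: "Double force scanning: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double force scanning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfscan)
```

## The physical model

`dfscan` treats a protein as an anisotropic network model (ANM): one node
per residue at its Cα position, Hookean springs of stiffness γ between
all node pairs closer than a cutoff r~c~. The second-order expansion of
that elastic energy around the native structure gives the 3N×3N hessian
**H**, whose 3×3 block for a connected pair (i, j) is
−γ·ê~ij~ê~ij~^T^ (ê~ij~ the unit inter-node vector) and whose diagonal
blocks make every super-row sum to zero, so rigid translations cost no
energy.

Linear response theory gives the displacement field under a static
external force analytically: ΔR = **H**⁺F, with the inverse taken as a
pseudo-inverse over the non-rigid spectrum. The central assumption is that
the structural strain introduced by a point mutation can be mimicked by a
force applied at the mutated site, without committing to a specific
amino-acid change; predictions are therefore positional.

A pathogenic mutation is modelled as a force **F**~i~, a candidate rescue
mutation as a simultaneous force **F**~j~, and the rescuability index

ρ~ij~ = (d(u, p~i~) − d(u, p~ij~)) / d(u, p~i~)

measures the relative reduction in deformation when the second force is
added. ρ ∈ (0, 1] indicates compensation, ρ = 1 exact cancellation, ρ < 0
aggravation, and ρ ≤ 1 always. Orientation matters, so each site samples a
spherical Fibonacci lattice of force directions; the pair score S~ij~
takes, for each first-site orientation, the *best* second-site orientation
(max over ρ), then averages over first-site orientations — "average-case
mutation at i, best-case rescue at j". All ordered pairs i ≠ j are scanned
under two magnitude schemes (FF: equal magnitudes; FR: the second-site
magnitude rescaled so both single forces deform the structure equally),
yielding matrices S^FF^ and S^FR^. A residue's compensatory power P is the
mean of the two schemes' min–max-rescaled ratios
(number of rescued first sites) / (contact degree), and the top 28 % of
residues by P are classified as predicted rescue sites.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `r_c` | 15 | Å | spring cutoff; the canonical ANM choice for Cα models. Smaller values risk floppy networks (rejected with an explicit error). |
| `gamma` | 1 | energy/Ų | spring stiffness. Displacements scale as 1/γ, so ρ, S and P are exactly γ-invariant (tested); the value is immaterial. |
| `n_orientations` | 12 | — | Fibonacci orientations per site; 12 gives near-icosahedral coverage at 144 ρ evaluations per pair. `dfs_convergence()` reports the max |ΔS| drift when the count doubles. |
| `magnitude` | 1 | arbitrary | base force magnitude. Within linear response every ρ is invariant under uniform force scaling (tested to 1e-10), so this only affects numerical conditioning. |
| `percentile` | 0.28 | — | top fraction of residues classified as rescue sites; the reference operating point for this class of predictor, applied as a strict threshold on the interpolated quantile. |
| `zero_tol` | 1e-6 | relative | eigenvalues below `zero_tol · λ_max` count as rigid. Separates the 6 rigid modes from soft internal modes in double precision up to N ≈ 10³. |

The distance function d is the RMS of per-residue displacement magnitudes
with **no rigid-body refit**: pseudo-inverse responses are exactly
orthogonal to the rigid subspace, so a refit is a no-op to first order,
and skipping it keeps the scan exactly reproducible and cheap.

## Numerical and algorithmic choices

* **Superposition.** Within LRT, ΔR~ij~ = ΔR~i~ + ΔR~j~ exactly, so the
  engine precomputes three unit-force responses per site (the site-block
  columns of **H**⁺) and evaluates every orientation pair through squared
  norms and one cross-product matrix per pair — no linear solve is ever
  repeated. A naive reference implementation (fresh force vectors, generic
  pseudo-inverse, explicit distance loops) agrees to 1e-10 in the test
  suite.
* **Rigid-mode handling.** The pseudo-inverse demands *exactly* 6
  eigenvalues below the zero threshold. More signals a planar,
  disconnected or under-connected geometry (out-of-plane and
  inter-cluster motions are zero-energy in an ANM); fewer signals a
  numerically broken hessian. Both abort with a diagnostic instead of
  silently inverting a defective spectrum.
* **Eigensolver.** Dense symmetric eigendecomposition: at the target sizes
  (N ≲ 1000, matrices ≤ 3000×3000) dense LAPACK routines beat iterative
  sparse solvers and carry no convergence parameters.
* **Ties.** The classification threshold is strict (`P >` the quantile),
  so an all-equal profile predicts nothing; the compensatory-motion argmax
  breaks exact ρ ties by the lowest orientation-index pair; the
  D-minimizing threshold search enumerates the observed score values and
  resolves ties toward fewer predicted positives. Each rule is
  deterministic by construction.
* **Degenerate rescaling.** If a scheme's rescued-count/degree ratios are
  constant across residues, min–max rescaling is undefined; the component
  is set to 0 everywhere, since a flat signal carries no compensatory
  information.
* **Altlocs and numbering.** PDB alternate locations resolve to the
  highest occupancy (ties: first in file); residue numbering and insertion
  codes are kept verbatim because reference tables use author numbering.
* **Contacts.** The "number of contacts" normalising the rescued count is
  the ANM degree (neighbours within r~c~), keeping the method
  self-contained in its own interaction graph. Proximity analysis of
  unpredicted sites, by contrast, uses minimum heavy-atom distances (4 Å
  cutoff) where heavy atoms are available, since 4 Å is not meaningful
  between Cα atoms; a Cα-only fallback (8 Å default) is applied and
  flagged when they are not.
* **Ordered pairs.** S is not symmetrized: rescuing i by j and j by i are
  different physical questions, and the matrices are kept ordered
  (rows = first/pathogenic site).

## What the synthetic fixtures emulate — and what they do not

`make_structure()` provides a regular tetrahedron (edge 3.8 Å), an ideal
α-helical Cα trace (rise 1.5 Å, 100° turn, radius 2.3 Å — consecutive Cα
spacing 3.83 Å, matching real backbones), a jittered cubic lattice and a
seeded self-avoiding globule at ~60 ų per residue. They reproduce the
*geometric* regime of protein ANMs: realistic nearest-neighbour spacing,
realistic contact degrees at r~c~ = 15 Å, connectedness, non-planarity,
exactly 6 rigid modes. They do not reproduce tertiary-structure
heterogeneity (sheets packed against helices, loops, domain interfaces),
side-chain packing or real heavy-atom geometry — fixture "heavy atoms" are
the Cα positions themselves. Green tests therefore certify the
*mechanics* of the method (linear response, scoring, aggregation,
evaluation arithmetic, determinism), not its biological accuracy on real
proteins, which depends on curated mutation datasets outside this
package's scope. `make_reference_labels()` draws labels uniformly at
random, so evaluation metrics on fixtures hover at chance level by design
— they exercise the arithmetic, not the predictor.

Problem sizes used throughout the tests and the acceptance script — a
60-residue helix for full scans (12 orientations, both schemes, ~0.5 s), 5-
and 6-residue fixtures for brute-force equivalence, 20-residue fixtures
for LRT oracles — were chosen as the smallest sizes at which every regime
(core vs terminal residues, converged orientation sampling, 6-mode rigid
spectra) is present.

## Design decisions that were genuinely open

* **Single-scheme runs.** With one scheme requested, P equals that
  scheme's rescaled component (the mean over a single component), and the
  other scheme's outputs are omitted entirely rather than written as
  placeholders.
* **Pair-specific rescue.** Whether "rescue sites for pathogenic site i"
  must also pass the global P threshold, or only S~ij~ > 0, is ambiguous;
  the default intersects with the classified rescue-site set (a site must
  first *be* a predicted rescue site), and `restrict = FALSE` exposes the
  looser variant for exploration.
* **Divergent positions.** Gap-containing alignment columns are not
  divergences — insertions/deletions are not point compensations — and
  only standard amino-acid pairs count; positions are reported in the
  ungapped numbering of the first (human) sequence.
* **Pocket threshold.** "At least 20 %" is inclusive: pct_RS = 0.20
  classifies as a rescue pocket.
* **Reproducibility policy.** Stochastic fixtures require an explicit
  seed (the CLI refuses to invent one), seeds never leak into the global
  RNG stream, and every scan writes a JSON config snapshot from which the
  run regenerates bit-identically.

## Known limitations

* Linear response is a first-order model: large perturbations, unfolding
  intermediates and anharmonic effects are outside its validity.
* Predictions are positional only — the method proposes *where* a rescue
  mutation may act, never *which* amino-acid substitution.
* The Cα elastic network ignores side-chain identity; two mutations at
  the same position are indistinguishable.
* Inter-molecular rescue (through binding partners, DNA, oligomer
  interfaces) is invisible to a single-chain network; the method targets
  intra-molecular, backbone-mediated compensation.
* Pocket analysis consumes externally computed pocket memberships (e.g.
  an fpocket export); no pocket detection is performed here.
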