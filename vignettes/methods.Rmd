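---
title: "Decomposition-guided multi-objective swarm refinement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposition-guided multi-objective swarm refinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmrefine)
```

## The problem

Protein structure refinement starts from a predicted model that is close to,
but measurably different from, the (hidden) native structure, and asks for a
conformation of higher quality. A single energy function rarely ranks the
native above all near-native decoys for every protein, so `swarmrefine`
treats refinement as a *multi-objective* minimization: several energies are
minimized simultaneously, and the outcome is a Pareto set of trade-off
conformations rather than one "best" structure. Decomposition then turns the
multi-objective search into a population of scalar subproblems — one per
weight vector on the objective simplex — each optimized by a particle of a
swarm, so that diversity across the Pareto front is built into the search
rather than recovered from it afterwards.

## Conformation model

The optimization variable is the backbone torsion representation
$C = [\phi_1, \psi_1, \omega_1, \dots, \phi_L, \psi_L]$ of an $L$-residue
chain. Angles live in degrees on the half-open interval $(-180, 180]$;
$\phi_1$, $\psi_L$ and $\omega_L$ are undefined by convention and stored as
`NA`, never as zero. Cartesian coordinates are regenerated from torsions by
sequential placement of each backbone atom in the frame of the previous
three (bond length + bond angle + torsion, the standard internal-coordinate
chain construction), with fixed Engh–Huber-style covalent geometry:
N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, and bond angles
N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°. The first three atoms fix the
canonical frame (N1 at the origin, CA1 on +x, C1 in the xy-plane), so
conversion is deterministic; all quality metrics are superposition-based and
therefore indifferent to this choice.

Two modelling decisions deserve emphasis:

* **ω is frozen during search.** Sampling perturbs and optimizes φ/ψ only;
  the peptide-bond dihedral stays at its input value (normally near trans,
  180°). Freely moving ω invites unphysical cis flips that no energy term
  here would veto. Both `perturb_chain()` and `torsion_space()` accept an
  `include_omega` flag for users who want the full variable set.
* **Input geometry is idealized.** Reading a PDB measures its torsions
  exactly, but regenerating Cartesian coordinates uses the ideal covalent
  geometry above. The resulting one-off RMSD drift versus the input is
  reported at startup when it exceeds 0.01 Å.

## Objectives

Real refinement pipelines score with physics-based and knowledge-based force
fields. Those backends are deliberately out of scope here; the engine is
exercised with three built-in surrogate energies that conflict the way real
energy functions do, plus an adapter contract (`external_scorer_model()`)
showing how a shell-out scorer would plug in:

* `clash_energy()` — soft-sphere repulsion $\sum \max(0, r_{\min} - d)^2$
  over non-bonded backbone atom pairs (bond separation ≥ 4). Default
  $r_{\min} = 3.1$ Å: measured on regular secondary structure, an ideal
  helix keeps non-bonded backbone distances above ≈ 3.2 Å while copies
  perturbed by 10° drop below ≈ 3.0 Å, so the term separates well-formed
  from distorted chains.
* `compactness_energy()` — squared radius of gyration of the CA trace.
  Rewards collapse, and is therefore in genuine tension with clash and with
  regular secondary structure; this keeps the surrogate Pareto front
  non-degenerate.
* `torsion_preference_energy()` — quadratic circular distance of each
  residue's (φ, ψ) from a basin, default the α-helical (−57, −47), scaled by
  a width of 5°. The width sets this term's magnitude so that no single raw
  energy monopolizes the scalarized distances below.

Objective scales matter because the decomposition operates on raw energies
(see below). The defaults were calibrated once, against two stated
conditions: a regular synthetic native must beat a 10°-perturbed copy of
itself on at least two of the three surrogates (it wins clash and torsion
preference; compactness prefers the perturbed coil), and the three terms
must have comparable magnitudes on typical fixtures. Users substituting
their own energies should check the same two properties.

For optimizer validation independent of protein geometry,
`benchmark_problem()` provides three-objective landscapes over $[0,1]^n$
with closed-form Pareto fronts: `"dtlz2"` (front = unit-sphere octant,
$\lVert F \rVert = 1$) and `"convex-plane"` (front = plane
$f_1 + f_2 + f_3 = 1$), the latter built like DTLZ1 but with a unimodal
distance term $g = \sum_{i>2} (x_i - 0.5)^2$ so convergence failures are
attributable to the optimizer, not to multimodality.

## Decomposition and scalarization

Weight vectors come from the canonical simplex lattice: all $M$-vectors with
components in $\{0, 1/H, \dots, 1\}$ summing to 1, giving
$\binom{H+M-1}{M-1}$ subproblems — 66 for the default $H = 10$, $M = 3$.
Zero components are kept (PBI, unlike the Tchebycheff scalarization, is well
defined with them), and the lexicographic generation order makes subproblem
indices reproducible. Each subproblem $i$ owns the neighborhood $B(i)$: the
$T$ weight vectors closest to $\lambda_i$ in Euclidean distance, self
included, ties broken toward lower indices. $T = 8$ by default.

A conformation with objective vector $F$ is scored for subproblem $i$ by
penalty-based boundary intersection:

$$ g^{pbi}(F \mid \lambda_i, z^*) = d_1 + \theta d_2, \qquad
   d_1 = \frac{\lVert (F - z^*)^T \lambda_i \rVert}{\lVert \lambda_i \rVert}, \qquad
   d_2 = \Big\lVert F - \big(z^* + d_1 \tfrac{\lambda_i}{\lVert \lambda_i \rVert}\big) \Big\rVert $$

where $z^*$ is the ideal point (running component-wise minimum of all
observed objective vectors). $d_1$ drives convergence along the subproblem's
ray; $d_2$ is the direction error; $\theta$ trades them off and is ramped
linearly over the run from 5 to 20 (an adaptive penalty schedule:
convergence first, directional diversity later). The distances act on raw
energy scales by default, exactly as the aggregation is defined; an optional
min–max normalization by the running ideal/nadir estimates is available
(`normalize_objectives`, also an argument `nadir` of `pbi_aggregate()`) but
off by default, and recorded here because raw scales can let one energy
dominate the utility of every subproblem when magnitudes are wildly
mismatched.

## The swarm

One particle per subproblem. Velocities are per-angle deltas; positions are
torsion vectors (or benchmark vectors). Each generation, in fixed ascending
particle order:

1. velocity update
   $v \leftarrow w v + c_1 r_1 (pbest - x) + c_2 r_2 (gbest - x)$ with
   differences taken as shortest signed angular differences, then clamped
   component-wise;
2. position update $x \leftarrow \mathrm{wrap}(x + v)$;
3. objective evaluation, ideal-point update;
4. personal-best update under $g^{pbi}(\cdot \mid \lambda_i)$, strict
   improvement only;
5. neighborhood-best update of every $j \in B(i)$ under
   $g^{pbi}(\cdot \mid \lambda_j)$, applied immediately (synchronous within
   the generation);
6. the new conformation is offered to the Pareto archive.

The inertia weight decreases linearly from 1.3 to 0.7 over the run and the
learning coefficients are $c_1 = c_2 = 2$. Note these coefficients put the
swarm in the oscillatory PSO regime (for $w \le 1$ convergence of the
deterministic recurrence requires $c_1 + c_2 < 2(1+w)$); the velocity clamp,
not the dynamics, bounds the motion, and improvement accumulates through the
best-keeping and the archive rather than through the particles settling.
This is a property of the prescribed coefficients worth knowing when
choosing iteration budgets: progress is roughly linear in generations, not
geometric.

Numerical and reproducibility choices:

* $r_1, r_2$ are drawn once per particle per generation and shared across
  angles; `per_angle_r = TRUE` switches to per-angle draws.
* The velocity clamp defaults to 60°/generation on torsion spaces (the
  plain update rule has no clamp; unbounded torsion velocities blow up
  immediately at these coefficients). It is configurable, including to
  infinity.
* Personal/neighborhood bests store raw objective vectors and are
  re-scalarized at comparison time with the *current* ideal point and
  penalty, so ideal-point drift never leaves a stored aggregate stale.
* One master seed drives the whole run through R's RNG with a fixed
  evaluation order, making runs reproducible bit for bit; `perturb_chain()`
  and the ranking stage take their own seeds. (A counter-based splitting
  scheme would allow out-of-order evaluation, but sequential draws from one
  seeded stream give identical reproducibility for this synchronous loop
  with far less machinery.)
* Initialization: particle 1 is the unperturbed input model; particles
  2..N perturb φ/ψ with Gaussian noise (σ = 10° by default — the
  perturbation magnitude for populating the initial swarm is not dictated
  by the method, so it is exposed as `perturb_sigma`); initial velocities
  are uniform in ± the clamp; bests start at each particle's own position.

## Pareto archive

The archive maintains the non-dominated set of every conformation ever
evaluated: an offered candidate removes the members it dominates and joins
unless dominated; exact duplicates of an existing objective vector are
rejected (first occurrence kept), which bounds duplicate growth without
touching the dominance semantics. The scan is a naive $O(n)$ pass per offer
— the documented complexity contract, adequate at desk scale. The archive is
unbounded by default; an optional capacity prunes by crowding distance.

## Model selection

After the run, every archive member is scored by expected utility under
random objective weights: $U_{C,w} = w^T F(C)$ averaged over $S$ weight
vectors sampled uniformly on the simplex (flat Dirichlet — the sampling
distribution is a package choice, as "random weights" admits several
readings), $S = 20{,}000$ by default. The same $S$ samples are reused for
every member (common random numbers), which makes the ranking noise cancel:
if $a$ dominates $b$ then $a$'s expected utility is strictly smaller in the
same sample set, exactly, not just in expectation. Members are ranked
ascending; ties break toward the earlier generation of discovery, then the
lower archive index; the top $k$ (default 5) are emitted as
`Model_1..k.pdb`. The quantity is a plain expected utility; the related
marginal/knee formulations subtract a counterfactual term and would change
only the tie structure on the front, not the dominance consistency.

## Quality metrics

`kabsch_rmsd()` is the RMSD after least-squares rigid superposition (Kabsch
via SVD, reflection-corrected), positional residue pairing. `gdt_ts()` is
the mean over 1/2/4/8 Å cutoffs of the maximal percentage of CA atoms
superposable within the cutoff. The maximization is approximate by
construction: superposition seeds from all contiguous windows of lengths 4,
8 and the full chain, each refined by up to 3 rounds of re-fitting on the
atoms currently within the largest cutoff. This tracks the official
exhaustive search closely at desk scale but is not it; scores are not
comparable to published assessment tables at decimal precision, which is one
reason benchmark-scale numbers are outside this package's scope.

## Synthetic refinement cases

`make_native()` builds reference backbones from ideal secondary-structure
torsions — helix (−57, −47), extended (180, 180), or alternating 8-residue
mixed blocks — plus a 2° deterministic jitter so fixtures are not exactly at
the surrogate basin. `make_refinement_case()` derives the "initial model" by
perturbing the native's φ/ψ with Gaussian noise of chosen σ and writes both
PDBs with a JSON manifest of the initial RMSD/GDT-TS. What this emulates is
the *geometry* of a refinement exercise: a known answer at a controlled
torsion-space distance. What it does not emulate: real prediction error
structure (errors concentrated in loops and termini rather than i.i.d.
across residues), side chains, sequence diversity, or real energy
landscapes. Tests passing on these fixtures therefore demonstrate that the
optimizer, archive and selection machinery work as specified — not that the
surrogate energies would refine real CASP targets.

## Scales used in the checks

The test suite and the acceptance script run the engine at desk scale,
chosen as the package's own verification sizes: the benchmark convergence
check uses the production lattice (66 particles, T = 8) for 300 generations
on the 7-variable convex-plane problem; the refinement-recovery check uses
L = 30 helical cases at σ = 10° over 5 seeds with 200 generations and
succeeds when the archive's best member beats the initial model's GDT-TS in
at least 3 of 5 — at these coefficients (see above) 100 generations is too
few for reliable movement, while 200 sits well inside a desk-scale compute
envelope. Production-scale defaults remain MaxIt = 3000 and S = 20,000.

## Known limitations

* Surrogate energies are deliberately simple; their Pareto front is a
  caricature (three-way tension between collapse, sterics and local
  regularity), and conclusions about real force-field fronts do not follow.
* GDT-TS is heuristic (above); RMSD pairing is positional, so the metrics
  module assumes equal-length, same-sequence comparisons.
* Single chain, backbone only, no cis-proline handling, no side chains.
* The archive's linear-scan offer is O(archive size) per evaluation; runs
  that accumulate very large fronts (cheap objectives, many generations)
  pay a quadratic total cost.
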