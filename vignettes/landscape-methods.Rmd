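---
title: "Methods: landscape exploration, network analysis and RNA descriptors in pelkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape exploration, network analysis and RNA descriptors in pelkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pelkit)
```

# Scope and model

`pelkit` treats a molecular system as a `potential_model`: a smooth energy
function V(x) in kcal/mol over a configuration vector in Ångström, with an
optional analytic gradient and Hessian, a count of rigid-body zero modes, and
a validity test for degenerate geometries. The landscape of such a model is
summarised by its stationary points — local minima and first-order saddles
(transition states, exactly one negative Hessian eigenvalue after the zero
modes are projected out) — organised into a kinetic transition network (KTN):
a graph whose nodes are minima and whose edges are transition states.

Everything downstream (superbasin analysis, funnels, barriers, convergence
checks, re-ranking) consumes only the KTN, so the machinery is agnostic to
where the energies come from. All-atom force fields with implicit-solvent
terms enter through `external_adapter()`, which wraps energy/gradient
callbacks behind the same contract; nothing in the toolkit reimplements a
Generalised Born model.

# The coarse-grained RNA chain

The shipped chain model uses three beads per nucleotide — phosphate (P),
sugar (S), and a base bead classed purine (R) or pyrimidine (Y) — with the
functional form shared by classical force fields: harmonic bonds and angles,
sinusoidal torsions, a Lennard-Jones term, and electrostatics. Torsions run
over every connected four-bead path in the bond graph, classed by bead-type
pattern (PSPS, SPSP, BSPS, SPSB). Nonbonded terms exclude 1-2 and 1-3
neighbours. Electrostatics are Debye–Hückel screened Coulomb,
k·q₁q₂·e^(−r/λ)/r, an implicit-solvent surrogate with the screening length λ
as an explicit, perturbable parameter.

Parameter choices, made once when the model was designed:

* **Phosphate charge −0.5 e** rather than the formal −1: a crude account of
  counterion condensation. With formal charges and λ = 10 Å the backbone
  repulsion (~12 kcal/mol per P–P pair at 10 Å) overwhelms every attractive
  term and the chain never leaves the extended state at desk-scale sampling.
* **Screening length λ = 3 Å** (high effective ionic strength), for the same
  reason. The re-ranking analysis perturbs λ by ±10%, mimicking a change of
  implicit-solvent model at fixed force field.
* **Purine–pyrimidine pairing well 3.0 kcal/mol** (cross-class LJ ε,
  overriding the Lorentz–Berthelot combination): the stand-in for base-pair
  hydrogen bonding. Same-class contacts keep the weak combined ε ≈ 0.3.
* **Angle stiffness 5 kcal/mol/rad², bond stiffness 20 kcal/mol/Å²**, with
  equilibria (P–S 4.0 Å, S–B 3.5 Å, S–P 3.8 Å; angles 95–110°) in the range
  typical of three-bead nucleic-acid models.

Two parameter sets ship. `cgA` is the reference (threefold backbone
torsions, twofold glycosidic-like terms, amplitudes 0.8–1.5 kcal/mol); `cgB`
keeps every bead, bond, angle and nonbonded parameter identical but changes
the torsion terms (periodicities 1–3, phase shifts, amplitudes up to 2.5).
This mirrors how RNA force-field variants genuinely differ mostly in their
dihedral parameterisations, and it is what makes `cgB` re-rank minima that
`cgA` considers close in energy.

**Native state.** The chain has no experimental fold, so "native" is defined
structurally, as in Gō-type models: `set_native_from_reference()` adopts the
base–base contact map (base beads within 6.5 Å, sequence separation ≥ 3) of
a reference configuration — by convention the global minimum of the
reference parameter set. The order parameter for seeding and for the
partially-folded analysis is the fraction of those native contacts formed.

# Sampling: basin-hopping and local minimisation

`local_minimise()` runs L-BFGS to near convergence and, when the projected
gradient RMS is still above tolerance, polishes with Newton steps on the
zero-mode-shifted Hessian. The database-grade tolerance of 10⁻⁶ kcal/mol/Å
is deliberately three orders of magnitude tighter than the deduplication
energy tolerance (10⁻⁴ kcal/mol), so convergence noise can never split one
minimum into two records.

`basin_hop()` perturbs every coordinate uniformly within ±step, quenches,
and applies a Metropolis test on the quenched minimum energies. The step
size adapts every 50 steps toward 50% acceptance. Every successful quench —
accepted or not — enters the census. For clusters, an optional container
radius about the centroid discards quenches that evaporated into dissociated
fragments, standard practice that keeps the census on bound structures; the
LJ₇ study conditions use 2.5 σ. Deduplication is by energy *and* structural
distance: Kabsch-aligned RMSD for distinguishable beads, and a
permutation/rotation-invariant metric — the RMS difference between sorted
interatomic-distance multisets — for identical-bead clusters. The latter
replaces a Hungarian assignment pass: for deduplication only same-structure
recognition matters (the metric is exactly zero for any permuted rigid
copy), while distinct isomers are already separated by the energy tolerance;
an assignment step without a rotation search would give neither guarantee.

# Transition states

`dneb()` relaxes a band of images (default 11, spring constant
10 kcal/mol/Å²) between two minima under the nudged projection of the true
gradient plus the spring gradient; the doubly nudged variant retains the
component of the perpendicular spring gradient orthogonal to the
perpendicular true gradient, which suppresses corner-cutting. Interpolation
is straight Cartesian with a deterministic clash-repair pass (offending bead
pairs pushed apart along their separation vector until the minimum distance
exceeds half the model's length scale); an image that cannot be repaired is
an error naming the image. Interior images that are local energy maxima
along the band are candidates.

`hybrid_ef_refine()` alternates an uphill step along the lowest eigenvector
of the projected Hessian (a Newton step −(g·v)/λ when the curvature is
already negative, a fixed-length push otherwise) with Newton minimisation in
the orthogonal subspace, trust-capped at 0.2 Å, until the projected gradient
RMS is below 10⁻⁶. Convergence to a point with zero negative eigenvalues is
a *rejected candidate* signal; more than one is a *higher-order saddle*
signal. Eigenpairs come from dense symmetric eigendecomposition, adequate
for the shipped models' dimensions (≤ a few hundred).

`descend_from_ts()` displaces ±0.05 Å along the negative eigenvector
(doubled on failure, up to four times) and relaxes each side. A short damped
steepest-descent prelude precedes the quasi-Newton quench: L-BFGS alone can
hop out of the saddle's own basins on surfaces with very steep walls, which
would corrupt the connectivity.

# The network and its analysis

The KTN has reference semantics (an environment), matching how
stationary-point databases are grown incrementally. `connect_minima()` is
the discrete-path-sampling driver: Dijkstra on a graph where TS edges cost
zero and missing edges cost aligned RMSD² (inflated fourfold per failed
attempt, abandoned after three), bridging the gaps on the current best path
with band searches until the endpoints are linked by true transition-state
edges or the cycle budget is spent; the unconnected outcome is an explicit
flag, not an error. Degenerate rearrangements (a TS whose two descents reach
the same minimum) are stored but ignored by path queries.

Superbasin analysis discretises energy into levels E_ref + kΔE (ΔE defaults
to 1 kcal/mol; E_ref to the global minimum). At each level, union-find joins
minima connected by any TS at or below the level; inclusion is non-strict
(≤), so the discrete merge level L of two minima brackets their continuous
minimax barrier b as b ≤ L < b + ΔE. `minimax_barrier()` computes b exactly
with a widest-path Dijkstra (relaxing the running maximum TS energy);
`barrier(x, x)` is defined as the minimum's own energy. A funnel is a
subtree whose lowest member lies at least `min_depth` below the level where
the subtree merges with any lower-energy subtree; `min_depth` is a required
analysis choice (5ΔE is the documented heuristic default), because what
counts as a distinct funnel is inherently a resolution decision. The
disconnectivity drawing orders children deterministically (subtree size,
then lowest energy, then smallest member id), which avoids crossings; a
shared `e_min`/`e_max` puts several landscapes on one scale.

The convergence report tracks, per snapshot, the funnel count at fixed ΔE,
the global-minimum energy, the minimax barrier matrix between funnel
bottoms, and the harmonic-superposition occupation of the lowest funnel at a
reference temperature (vibrational prefactors treated as equal — a
heuristic, stated as such); "converged" means every metric is stable to 1%
over the last two snapshots.

# RNA descriptors

`read_pdb_models()` wraps the bio3d reader (first altloc kept, one structure
per MODEL) behind a light line validator so malformed ATOM records are
reported with their line numbers. Sugar pucker is the Altona–Sundaralingam
pseudorotation phase computed from the five ring torsions,
P = atan2((ν₄+ν₁)−(ν₃+ν₀), 2ν₂(sin 36° + sin 72°)), amplitude ν₂/cos P;
phases in [0°, 36°) are C3′-endo (A-form-like). Base pairs require close
ring centres (≤ 6.5 Å), near-parallel planes (≤ 35°), near-coplanarity
(vertical offset ≤ 2 Å — this is what separates pairing from stacking), and
at least one polar N/O–N/O contact within 3.5 Å, counted by greedy
one-to-one matching so each atom hydrogen-bonds at most once. Edges
(Watson–Crick, Hoogsteen, Sugar) are assigned by which rim atoms
participate; the full Leontis–Westhof taxonomy with cis/trans annotation is
out of scope. G·U wobble counts toward the canonical tally by default
(toggleable). Stacking requires centres ≤ 4.5 Å, planes ≤ 30°, and in-plane
offset ≤ 2.5 Å. All cutoffs live in `geometry_cutoffs()` and were fixed
against the idealised fixtures, not against any experimental structure.

Dot-bracket strings include canonical and wobble pairs; conflicting claims
on a residue keep the pair with more polar contacts. Crossing pairs
(pseudoknots) go to successive bracket tiers `()[]{}<>` by greedy page
assignment; more than four tiers is an explicit overflow error. Ensemble
profiles average angular fields with circular statistics (undefined terminal
dihedrals are excluded, never imputed as zero) and report the dominant
dot-bracket string with its frequency.

The fixture geometries (`ideal_base`, `ideal_pair`, `ideal_stem`,
`nmr_like_ensemble`) are synthetic: regular-polygon rings with radially
placed substituents, pairs assembled by optimising an in-plane rigid
placement to put designated donor–acceptor pairs at 2.9 Å, stems stacked at
3.4 Å rise / 32.7° twist, and a 21-residue pseudoknot-shaped chain with
stems 1–4/13–10 and 6–8/21–19 jittered over 14 models. They are internally
consistent test objects, not crystallographic averages — passing descriptor
tests on them shows the geometry machinery is correct, not that the cutoffs
are optimal for experimental structures.

# Re-ranking analysis

`sample_minima()` draws a seeded, optionally energy-stratified sample;
`rescore()` evaluates the stored geometries under a second model
(single-point by default, so the comparison is on identical configurations;
re-minimised as an option). `rank_correlation()` reports tie-corrected
Kendall τ-b by explicit pair counting — exact ±1 for identical/reversed
orderings — with Spearman ρ from the stats library and the discordant pairs
retained. The shipped contrast: perturbing the screening length by 10%
(solvent-model analogue) leaves the ordering essentially intact (τ ≥ 0.9 on
the fixture network), while swapping `cgA` → `cgB` torsions reorders minima,
with discordant pairs concentrated among partially folded structures.

# Problem sizes, determinism, limitations

The study conditions exercised by the tests and the acceptance script:
Müller–Brown with 500 basin-hopping steps; LJ₇ with 2000 steps × 5 seeds
(census frozen against a long multi-seed oracle run: −16.50538, −15.93504,
−15.59321, −15.53306); 200 random networks of ≤ 20 minima for the barrier
oracle; a 10-nucleotide chain (GGGAAAACCC) with 120 basin-hopping steps for
the re-ranking network. Every stochastic routine takes an explicit RNG seed
and restores the global RNG state; seeded explorations are byte-reproducible
including their on-disk KTN file sets (energies serialised with 17
significant digits, the shortest representation that round-trips doubles).

Known limitations: the chain model is a caricature — no sequence-specific
pairing geometry, no explicit hydrogen-bond directionality, no ions; the
funnel definition is resolution-dependent by design; dense Hessians limit
saddle refinement to moderate dimensions; harmonic-superposition occupations
ignore vibrational prefactors; and the descriptor cutoffs, while standard in
magnitude, were validated on idealised geometry only.
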