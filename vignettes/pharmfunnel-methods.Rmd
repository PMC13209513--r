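---
title: "Methods: pharmacophore screening, pose triage and trajectory analysis with pharmfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore screening, pose triage and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmfunnel)
```

## Scope

`pharmfunnel` re-implements, as an open toolkit, the *decision layers* of an
integrated virtual-screening funnel for phosphodiesterase-1 (PDE1)
inhibitors: 3D pharmacophore perception, consensus model construction,
tolerance-sphere matching, screening validation metrics, geometric triage of
docked poses, trajectory stability and hydrogen-bond occupancy analysis, and
binding-energy-window enrichment. What it deliberately does **not** do:
conformer generation, docking and scoring, force-field MD, quantum charge
fitting, or MM-PB(GB)SA energy evaluation. Binding energies and inhibition
rates enter as *data* (CSV); structures enter as SDF V2000 and PDB.

## The pharmacophore model and its matching semantics

A pharmacophore model is an ordered set of *tolerance spheres*: each feature
has a kind (`AROMATIC_RING`, `HBA`, `HBD`, `HYDROPHOBIC`, `LINKER`), a 3D
center (Å) and a radius. The packaged refined PDE1 model has seven features:
two aromatic ring centers and an aromatic/hydrophobic ring center at 1.0 Å
radius, two hydrogen-bond acceptors and a linking atom at 0.7 Å, and a
hydrophobic center at 1.0 Å. The kinds and radii follow the published refined
model; the **centers are synthetic** (the original coordinates were never
published) and were laid out once on a plausible fused-ring inhibitor frame —
hence the asset name `pde1_model_synthetic.json`. `build_consensus_model()`
is the reproducible surrogate for the manual model-building step: feature
points of like kind across pre-superposed ligands are single-linkage
clustered (default cut 1.5 Å), clusters supported by all ligands become
features at the cluster centroid with a common initial radius (default
1.0 Å, the published starting value).

### Feature perception

Perception is deterministic and rule-based, per conformer:

* **Aromatic rings**: smallest rings (shortest cycle through each ring bond,
  size ≤ 8); a ring is aromatic when all its bonds carry SDF order 4, when an
  even ring alternates single/double orders (Kekulé), or — only for
  molecules whose bonds were perceived from distances, e.g. a PDB HETATM
  ligand — when a 5/6-ring of C/N is planar within 0.15 Å. The point is the
  ring centroid.
* **HBA**: N or O with an available lone pair. Pyrrole-type nitrogens
  (aromatic N with three substituents, lone pair in the ring) are excluded.
  Formal charges are not parsed from SDF, so the "not positively charged"
  exclusion is vacuous here; charged species are out of scope of the
  fixtures and tests.
* **HBD**: N or O carrying at least one hydrogen, explicit or implied by
  standard valences (N:3, O:2); explicit hydrogens override the valence
  guess.
* **HYDROPHOBIC**: centroid of each all-carbon(/halogen) ring, and of
  terminal branched alkyl groups (an sp3 carbon with ≥ 2 terminal carbon
  neighbours, group size ≥ 3).
* **LINKER**: a non-ring heavy atom directly bonded to two distinct ring
  systems (diphenylmethane's CH2 qualifies; biphenyl has none). This
  operationalises the published model's "linking atom", which was never
  defined chemically; the rule is a package convention.

A point can carry several kinds (a benzene centroid is both
`AROMATIC_RING` and `HYDROPHOBIC`). In consensus construction, co-located
clusters of different kinds arising from the same source points are merged
into one feature (priority `AROMATIC_RING` > `HBA` > `HBD` > `HYDROPHOBIC` >
`LINKER`); without the merge, N identical copies of a ligand would produce
two co-located features that the ligand itself could not match injectively.

### Matching

A conformer matches iff an injective, kind-compatible assignment of its
feature points to *all* model features exists such that some rigid transform
places every assigned point inside its feature's sphere (`LINKER` features
accept any single-atom point). Candidate assignments are enumerated as
size-K cliques of a correspondence graph — nodes are kind-compatible
(point, feature) pairs; two nodes are connected when they involve distinct
points and features and their point–point and feature–feature distances
agree within the sum of the two radii — and each clique is verified by
superposition.

Verification is the one place where a numerical design choice matters. The
unweighted Kabsch fit minimises the *sum* of squared residuals; with
heterogeneous radii it can park one point just outside its sphere although a
containment-feasible transform exists. Since tolerance-sphere matching is a
containment question, verification first tries the plain Kabsch optimum and,
if a point violates its radius, runs a tolerance-weighted Kabsch iteration
(weights escalate on the largest residual/radius ratios, up to 60 rounds)
searching for a feasible transform. With this, synthetic actives whose
points are planted anywhere within 0.9 × radius of the centers are always
recovered. The reported `fit_rmsd` is the unweighted RMSD at the accepted
transform; the best verified assignment over all conformers (smallest
`fit_rmsd`, ties broken lexicographically) is returned, which makes the
matcher deterministic and — as the property tests assert — invariant to
rigid motion of the molecule to 1e-6.

### Refinement

`refine_model()` performs one coordinate-descent sweep over the features in
order; for each feature, the candidate radius (grid 0.5/0.7/1.0/1.2 Å plus
the incumbent) maximising the Goodness-of-Hit score on a labelled test set
is kept, exact ties going to the smaller, stricter radius. Keeping the
incumbent among the candidates guarantees the refined model's GH never drops
below the input model's. Inside the sweep, two degenerate GH cases are
defined pragmatically: zero hits scores 0, and an empty decoy set sets the
false-positive factor to 1.

## Validation metrics

For a test set of `D` compounds with `A` actives, of which screening
retrieves `Ht` hits containing `Ha` actives:

* enrichment factor `EF = (Ha/Ht) × (D/A)`,
* Goodness-of-Hit `GH = (Ha/A) × [(3A + Ht)/(4Ht)] × [1 − (Ht − Ha)/(D − A)]`,
* `TPR = Ha/A`, `FPR = (Ht − Ha)/(D − A)`.

On the published test-set counts (D = 2020, A = 20, Ht = 42, Ha = 17) these
give 40.88, 0.51, 0.85 and 0.0125 (0.01 at two decimals) — the package's
acceptance script recomputes exactly this. A GH above 0.5 is conventionally
read as acceptable model quality.

## Pose triage geometry

All criteria are configuration with crystallographic-convention defaults,
since the original study left them to a commercial package and visual
inspection:

* hydrogen bond: donor–acceptor heavy-atom distance ≤ 3.5 Å and, when an
  explicit hydrogen is present, D–H···A angle ≥ 120°; without hydrogens the
  heavy-atom criterion stands. Protein donor/acceptor capability is assigned
  by residue and atom name; ligand capability follows the perception rules.
  Water-mediated bonds are detected only as two chained direct bonds through
  explicit water atoms.
* π–π stacking: face-to-face when the interplanar angle ≤ 30°, centroid
  distance ≤ 5.5 Å and lateral offset ≤ 2.0 Å; edge-to-face when the angle
  exceeds 60° at centroid distance ≤ 6.0 Å. Protein rings come from
  Phe/Tyr/His/Trp ring-atom name sets; the ligand contributes every
  perceived aromatic ring.
* pocket contact: any ligand heavy atom within 4.0 Å of a *side-chain* heavy
  atom of a listed residue (backbone N/CA/C/O/OXT excluded — "entering the
  pocket" refers to side-chain-lined space). Named sets: Q2 =
  {Leu388, Phe392, Leu409, Val417}, H-loop = {His267, Thr271}. Residue
  numbering follows the crystal structure used for docking and is treated as
  configuration, not truth, across PDE1 isoforms.
* steric clash: protein–ligand heavy-atom pairs closer than 2.0 Å. The
  original study's "obvious steric hindrance" was a human call; it is
  operationalised here as a zero-clash requirement, logged and overridable.

Round 1 passes iff (H-bond to Gln421 **or** His373) **and** a ring stack
with Phe424 **and** zero clashes; round 2 prefers round-1 poses that also
engage the Q2 pocket or the H-loop. The decision is a pure function of the
detector outputs and is invariant under a joint rigid transform of protein
plus ligand.

## Trajectory analyses

`backbone_rmsd()` superposes each frame onto the reference (default frame 1)
on the backbone atoms (N, CA, C, O) before measuring; `is_stable()` applies
a *strict* threshold (default 2.5 Å: a maximum of 2.49 is stable, 2.50 is
not). `hbond_occupancy()` evaluates a single protein-residue contact per
frame and reports the fraction of in-window frames where it exists, plus
mean and sd of the best D–H···A angle over present frames; the default
window is the first 20 ns, the convention under which the published
occupancies were read. Occupancy is per-frame counting, hence invariant to
frame reordering and duplication. Multi-MODEL PDB input gets frame times
from a configurable spacing (default 0.01 ns/frame; the original write
frequency was never stated). A window-slicing utility supports conventions
like snapshot extraction over the final nanoseconds of a run; the energy
computation itself stays out of scope.

## Screening statistics on measured records

Screening records carry a compound id, predicted binding free energy
(mean ± sd, kcal/mol) and percent inhibition per assay concentration (µM).
"n.d." entries are preserved as missing, never as zero, and are excluded
from both numerator and denominator of the affected concentration.
`activity_filter()` uses a *strict* threshold ("beyond 50%" read as > 50;
the packaged table's 50.7/54.0 values are insensitive to the boundary
choice). `energy_window_enrichment()` partitions records into right-open
windows `(-∞,−40), [−40,−30), [−30,−20), [−20,∞)` — the convention under
which every printed record lands in the window the published analysis
assigns it (no printed mean equals a boundary) — and reports percent actives
rounded half away from zero, which is what makes 3/8 print as 38. The
packaged 26-compound table reproduces: 11 hits above 50% at 10 µM (hit rate
42%), two compounds above 50% at 1 µM, window enrichments 53% / 38% and 0%
in both extreme windows, and the most favorable predicted energy
(−43.20 kcal/mol) ranked first. `selectivity_class()` encodes the 10 µM
on-target / 50 µM off-target rule with its fivefold concentration ratio;
`significant_residues()` selects decomposition rows strictly below
−1.0 kcal/mol in at least one complex.

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated data; identical (specification, seed) pairs give
identical outputs, with per-generator substreams derived from one seed.

* `make_screen_deck()` plants actives whose perceived feature points sit
  uniformly within `jitter_frac` × radius of each model center (assembled
  from real chemical fragments — benzene rings, carbonyl acceptors, amine
  donors, aliphatic rings, tert-butyl groups, bridging carbons — then
  rigidly moved at random), and decoys carrying the same feature-kind
  inventory strung out with pairwise distances beyond any model distance
  plus twice the radii, so no distance-compatible assignment exists. Default
  composition 20 actives / 2000 decoys mirrors the published test set;
  default jitter 0.5 is a moderate perturbation well inside the tolerance
  spheres. The deck emulates *geometry*, not chemistry: decoys are not
  property-matched, and no conformational strain exists.
* `make_complex()` builds a toy scaffold of the PDE1 hotspot residues
  (correct atom names, locally sensible geometry, residues spread ~16 Å
  apart so planted contacts stay local) and assembles a ligand satisfying a
  declared contact plan exactly: planned distances and angles are realised
  analytically and recovered by the detectors to numerical precision at zero
  noise. It is not a folded protein; only local geometry is meaningful.
* `make_trajectory()` replicates a complex over frames, displaces a
  contact's ligand fragment 8 Å outward wherever the schedule marks it
  absent, and adds isotropic Gaussian noise (`noise_sigma` is the per-atom
  RMS displacement; each coordinate gets sd `noise_sigma/√3`, so the
  expected backbone RMSD between two noisy frames is ≈ `noise_sigma·√2`).
  Occupancies computed downstream equal the schedule fractions exactly for
  sub-threshold noise.

Passing these tests therefore shows the *decision layers* are correct on
geometry they fully control; it does not show anything about conformer
coverage, docking accuracy or force-field quality on real systems, which
are upstream of this package.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes chosen as representative:
matcher-vs-brute-force equivalence on 200 random instances with ≤ 8 feature
points and 3–5 features; deck recovery at 20 actives with 20–30 decoys at
jitter 0.5 and 0.8; refinement monotonicity on 5-active/8-decoy sets;
trajectory properties on 5–51 frames. Tie-breaks are deterministic
throughout (smaller radius in refinement; smallest fit RMSD then
lexicographic assignment in matching; lexicographic id on equal energies in
ranking). Containment tolerances use a 1e-9 slack; rigid-invariance
assertions use 1e-6. Degenerate inputs error early with named messages:
empty RMSD series, zero-active refinement sets, windows outside the
trajectory time range, residues absent from a structure, malformed SDF
counts lines (with line number), ragged multi-MODEL PDB files, and
insertion codes (unsupported by the residue-identity convention
chain/number/name).

## Known limitations

Formal charges, protonation states and tautomers are not modelled; aromatic
perception trusts reader flags or Kekulé patterns (plus planarity only for
distance-perceived ligands), so exotic heteroaromatics may be missed;
H-bond capability tables cover the standard residues only; the LINKER rule
is a convention, not a published definition; partial (fewer-than-all
features) pharmacophore matches are deliberately unsupported; and the
funnel's library-scale throughput targets correctness, not speed — the
matcher is exhaustive over cliques rather than heuristic.
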