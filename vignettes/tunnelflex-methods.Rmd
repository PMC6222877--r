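---
title: "Side-chain flexibility of protein tunnels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-chain flexibility of protein tunnels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunnelflex)
```

## The problem

Tunnels and channels are the pathways by which ligands reach buried active
sites or cross a protein. A static crystal structure gives one tunnel
shape, but side chains rotate: a residue lining the tunnel can swing into
the lumen and close it, or swing away and widen it. `tunnelflex` answers
two questions for a given structure and a given tunnel:

1. Which combinations of side-chain rotamer choices around the tunnel are
   *simultaneously* possible, i.e. free of steric collisions? (All of
   them, enumerated exactly — not sampled, not energy-ranked.)
2. Over all those conformations, how large can the bottleneck of the
   deformed tunnel get — what is the largest spherical ligand that could
   ever pass?

## The sphere model

Every heavy atom is a sphere at its PDB coordinates with a van der Waals
radius taken from a swappable table (bundled Bondi-style values: C 1.70,
N 1.55, O 1.52, S 1.80 Å). Hydrogens are ignored: their volume is small
against the heavy-atom spheres. Two non-bonded atoms *collide* when

$$ (x_1 - x_2)^2 + (y_1 - y_2)^2 + (z_1 - z_2)^2 < (r_1 + r_2)^2 , $$

a strict inequality: tangency is contact, not collision. All collision
tests subtract a tolerance of $10^{-9}\,\text{Å}^2$ from the right-hand
side so floating-point noise at exact tangency cannot flip an outcome.

Each residue splits into an invariant main chain (N, Cα, C, O) and a side
chain. The line through the Cα and Cβ centers is the rotation axis. The
model makes one deliberate simplification: *the whole side chain rotates
rigidly about that single axis*, in steps of 30° by default, giving 12
rotamers per rotatable residue with rotamer 0 equal to the input pose.
The finer picture — three staggered positions on each of up to four
torsion axes, $3^4 = 81$ conformations for a long side chain — is
deliberately not enumerated; the single-axis sweep is the approximation
that keeps the candidate space at $12^n$ instead. Glycine (no Cβ),
alanine (Cβ lies on the axis, so rotation is the identity) and proline
(ring closed onto the backbone) are treated as non-rotatable: one
"rotamer", the input pose.

A caveat that follows from the naming rule rather than chemistry: a
terminal carboxylate OXT is not one of the four main-chain names and
therefore travels with the side chain. For tunnel-adjacent terminal
residues this slightly overstates flexibility.

## Bounding sphere volumes

For each residue we build one sphere — the BSV — containing its main
chain and *every* rotamer: each side-chain atom contributes the sphere
swept around the axis (center at the orthogonal projection of the atom
center onto the axis, radius = distance-to-axis + atom radius), and the
swept spheres are merged with the main-chain spheres by a deterministic
Ritter-style pass (seed ball on two mutually farthest surface points, one
growth sweep, then a short farthest-point polish that keeps the best
center seen). The result always contains its inputs exactly — the final
radius is the exact maximum reach from the chosen center — but it is
near-minimal, not minimal; exact minimality buys nothing here, because a
slightly oversized BSV only sends a few extra residue pairs to the exact
rotamer-level scan. One consequence worth knowing: because the
construction is a heuristic, adding a sphere to the input can in rare
cases shrink the output by a fraction of a percent; the test suite
asserts no-shrink only up to 1% of the radius.

Non-overlap of two BSVs certifies that *no* rotamer pair between the two
residues can collide, which is what makes the broad-phase filter lossless.

## The pipeline

1. **Tunnel-adjacent set S.** The tunnel is a swept ball: ordered samples
   $(t, \mathbf{c}(t), r(t))$ with $t$ strictly increasing in $[0,1]$. A
   residue joins S when its BSV has a non-empty intersection with at
   least one sample ball (touching counts — this is set intersection, not
   collision). Because the BSV spans all rotamers, S covers both residues
   contacting the tunnel now and residues that could reach it after
   rotating.
2. **Pruning.** A rotamer is invalid if it collides with any main-chain
   atom of any residue (Case 1) or with anything outside S — other
   residues' atoms or non-water hetero groups such as heme or metals
   (Case 2). Waters are dropped at parse time; hetero handling is a flag
   because structures differ in whether such groups should block. The
   check of a rotamer against *its own* main chain is optional
   (`self_main_chain`, default on) and exempts exactly the
   **pose-invariant pairs**: pairs in which either atom lies on the
   rotation axis (Cβ, and Cα against every side-chain atom). Their
   distances do not change under the rotation, so they are properties of
   the input structure — which the model takes as valid — and would veto
   either all rotamers or none. The exemption also covers the covalently
   forced near-contacts (Cβ–Cα, Cβ–N, Cβ–C, γ-atom–Cα) that tetrahedral
   geometry produces in every side chain. Pose-dependent contacts (γ and
   beyond against N, C, O) remain checked; with full Bondi radii and a
   strict inequality this is a deliberately conservative reading, and on
   real structures it prunes gauche-like poses that molecular mechanics
   would merely penalize. A residue whose rotamers *all* die is an error,
   not a silent drop: the static environment already contradicts the
   model's premise that the input pose is valid.
3. **Graphs and cliques.** A temporary graph TG joins residues of S whose
   BSVs collide; for TG edges only, all rotamer pairs are scanned at atom
   level, giving the collision graph CG ⊆ TG. Maximal cliques of CG
   (Bron–Kerbosch with pivoting; pivot = candidate with most neighbours,
   ties by sorted order) are the *amino-collision cliques*: conflicts
   cannot cross clique boundaries, which is the divide step. A residue
   may sit in several cliques; consistency is restored when combining.
4. **Local conformations.** Per clique, the collision-free graph FG holds
   every surviving rotamer as a vertex and an edge for every
   collision-free inter-residue pair. Maximal cliques of FG whose size
   equals the residue count of the clique assign exactly one rotamer per
   residue — the local valid conformations. Smaller maximal cliques are
   rejected: some residue has no compatible choice.
5. **Combination.** Local conformations are length-$n$ vectors with $-1$
   for unconstrained positions. A depth-first recursion over cliques
   (largest first, a pure performance ordering) merges vectors, pruning a
   branch the moment two assignments disagree. The compatibility test is
   "both entries ≥ 0 and different": index 0 is a real assignment, not a
   sentinel. Overlapping cliques can reach the same full assignment along
   different branches, so the final set is deduplicated and sorted;
   memory scales with the number of local conformations, not their
   product. A `max_conformations` guard aborts pathological cases with a
   clear error.

A brute-force enumerator over the full product of surviving rotamers,
with a direct all-pairs collision filter and a candidate bound of
$10^6$, exists purely as a verification oracle; the test suite asserts
set equality between the two routes on randomized systems.

## Deformed tunnels and bottlenecks

A bottleneck is a sample whose radius is a *discrete strict local
minimum*: both neighbours one sample step away are strictly larger (ε is
one sample step; no interpolation — inputs are discrete sphere
sequences). A plateau of equal minimal radii flanked by larger ones
counts once, at its first sample; endpoints never qualify. The minimum
bottleneck limits the ligand; when a profile is monotone and has no
interior minimum, the narrowest sample still limits passage, so the
global minimum is the fallback.

For each global conformation the tunnel is recomputed with the
**centerline held fixed**: every sample radius becomes the clearance to
the nearest obstacle sphere (static atoms plus the chosen rotamers),
clamped to $[0, r_{cap}]$ with $r_{cap}$ = twice the original maximum
radius. Zero means the tunnel is completely blocked at that point. The
cap keeps profiles comparable where the centerline exits the protein.
This recomputation deliberately replaces a full tunnel-detection program:
it is deterministic and self-contained, and it preserves bottleneck
semantics *along the given path* — but it cannot relocate the tunnel, so
conformations that would reroute the entrance are reported as narrowed or
blocked rather than rerouted. The step sits behind `recompute_tunnel()`
so a real tunnel finder can be plugged in.

The report over all conformations gives the per-conformation minimum
bottlenecks, their maximum (the maximum passable ligand radius, with the
achieving conformation, lowest id on ties), and a min/mean/max summary.
Internally the clearance splits into a static part and a per-rotamer
part, each computed once per sample; the tests assert this fused path
equals a literal per-conformation recomputation loop.

## Synthetic data

The package generates its own test systems; no structure download is
needed.

* `worked_example_graph()` pins a three-residue, three-rotamer
  collision-free graph with two invalid rotamers and three planted
  collisions — the counts it must reproduce (6 size-3 cliques, 1 size-2
  clique, 6 local conformations) are fixed by construction.
* `worked_example_geometry()` realizes the same relations with concrete
  spheres (radius 0.5 Å, 120° step): tips of the three arms move on
  circles in one plane, one center obtained by a rotation-center
  construction so that two planted collision sites sit exactly 120°
  apart; two floating backbone fragments prune exactly one rotamer each.
  The constructor re-derives the collision matrix and aborts if the
  planted relations are not realized, so the fixture cannot silently
  drift.
* `random_toy()` builds seeded pseudo-residues around a curved tunnel:
  four backbone spheres laid out tangentially to the tube, a genuine
  Cα–Cβ axis, and an arm that bends well off the axis so rotamers sweep
  wide circles. Arm spheres are fluorine-sized (1.47 Å): with full carbon
  radii the forced γ-backbone contact of such a compact pseudo-residue
  would leave almost no admissible pose at coarse rotamer steps. The
  `packing` knob targets the fraction of residue pairs with overlapping
  BSVs by bisecting a global centerline scale (ties prefer the roomier
  layout); residues share a base azimuth so neighbouring arms genuinely
  interlock. Tunnel radii are clamped below the identity-pose clearance,
  making the initial tunnel collision-free by construction — which is
  what licenses the invariant that the identity conformation never
  narrows it. Draws that leave a residue with no valid rotamer are
  retried deterministically; persistent failure (for example requesting a
  mid-range packing fraction from two residues, whose only possible
  fractions are 0 and 1) raises an "infeasible packing" error.

What the toys do **not** emulate: real main-chain connectivity between
consecutive residues, realistic side-chain chemistry or rotamer-library
statistics, backbone flexibility, crystallographic artifacts. Passing
tests on toys therefore demonstrates the *algorithm* — selection,
pruning, clique decomposition, exact enumeration, bottleneck analysis —
not biological realism of any particular prediction.

## Numerical and design choices

* Collision tolerance $10^{-9}\,\text{Å}^2$ on squared distances; strict
  inequality everywhere; tunnel adjacency is inclusive (tangency joins S).
* Determinism throughout: residues ordered by chain/number/insertion,
  vertices and cliques sorted, Bron–Kerbosch pivot ties broken by order,
  global conformations sorted lexicographically, toys seeded.
* Altloc resolution keeps the highest occupancy (ties → "A"); one model
  per parse.
* Coordinates stay in the PDB frame, Å, no re-centering.
* Test problem sizes: the oracle-equivalence suite runs twenty seeded
  toys with 2–5 residues, 1–3 arm atoms and rotamer steps of 30–120°,
  and the bottleneck-definition check runs 1000 random radius profiles of
  length 3–50. These sizes keep brute-force oracles exact and the whole
  suite comfortable on one CPU.

## Known limitations

* Single rigid axis per side chain: χ2+ torsions are folded into the 30°
  sweep rather than enumerated.
* Fixed backbone, fixed tunnel centerline: entrance relocation cannot be
  observed.
* Full-radius strict spheres are conservative for 1-4 contacts; the
  `self_main_chain` flag exists because reasonable readings differ on
  checking a rotamer against its own backbone.
* The enclosing-sphere construction is near-minimal, not minimal (see
  above).
* Counts are reported for *distinct* assignments; overlapping cliques
  that reach the same assignment twice are deduplicated.
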