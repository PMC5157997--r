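---
title: "Growing conducting airway trees by space subdivision: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing conducting airway trees by space subdivision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtree)
```

## The model

The conducting part of the bronchial tree — trachea to terminal
bronchioles (TBs) — is modelled as a binary tree of straight tubes grown
inside confining lobar volumes. The governing idea is self-similar volume
division: a branch that must supply a region of lung splits that region in
two, sends one child toward the centre of volume of each half, and
recurses. Because each child inherits exactly the seeds of its half, the
terminal sub-space volumes tile the lobe exactly and can be read as model
acini.

The confining space enters as a voxel label mask (`LobeMask`). The voxels
of each lobe are decimated to a seed grid (`SeedSet`): every seed stands
for an equal share of the lobe volume, so centroids of seed subsets are
centres of volume and counting seeds measures volume exactly. The default
decimation of 64 voxels per seed (with 1 mm³ voxels) keeps several seeds
per prospective acinus — the stopping criterion needs sub-acinar volume
resolution — while staying cheap; 32–64 voxels per seed behaves
equivalently, and a lobe always keeps at least one seed.

Expansion starts from the unflagged leafs of a segmented (or synthetic
stub) central tree. Each leaf must have a sibling, because the splitting
plane through the sub-space centre of volume takes its normal from the
cross product of the leaf direction and the sibling direction: successive
bifurcation planes are thereby forced toward mutual orthogonality, which
is what produces planar rotation angles distributed around 90° without any
explicit rotation rule.

## Expansion rules and their parameters

All thresholds live in `GrowthConfig`; each is configurable, and the
defaults are the study conditions the package is validated under.

| parameter | default | units | role |
|---|---|---|---|
| `lengthFraction` | 0.4 | — | child length as a fraction of the parent-end-to-centroid distance |
| `lRatioMax` | 1.5 | — | cap on L_child / L_parent |
| `ldRatio` | 3 | — | diameter rule D = L / 3 |
| `dRatioMax` | 0.95 | — | cap on D_child / D_parent |
| `thetaMax` | 75 | degrees | branching-angle cap |
| `lTB` | 1.4 | mm | TB length threshold |
| `vAcThreshold` | 233.75 | mm³ | TB sub-space (acinar) volume threshold |
| `reassignIterations` | 1 | — | per-bifurcation seed re-assignment cycles |
| `terminalRule` | "or" | — | combination of the two TB criteria |

The 40% length fraction stops children short of their centroids so that
deeper subdivisions retain room; reported TB lengths span roughly
0.65–2 mm, motivating the 1.4 mm threshold. Diameters are deliberately
*not* assigned by a fixed parent–child ratio: the length rule D = L/3
(the anatomical rule of thumb L/D = 3 ± 1) lets the asymmetry of the
sub-spaces drive diameter asymmetry, and the homothety ratio near
2^(−1/3) ≈ 0.794 then *emerges* from volume halving rather than being
imposed. The 0.95 diameter cap and 1.5 length cap keep pathological
sub-space shapes from producing children larger than their parents; the
75° cap removes the unnaturally large branching angles that irregular
sub-space shapes occasionally produce. The acinar threshold 233.75 mm³ is
25% above the mean cast-measured acinar volume of 187 mm³, reflecting
lung volumes between FRC and TLC.

## Order of operations and numerical choices

Per bifurcation the implementation applies, in order: splitting plane →
seed partition → centroids → child proposal (40%) → `reassignIterations`
cycles of nearest-skeleton re-assignment with re-proposal → length clamp
(shortening the child along its own direction, so it still points at its
centroid) → diameter from the *final* length → angle check, with an
in-plane rotation to exactly 75° when exceeded, followed by a single
nearest-skeleton re-partition of the bifurcation's seeds (no further
iterations, and no re-check of the length/diameter caps — rotation
preserves length).

Degenerate cases are resolved deterministically:

* **Collinear parent and sibling** (splitting-plane normal undefined): fall
  back to the plane perpendicular to the parent–grandparent plane, then to
  a plane containing the parent direction chosen from the least-aligned
  coordinate axis.
* **Seeds exactly on the plane** go to the positive side.
* **Nearest-skeleton ties** go to the lower-id child.
* **A plane that fails to divide** (all seeds one side), a centroid
  coinciding with the parent end-point, or a child that loses every seed
  during re-assignment all flag the affected branch as a terminal
  candidate rather than forcing a split.
* Angles are compared in degrees with 1e−6 absolute tolerance; direction
  vectors are renormalized after every rotation; the recursion aborts with
  a diagnostic beyond `maxDepth` (default 60) generated generations.

Growth contains no randomness whatsoever: identical inputs give
bit-identical trees, which the suite asserts.

Two readings of the stopping test are defensible — length and volume
criteria each individually sufficient ("or"), or jointly required
("and"). The package defaults to "or": under "and" a branch wedged in a
small but elongated sub-space could grow indefinitely, and the known
artifact of occasional over-sized acini terminated by the length rule only
arises under "or". Both modes are exposed (`terminalRule`).

Whether the 40% fraction is re-applied to the updated centroid after each
re-assignment iteration was also open; it is (each cycle re-proposes the
child toward the new centroid), matching the iteration's purpose of
letting skeletons track their actual supplied regions.

## The synthetic fixtures

`syntheticLung()` provides confining spaces without any medical images:
1–5 axis-aligned ellipsoidal lobes with human lobar volume shares
(20/10/25/20/25%), mildly jittered semi-axis ratios, and one stub entry
per lobe at the superior-medial surface pointing into the lobe with a
seed-controlled tilt. The stub supplies what a segmented central tree
would: an unflagged leaf with a parent and a 45° sibling so the first
splitting plane is defined. The seed feeds only this fixture jitter, via a
private linear-congruential stream so the global RNG is untouched.

What the fixtures emulate is the *geometry class* the algorithm assumes —
closed, convex-ish confining volumes with realistic linear dimensions and
entry orientation. What they do not emulate: real lobe shapes (fissure
concavities, mediastinal moulding), multi-generation segmented central
trees with their measured diameters and Boyden labels, or inter-subject
variability. Statistics that depend mostly on the subdivision rules (HR,
L/D, θ, φ, RB, TB dimensions, acinar volumes) transfer well from
ellipsoids to real lobes; statistics dominated by the central airways
(low-generation diameter/length tables, per-lobe AGR differences) do not,
and passing tests on fixtures say nothing about them.

## Problem sizes

The validation suite grows one ~1.0 L lobe (10⁶ voxels of 1 mm³, 64
voxels/seed → 15,626 seeds) with the default configuration, yielding
roughly 10,500 branches and 5,300 terminals in a few seconds; unit tests
use 0.05–0.2 L lobes. One lobe of this size is the natural analysis unit:
statistics are per-branch means over ~10⁴ branches, so a whole-lung run
(5 lobes) changes the reported means by far less than the inter-subject
spread they are compared against.

```{r example}
fix <- syntheticLung(2e5, 1, c(1, 1, 1), seed = 1)
seeds <- seedsFromMask(fix$mask, 1L, 64L)
tree <- growTree(fix$tree, assignSeedsToSubtrees(fix$tree, seeds))
s <- summarizeTree(tree)
c(LD = s$ld[["mean"]], HR = s$hr[["mean"]], RB_S = s$ratios$strahler$RB$ratio)
```

## Known limitations

* Seed sub-space volumes are multiples of `volumePerSeed` (64 mm³ at the
  defaults), so terminal "acinar" volumes are quantized; distributions
  smooth out only at finer seed grids.
* The volume already occupied by proximal airways is not subtracted from
  the confining space, which biases seeds near the lobe entry and thereby
  slightly inflates local branching angles.
* Terminations by the length rule can strand over-threshold sub-volumes
  (the large-acinus tail); `summarizeTree()` reports how many terminals
  arose this way (`terminalsByLengthRule`).
* Branches are straight tubes: no carina geometry, curvature, or lumen
  surface — downstream CFD needs its own meshing.
* Trifurcations are accepted in segmented input (ordering rules generalize)
  but never generated.
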