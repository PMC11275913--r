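---
title: "Surface morphometrics of membrane-associated ribosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface morphometrics of membrane-associated ribosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosurf)
library(ggplot2)
```

## The problem

Most mitochondrial proteins are made by cytoplasmic ribosomes and imported
afterwards, but a subset is imported co-translationally: the ribosome docks on
the outer mitochondrial membrane (OMM) with its peptide exit tunnel facing the
membrane so the nascent chain threads straight into the import machinery. In
cellular cryo-electron tomography such events appear as ribosome particles
(positions plus Euler-angle orientations from subtomogram refinement) hovering
over triangle-mesh reconstructions of the OMM and the inner membrane (IMM).
`ribosurf` turns those two ingredients into quantitative statements: which
ribosomes are oriented for import, whether they cluster, whether they form
polysome-like chains, and whether the membranes beneath them look different.

All positions and distances in the API are Angstrom; clustering radii follow
the field convention and are quoted in nanometres.

## Distances, orientations and the two particle classes

A particle's orientation comes from its `(rot, tilt, psi)` Euler triplet.
The package uses the intrinsic ZYZ convention,
`R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`, the common reading of the
`rlnAngle*` columns; because refinement packages disagree about the
active/passive reading, every consumer accepts `invert = TRUE` and the
convention is covered by a round-trip test rather than assumed silently.

Distances to the membrane are *nearest-triangle-centroid* distances computed
with a k-d tree, matching the procedure used by membrane-morphometrics
pipelines (`mode = "exact_surface"` is available where the true
point-to-surface minimum matters; it is never larger than the centroid
distance, which overestimates by at most about one edge length).

Each particle gets:

* `d_center` — distance from its centre to the nearest OMM triangle centroid;
* `d_exit` — the same for the *peptide-exit point*, the particle centre
  shifted by a fixed particle-frame offset (`frame_offset()`), because the
  exit tunnel, not the centre, is what must reach the membrane;
* three relative angles `acos(|v_i . n|)` between the particle axes and the
  local surface normal, folded into [0°, 90°] so neither vector's sign
  matters.

Classification then uses two thresholds (defaults in `classifier_config()`):

* **import-oriented**: `d_exit <= 95` Å. The boundary is inclusive — the
  two natural readings ("threshold of 95 Å" vs "closer than 95 Å") differ
  only at the boundary, and the inclusive choice is documented and tested.
* **near-unoriented**: `d_center <= 250` Å and *not* import-oriented, so the
  classes are disjoint by construction. Everything else is `other`.

The angles are reported but never filtered on: the selection rule is the
exit-distance threshold alone.

The exit-tunnel offset itself is a required input for real data (it is
derived upstream by masking a consensus map). `default_offsets()` provides
synthetic defaults — exit tunnel 120 Å along −z, mRNA 5′-exit/3′-entry ports
±105 Å along x — chosen so that a particle hovering 150 Å above the membrane
with its exit axis anti-parallel to the normal has `d_exit ≈ 30` Å, and two
chain neighbours spaced 250 Å have a 40 Å port gap.

## Clustering: Ripley's K ratio on the membrane

For each particle class we compute `K_obs(r) = (2/n) × #{pairs within r}`
over a 1 nm radius grid spanning 27–166 nm, and divide by `K_csr(r)`, the
same statistic averaged over `n_null` placements of equally many points
uniformly *by area* on the same membrane mesh. Because numerator and
denominator are computed at identical n on the identical domain, intensity
and edge-correction factors cancel: under complete spatial randomness the
ratio is 1, and no separate edge correction is needed. This self-consistent
estimator is a deliberate design choice — only the ratio is used downstream,
and its CSR anchor of 1 is what the interpretation rests on. A volumetric
null is not provided: the particles of interest live on the membrane, so the
membrane is the reference domain.

Per-tomogram curves are summarised as maxima over half-open 10 nm intervals
`[a, a+10)`. Intervals are anchored at multiples of the width (20–30, 30–40,
…) rather than at the grid origin, so the conventional 30–40 nm interval
exists even though the grid starts at 27 nm. Groups of per-tomogram maxima
are compared with the two-sided Mann–Whitney U test (`mann_whitney()`, exact
for small tie-free samples, tie-corrected normal approximation otherwise).

## Membrane patches, cristae junctions and intermembrane distance

A *patch* is the set of mesh triangles whose centroids lie within 150 Å
(Euclidean, not geodesic — the patch radius is far below the membrane's
curvature radius, so the difference is negligible and the k-d-tree search
stays simple) of a seed triangle. Seeds are the nearest OMM triangles of a
particle class; patch labels are unions, so overlapping footprints are
counted once.

Cristae junctions are detected operationally, not by curvature: IMM
triangles whose OMM distance falls in the 180–300 Å band (away from
junctions the OMM–IMM spacing sits near 135 Å, and inside a crista body the
IMM is much farther). Manual cleanup of stray band triangles is replaced by
an optional exclusion mask. Band triangles are projected to their nearest
OMM triangles, and the projection is expanded by 150 Å (half a cristae-body
width) to give the *crista-associated OMM*.

`overlap_fraction(mesh, a, b)` is the area of triangles carrying both labels
over the area of `a` — undefined (NA, never 0) when `a` has zero area.
`patch_imm_distances()` records, for every OMM triangle, the distance to the
nearest IMM centroid, split by patch membership; per-tomogram distributions
are summarised by the peak of a 100-bin histogram spanning that tomogram's
[min, max] (the bin count is convention; the range is per tomogram because
no global range is defined — ties break to the lower bin). Matched-count
randomized patches (`randomize_patches()`, seed triangles uniform over
triangles with pairwise separation > 150 Å, area-weighted sampling
available) provide the null for both the overlap and the distance
comparisons. `proximity_region()` generalises the same machinery to
inter-organelle contacts, e.g. OMM triangles within 250 Å of an ER mesh.

## Polysome chains

Putative polysomes are detected among import-oriented particles from port
geometry: a directed edge `i -> j` exists when centres are within 300 Å
(30 nm) and the 5′ exit of `i` is within `adj_max` of the 3′ entry of `j`.
"Directly adjacent" was a visual judgement in the source workflow; here it
is an explicit threshold, default 60 Å (about three 20 Å marker-sphere
radii), configurable and reported. Edges are accepted in order of increasing
port gap with in/out-degree at most 1 and no cycles — so degree conflicts
resolve to the closest ports and any would-be cycle is broken at its largest
gap, deterministically. Chains are the resulting maximal paths, 5′-most
member first.

Two metrics are emitted per chain because an "end-to-end" measurement admits
either reading: `end_to_end`, the straight line between the terminal ports,
and `path_length`, the full mRNA polyline (inter-member rods plus the
within-member traverse of interior members). The polyline definition keeps
`path_length >= end_to_end` unconditionally; when consecutive ports coincide
the within-member terms vanish and the polyline reduces to the sum of rods.

## The synthetic scene generator

Real tomograms for this problem are not available at desk scale, so the
generator is a first-class module that produces the study conditions with
known ground truth:

* **Membranes** — an icosphere-based ellipsoid OMM (default semi-axes
  2000 Å, matching a yeast mitochondrion's ~0.4 µm girth; edge target
  100 Å) and an IMM offset 135 Å inside along the normal — the
  inner-boundary-membrane spacing reported for regions away from import
  sites (130–140 Å).
* **Cristae** — smooth cosine-cap invaginations (default depth 600 Å, neck
  radius 300 Å) whose necks sweep the 180–300 Å detection band, one annular
  band component per crista. "Junction" is the thresholded band, exactly as
  the detector defines it, not a curvature feature.
* **Constrictions** — IMM vertices displaced toward the OMM with a Gaussian
  falloff (`amplitude`, `radius`), so a 35 Å amplitude turns a 135 Å gap
  into a 100 Å local minimum; amplitude and radius are directly recoverable,
  which is what the recovery tests exploit.
* **Particles** — surface sites (uniform by area, Thomas-clustered with
  truncated-Gaussian offspring displacement so every offspring provably lies
  within the stated spread of its parent, or caller-pinned sites), centres
  lifted 150 Å along the normal. Import-oriented particles get the exit axis
  anti-parallel to the normal; all others get it flipped outward, which
  makes ground truth unambiguous. The import fraction is assigned
  deterministically (first ⌊f·n⌋ particles) before a seeded shuffle, so
  integer fractions are exact. Polysome chains walk along the surface with
  each successor pinned so the port gap is exact.

What the generator does **not** emulate: tomographic noise, the missing
wedge, segmentation errors, curvature-dependent junction geometry, or any
biological truth about the ribosome point process (the Thomas process is a
stand-in for "clustered", not a claim). Passing recovery tests therefore
demonstrates correctness of the measurement machinery under controlled
geometry, not robustness to real-data artefacts.

## Numerical choices and degenerate inputs

* Nearest-neighbour queries use a compiled 3-D k-d tree with a
  smallest-index tie-break; exhaustive scans are kept as independent test
  oracles.
* Zero-area faces are dropped (with a count) on mesh read — screened-Poisson
  reconstructions routinely carry slivers — but are an error when
  constructing a mesh directly.
* `histogram_peak` of a constant vector returns that constant; empty inputs
  are errors, as are empty groups in `mann_whitney` (whose all-ties
  degenerate case returns p = 1).
* Randomized-patch placement is rejection sampling with a budget; failure
  names the achieved count instead of looping forever.
* Every stochastic routine takes an explicit seed and restores the session
  RNG state; the pipeline derives per-tomogram seeds from the global one, so
  a rerun is bit-identical.

## Problem sizes

The shipped tests and the acceptance script run on meshes of roughly
5,000–80,000 triangles and point sets of 100–500 particles: large enough
that the kd-tree, area-weighted sampling and the CSR null behave as they do
at production scale, small enough that the whole suite completes in a few
minutes on one core. The CSR anchor uses the full target geometry (2000 Å
sphere, ~50 Å edges, 500 particles, 20 null replicates).

## A worked example

```{r example, fig.width = 6, fig.height = 4}
scene <- generate_scene(scene_config(mesh_edge = 150, n_cristae = 2, seed = 1))
placed <- place_particles(
  scene$omm,
  placement_config(n_particles = 60, frac_import_oriented = 0.5,
                   cluster_process = "thomas", n_parents = 6,
                   offspring_spread = 150, seed = 2)
)
particles <- placed$particles |>
  annotate_particles(scene$omm) |>
  classify_particles()
table(particles$class_label)

imp <- dplyr::filter(particles, class_label == "import_oriented")
curve <- k_ratio_curve(imp, scene$omm, k_config(n_null = 10, seed = 3))
glance(curve)
autoplot(curve)
```

## Known limitations

* Centroid-mode distances inherit the mesh resolution; thresholds tuned for
  one edge length shift slightly at another.
* The K ratio is a per-tomogram statistic; tomograms holding several
  mitochondria are treated as one domain.
* Chain detection assumes the configured port offsets; wrong offsets degrade
  silently into "no chains found".
* The `.gt` triangle-graph format of the upstream morphometrics tooling is
  not read; per-triangle labels travel as PLY face properties or CSV
  sidecars instead.
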