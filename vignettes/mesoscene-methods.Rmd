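---
title: "Models and methods behind mesoscene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesoscene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoscene)
```

`mesoscene` re-creates, offline and at desk scale, the computational
core of an instanced mesoscale-model viewer. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices, and what the test suite does and does
not demonstrate.

## The instanced scene model

A mesoscale model of a virus or organelle contains thousands of copies
of a few hundred distinct macromolecules. `mesoscene` exploits that
redundancy the way GPU viewers do: an `Entity` stores one canonical set
of spheres (centers in Å, strictly positive radii), and an `Instance`
is a rigid placement — a unit quaternion plus a translation. The full
geometry is never materialized; `world_spheres()` applies
`R p + t` on demand, and rigid transforms being isometries, pairwise
distances and radii are preserved (tested to 1e-5).

Entities belong to exactly one leaf of a group hierarchy (e.g.
compartment → molecular class). All styling — color, visibility,
opacity, clip opt-out, LOD bias — is per group, never per instance;
this matches how mesoscale viewers expose their UI and keeps styles
orthogonal to geometry (toggling any style leaves `world_spheres()`
untouched, a tested invariant).

Conventions, fixed once and tested everywhere: right-handed world frame
in Å; the camera looks from `position` toward `target`; vertical field
of view in degrees; image origin top-left with rows downward; depth is
the axial view-space distance mapped linearly to [0, 1] with 0 at the
near plane and 1 at or beyond the far plane.

## On-disk representations

**mmCIF.** Standard files carry Biological Assembly Descriptions:
`_pdbx_struct_oper_list` holds rigid operators (orthonormality is
validated to 1e-6 with determinant +1; violations name the operator),
and `_pdbx_struct_assembly_gen` pairs an operator expression with the
chains it applies to. Operator expressions follow the PDB convention:
comma lists, numeric ranges, and products of parenthesized terms where
`"(X)(Y)"` means X·Y — the left term is applied last. Expansion is
tested against brute-force enumeration with explicit 4×4 matrix
products. A small category-level CIF parser backs this (no installed R
package exposes arbitrary mmCIF categories); it handles loops,
key-value items, quoting and multi-line values, and its output has been
cross-checked against gemmi on the package's own fixtures.

**PetWorld dialect.** Many objects in one file, partitioned by
`atom_site.pdbx_PDB_model_num`; `pdbx_model.name` and
`pdbx_model.instances` annotate each model; gen rows carry a
`PDB_model_num`. A declared instance count that disagrees with the
generated count is recorded as a warning in the load report and the
generated count wins; a gen row naming an absent model is an error.

**BinaryCIF.** Categories as msgpack with per-column encoding chains.
Seven encodings are implemented (ByteArray, FixedPoint,
IntervalQuantization, RunLength, Delta, IntegerPacking, StringArray)
together with a matching encoder used by the manifest writer and the
tests; chains are listed in encoding order and decoded in reverse;
anything else fails loudly naming the kind. A minimal msgpack codec is
included because no installed R package provides one.

**Manifest container.** A ZIP archive with `manifest.json` (group
filter, entity records, styles), one BinaryCIF sphere payload per
entity, and one binary transform file per entity. The transform record
layout is 7 little-endian float32 values per instance — quaternion
(x, y, z, w) then translation (Å) — chosen because rotation validity
stays testable by norm (float32 rounding keeps unit quaternions within
1e-6). Everything written is canonical: JSON keys sorted at every
level and serialized at 17 significant digits (the precision at which
IEEE doubles round-trip through decimal), archive entries sorted,
stored (uncompressed) ZIP entries with fixed 1980-01-01 timestamps.
Canonical output is what makes the write→read→write byte-identity test
meaningful. Coordinates are fixed-point encoded at factor 1000 (0.001 Å
resolution), matching the 3-decimal precision of the text dialect.

Fixture mmCIF files carry sphere radii in `B_iso_or_equiv` (mmCIF atoms
have no radius field); loaders use that column when positive and fall
back to an element van-der-Waals table keyed on `type_symbol`.

## Level of detail

Distant structures do not need per-atom spheres; the viewer-scale idea
is to merge adjacent spheres as structures recede.
The merge rule here is a uniform grid with dyadic cell growth: level
ℓ ≥ 1 buckets sphere centers into cells of size `base_cell · 2^ℓ`
(anchored at the world origin, so the result is permutation-invariant),
and each non-empty cell becomes one sphere at the volume-weighted
centroid with the enclosing radius `max_i(|p_i − c| + r_i)`. The
enclosing rule buys a provable invariant — the union of level-ℓ spheres
contains the union of level-0 spheres — which the suite verifies by
sampling 10^4 points on and in the input spheres. Defaults:
`base_cell` = 2 × median input radius, 4 levels.

One consequence found by testing: because enclosing radii can extend
*beyond* the level-0 union, culling bounds must enclose every LOD
level, not just level 0. `instance_bounds()` therefore takes the
maximum over all levels; the bound is still computed once per entity
and is LOD-independent at cull time.

Level selection is `clamp(base + preset_bias + group_bias, 0, max)`
where `base` counts how many normalized-distance thresholds
(default {4, 16, 64} × entity extent) the instance has passed. The four
preset modes are Ultra (bias −1, exact impostors), Quality (0, exact),
Balanced (+1, approximate impostors) and Performance (+2, flat discs at
half resolution). The mode names and which parameters vary per mode
follow the viewer tradition; the numeric values are this package's
defaults and are configurable. Monotonicity in distance and the
Ultra ≤ Quality ≤ Balanced ≤ Performance ordering at any fixed distance
follow from the formula and are tested over a distance grid.

## Culling

Frustum culling tests per-instance bounding spheres against six inward
planes; the sphere test is conservative by construction, and a
brute-force oracle (projecting every sphere of every instance) confirms
no instance with a visible sphere is ever lost.

Occlusion culling must never change a pixel, so occluder depth comes
from real geometry: the K largest-by-screen-area instances (default
64) are rendered exactly as the final frame would render them (same
LOD, same sphere mode, same clips), the depth buffer is reduced to a
max pyramid (each coarser texel the max of its 2×2 children), and any
other instance whose bounding-sphere near face is *strictly* farther
than the pyramid maximum over its whole clamped screen footprint is
dropped. The strict comparison plus the subset property of the prepass
give a short conservativeness argument: every fragment of a culled
instance lies strictly behind what the final buffer already contains,
so it could never have won the depth test. The headline invariant —
`render(cull = on)` bit-identical to `render(cull = off)` for opaque
scenes at every preset — is exercised on randomized packed scenes from
both overview and interior cameras.

## Clipping

Five signed-distance primitives — plane, sphere, cube, cylinder,
infinite cone — are exact in their local frames (the cone uses the
exact 2D profile distance in the radial/axial plane, apex at the local
origin, opening along −z), posed by a rigid transform, optionally
inverted. Clipping keeps the *inside*; a sphere is removed when its
**center** is outside at least one applicable clip. The center-only
test gives crisp whole-sphere cuts with no popping ambiguity; users
wanting surface-accurate cuts can offset the primitive by a mean
radius. Groups with `clip_enabled = FALSE` are never removed — that is
how a genome stays fully visible while the capsid around it is peeled
away — and multiple clips combine as a union of removed regions, which
makes composition monotone and growing-radius sphere clips produce
nested kept sets (the layer-by-layer peel). Signs are verified against
membership oracles on 10^4 points per primitive, magnitudes against
surface sampling, and gradients against central differences.

## Rendering

The renderer is a deterministic CPU rasterizer (compiled via Rcpp,
scalar double arithmetic, no threading): per sphere, a conservative
screen bounding box from the eight view-space AABB corners, then a
per-pixel analytic ray-sphere solve. Ties at equal depth go to the
earlier instance (stable). Three sphere modes: *exact* (true hit depth
and normal), *approximate* (exact silhouette, constant front-face
depth, normal reconstructed from the disc parameterization) and
*flat-disc* (center depth, camera-facing normal) — all three share the
silhouette, which the suite checks directly.

Contact shadows march each covered pixel's view-space position toward
the light in steps whose projection covers about 10% of the image
diagonal (16 steps, bias 0.002 in normalized depth, strength 0.5 by
default); a sample whose depth exceeds the recorded depth at its screen
location means something lies between the pixel and the light.
Head-on light provably shadows nothing (marching toward the camera only
decreases depth), and oblique shadows must fall opposite the light's
screen direction — both tested.

SSAO samples a seeded hemisphere kernel at three radii (2/8/32 × median
sphere radius, 16 samples each, equal weights) and applies a
depth-aware 5×5 bilateral blur (depth sigma 0.01). Two numerical
choices matter on sphere geometry: a minimum kernel elevation
(z ≥ 0.25) and a depth bias of 0.2 × the smallest radius. Both
suppress *curvature self-occlusion* — near-tangent samples on a bumpy
wall of spheres measure the wall's own bumps, not cavities — while
leaving cavity-scale occlusion (many radii deep) intact. The tested
behavior: a flat wall of overlapping spheres keeps mean occlusion below
0.05, a deep slit stays visibly darker than the flat region, and
strength 0 returns exact ones.

Transparency is composited exactly: fragments of groups with opacity
below 1 are collected per pixel, sorted back-to-front and blended with
`alpha_eff = alpha · clamp(n·v, 0, 1)^gamma` (γ defaults to 1), so
spheres fade as their normals turn away from the viewer. A CPU
renderer can afford exact order-independent transparency; endpoint
exactness and monotonicity in n·v are asserted directly.

Determinism is a contract: identical scene + settings + seed give
bit-identical rasters, and three fixture scenes are pinned to golden
digests recorded at first implementation.

## Tours

A snapshot captures everything that determines a frame — camera,
styles, clips, preset, labels, markdown description — under a unique
key, so `render(apply(snapshot))` is bit-identical to the capture-time
render, including after a JSON round trip (canonical serialization,
17-digit doubles). Camera playback interpolates position and target
linearly after smoothstep easing and the orientation by quaternion
slerp on the short arc (antipodal-safe); endpoints are returned
exactly, by construction. Non-camera state snaps at the end of a
transition — only the view is interpolated, deliberately.

Markdown links drive navigation: `[text](#key)` jumps to a snapshot,
`[text](highlight:name)` highlights an entity,
`[text](group:path)` highlights a group; the scheme spellings are this
package's choice (the behaviors are standard, their spelling is not).
Other targets and malformed links pass through untouched. Since there
is no event loop, interactability is exported as data: `play_tour()`
returns an index map from interactable label text to the frame index
of its target snapshot, and validation reports every dangling key.

## The synthetic-scene generator

`make_scene()` emulates the geometric archetypes of mesoscale models:
capsid shells (instances on a Fibonacci sphere, oriented outward),
membrane sheets (a planar tile), packed interiors (dart-throwing with
non-overlapping instance bounds, capped attempts, uniform random
orientations via the subgroup algorithm), lattices, and single
molecules. Entities are random sphere blobs — Gaussian-jittered centers
with uniform radii (defaults: 3 entities, 10 copies, 30 spheres of
1.5–2.5 Å in a 200 Å extent). Every generator draws from one seeded
stream restored afterwards, so fixtures are reproducible and golden
images stable.

What passing tests therefore show — and do not show: the geometric and
visual contracts (expansion, coverage, conservativeness, determinism,
round trips) hold on scenes with the *statistics* of mesoscale models
(many instances, shared entities, dense packing). Blob entities say
nothing about biochemical realism, crowding physics, or real PDB
content, and file-format coverage extends to the constructs the
generators emit plus the standard assembly machinery — not to every
dialect in the wild.

## Problem sizes and other choices

Test and acceptance runs use scenes of tens of instances with tens of
spheres each, rendered at 96–512 px — sizes chosen so the whole suite
documents itself in well under a minute of compute while still
exercising every code path (the rasterizer handles 10^5-sphere scenes
comfortably; nothing in the design caps scene size below the 10^6
spheres the generators allow). Degenerate inputs are defined, not
accidental: empty scenes render pure background at depth 1; entities
must have ≥ 1 sphere and positive radii; cameras reject coincident
position/target, parallel up vectors and inverted clip ranges; an
infeasible packing errors with advice rather than looping forever.

Known limitations: spheres only (no bonds, surfaces or cartoons, by
design); whole-sphere clipping rather than per-fragment cuts; no
global illumination (single directional light + constant ambient); the
PNG path is 8-bit RGB; and the manifest layout, while self-consistent
and fully specified here, does not claim on-disk compatibility with any
deployed web viewer.
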