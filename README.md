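# mesoscene

Integrative mesoscale models — whole virions, bacterial cells,
organelles — describe thousands of macromolecule copies and up to
billions of atoms. Interactive viewers make such models tractable with a
small set of computational ideas: store **one** coordinate set per
molecular entity and place copies with rigid per-instance transforms
(instancing); draw atoms as ray-cast **sphere impostors**; merge
adjacent spheres into enclosing spheres as structures recede from the
camera (**LOD**); skip instances outside the view frustum or provably
hidden behind nearer geometry (**culling**); cut models open with
signed-distance **clipping** primitives scoped to entity groups; and
recover depth cues with screen-space **contact shadows** and
**multiscale SSAO**. `mesoscene` is a desk-scale, fully offline R
implementation of that computational core, plus the authoring layer
around it: snapshot-based guided tours with interpolated camera
playback and markdown-linked navigation.

For structural bioinformaticians and visualization researchers it is a
testable reference: every stage is an ordinary R function with a
deterministic contract, checked against independent oracles.

## What is inside

| Area | Functions |
|---|---|
| Model I/O | `load_mmcif()`, `load_petworld()`, `read_manifest()` / `write_manifest()`, `read_bcif()` / `write_bcif()`, `parse_oper_expression()` |
| Scene graph | `meso_scene()`, `meso_entity()`, `meso_style()`, `validate_scene()`, `world_spheres()`, `assign_colors()` |
| LOD | `build_lod()`, `select_level()`, `quality_preset()` |
| Culling | `make_frustum()`, `frustum_cull()`, `build_depth_pyramid()`, `occlusion_cull()` |
| Clipping | `meso_clip()`, `sdf()`, `clip_mask()` |
| Rendering | `render_scene()`, `render_opaque()`, `contact_shadows()`, `ssao_multiscale()`, `composite()`, `ray_sphere()` |
| Tours | `capture_snapshot()`, `interpolate_camera()`, `parse_markdown_actions()`, `play_tour()`, `write_tour()` / `read_tour()`, `storyboard_html()` |
| Fixtures | `fixture_spec()`, `make_scene()`, `write_fixture_mmcif()`, `uniform_rotation()` |
| CLI | `cmd_info()`, `cmd_render()`, `cmd_tour()`, `cmd_convert()`, `cmd_fixtures()`; dispatcher at `inst/cli/mesoscene.R` |

Supported representations: standard mmCIF with biological assembly
descriptions (`_pdbx_struct_oper_list` operators composed through
`_pdbx_struct_assembly_gen` operator expressions such as
`"(1-12)(13-18)"`), the YASARA PetWorld multi-object mmCIF dialect
(entities split by `atom_site.pdbx_PDB_model_num` with `pdbx_model.*`
names and instance counts), BinaryCIF (msgpack columns through the
ByteArray / FixedPoint / IntervalQuantization / RunLength / Delta /
IntegerPacking / StringArray encodings), and a ZIP manifest container
(`manifest.json` + per-entity BinaryCIF payloads + binary transform
files, 7 little-endian float32 per instance: unit quaternion then
translation in Å).

The model at the renderer's heart is the analytic impostor: for a pixel
ray with unit direction **d** from the camera origin and a sphere
(**c**, r), the hit is the smallest non-negative root of

    t^2 - 2 t (d . c) + |c|^2 - r^2 = 0,

with normal (**p** − **c**)/r at the hit **p**. Shading is Lambertian
with a single directional light, multiplied by a contact-shadow factor
(depth-marched toward the light) and a multiscale SSAO factor
(hemisphere occlusion at several radii, bilaterally blurred).
Transparent groups composite back-to-front with
α_eff = α·clamp(**n**·**v**, 0, 1)^γ, so spheres fade as their normals
turn away from the viewer. See `vignette("mesoscene-methods")` for the
full account.

## Worked example

Generate a synthetic capsid-shell model, inspect it, render it:

```r
library(mesoscene)
cmd_fixtures("capsid-shell", "capsid.zip", seed = 7)
cmd_info("capsid.zip")
cmd_render("capsid.zip", "capsid.png", quality = "quality",
           width = 512, height = 512, seed = 7)
```

which prints

```
scene:     capsid-shell-seed7
entities:  3
instances: 30
unique spheres: 90   drawn spheres: 900
drawn spheres per LOD level: L0=900  L1=580  L2=290  L3=230
bounding box (A): x [-113.5, 114.4]  y [-113.1, 113.3]  z [-113.6, 114.0]
rendered capsid.png (512x512, quality): culled 0 by frustum, 0 by occlusion
```

Read: the model stores only 90 unique spheres (3 entities × 30 each)
but draws 900 (30 placed instances); at coarser LOD levels the drawn
count falls to 230. From the overview camera nothing is culled — zoom
in (or hide a hemisphere behind the nearer one) and the frustum and
occlusion counters grow while the image stays pixel-identical to an
unculled reference render.

The same pipeline from R objects:

```r
sc  <- make_scene(fixture_spec("packed-interior", seed = 7))
img <- render_scene(sc, settings = meso_settings(512, 512, seed = 1),
                    clips = list(meso_clip("plane")))   # cut at z = 0
write_png_image(img, "interior.png")
```

A two-stop guided tour:

```r
s1 <- capture_snapshot(sc, auto_frame(sc), "overview",
                       description = "Start here, then [zoom](#closeup).")
s2 <- capture_snapshot(sc, meso_camera(c(0, 0, 260), c(0, 0, 0)), "closeup")
tour <- meso_tour(list(s1, s2))
res  <- play_tour(tour, sc, frames = 5)    # 5 frames, endpoints exact
```

The shell dispatcher wraps the same functions:

```sh
Rscript inst/cli/mesoscene.R render capsid.zip out.png --quality balanced --seed 7
Rscript inst/cli/mesoscene.R convert capsid.zip capsid.cif
```

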