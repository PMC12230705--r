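# mvsr — declarative molecular scene descriptions in R

Structural biologists routinely need to say *exactly* what a 3D molecular
view shows — which entry, which assembly, which chains, colored and
labelled how, seen from where — in a form that survives email, appears in
a methods section, drives a web viewer, and reproduces identically years
later. Viewer session files and screenshots do not do this; a declarative,
viewer-independent description does.

`mvsr` implements the MolViewSpec open standard for such descriptions as a
self-contained R library plus a small command-line tool. A scene
("state") is a rooted, ordered tree of typed nodes:

```
root ── download(url) ── parse(format) ── structure(mode)
                 ── component(selector) ── representation(type) ── color
     ── camera | focus | primitives(distance, angle, sphere, mesh, …)
```

The package provides, in one place:

* a **fluent builder** that can only produce hierarchy-legal trees
  (`mvs_builder()`, `mvs_download()`, …, `mvs_state()`);
* **validation** of arbitrary (hand-written or deserialized) trees against
  the node-kind hierarchy and per-kind parameter schemas, with issues as
  data (`validate_state()`, `assert_valid()`);
* **MVSJ** (canonical JSON) and **MVSX** (ZIP archive with bundled assets)
  reading and writing, plus **URL-fragment** embedding
  (`write_mvsj()`, `pack_mvsx()`, `encode_url_fragment()`);
* a minimal **mmCIF reader and selector resolver** so focus targets,
  per-component atom counts and measurement endpoints can be computed
  without any external viewer (`read_mmcif_atoms()`,
  `resolve_selector()`, `audit_state_against_structures()`);
* the **geometry** the standard implies: rotation checking, rigid
  transforms, bounding spheres, focus-derived cameras
  (distance = r / sin(fov/2), the sphere-in-cone fit), and
  distance/angle measurements;
* deterministic **synthetic fixtures** and five canned example scenes, so
  everything above is testable offline (`make_mmcif()`,
  `make_example_state()`, `mvs_demo()`).

Multiple states compose into narratives ("snapshots") with timing
metadata via `mvs_snapshots()`. Rendering itself is out of scope: this
package builds and checks descriptions; a viewer interprets them.

## A worked example

```r
library(mvsr)

state <- mvs_builder() |>
  mvs_download("./model.cif") |> mvs_parse("mmcif") |>
  mvs_structure("model") |>
  mvs_component(mvs_selector(expressions = list(list(label_asym_id = "A")))) |>
  mvs_representation("cartoon") |> mvs_color("skyblue") |>
  mvs_state(title = "Chain A, cartoon")
state
#> <mvs_state> version 1.0
#>   title: Chain A, cartoon
#>   nodes: color=1 component=1 download=1 parse=1 representation=1 root=1 structure=1
```

The state references `./model.cif`; generate a synthetic structure,
resolve the same selector against it, and derive a camera from the
selection's bounding sphere:

```r
atoms <- read_mmcif_atoms(make_mmcif(fixture_spec(include_water = TRUE)))
idx <- resolve_selector(atoms, mvs_selector(expressions = list(list(label_asym_id = "A"))))
length(idx)
#> [1] 12                       # 3 residues x 4 backbone atoms

component_sphere(atoms, idx)
#> <mvs_sphere> center (3.738, 1.822, -0.104)  radius 4.563 A

cam <- camera_from_focus(component_sphere(atoms, idx), fov_deg = 45)
cam$position
#> [1]  3.738364  1.821631 11.821898   # center - direction * r/sin(22.5 deg)
```

Serialize canonically, embed in a URL, or pack a fully self-contained
archive (the state plus the structure it references):

```r
txt  <- write_mvsj(state)                       # canonical JSON text
frag <- encode_url_fragment(state)              # "mvs:eJyVVMluwjAQvfMVkX..."
arc  <- pack_mvsx(state, assets = list("./model.cif" = make_mmcif(fixture_spec())))
unpack_mvsx(arc)$audit
#>            url     member resolved
#> 1  ./model.cif  model.cif     TRUE
```

Round trips are exact: `tree_equal(read_mvsj(write_mvsj(s))$root, s$root)`
holds for every builder-produced state, and equal trees always serialize
to identical bytes.

## Command line

```sh
MVS=$(Rscript -e 'cat(system.file("cli", "mvs", package = "mvsr"))')
Rscript $MVS demo measurements -o demo.mvsx
Rscript $MVS validate demo.mvsx            # exit 0 clean, 1 issues, 2 usage/I-O
Rscript $MVS describe demo.mvsx
Rscript $MVS unpack demo.mvsx -d out/
Rscript $MVS encode-url out/index.mvsj
```

`validate --json` emits one JSON object per issue (path, severity, code,
message) for machine consumption; `--lenient` downgrades unknown-parameter
errors to warnings.

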