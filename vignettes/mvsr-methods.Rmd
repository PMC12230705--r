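---
title: "Declarative molecular scenes with mvsr: model, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative molecular scenes with mvsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvsr)
```

## The model: scenes as trees

A molecular visualization is described here as *data*, not as viewer
commands: a **state** is a rooted, ordered tree of typed nodes, each node
carrying a kind (one of `r length(node_kinds())` closed vocabulary members,
see `node_kinds()`), a parameter map, and ordered children. The path from
the root to a leaf reads like a data-flow pipeline:

```
root -> download(url) -> parse(format) -> structure(mode)
     -> component(selector) -> representation(type) -> color(...)
```

Sibling order is semantically significant — a later color node may paint
over an earlier one in a renderer — so tree equality (`tree_equal()`) is
order-sensitive for children and list-valued parameters, order-insensitive
for map keys, and exact (no tolerance) for floating-point parameters.
An ordered sequence of states plus timing metadata (`mvs_snapshots()`)
forms a visual narrative; each snapshot carries `linger_duration_ms` and
`transition_duration_ms`.

Nothing in this package renders anything. Interpretation (drawing,
focusing a camera, dereferencing URLs) is a viewer's job; this library
builds, checks, serializes and audits the description. Network URLs are
never dereferenced by the library itself.

## The hierarchy table

The standard's prose does not print a parent/child table, so this
implementation fixes one and treats it as normative
(`hierarchy_table()`):

| parent                | permitted children                          |
|-----------------------|---------------------------------------------|
| root                  | download, camera, canvas, primitives, focus |
| download              | parse                                       |
| parse                 | structure, volume                           |
| structure             | component, transform, primitives            |
| component             | representation, label, tooltip, focus       |
| representation        | color                                       |
| volume                | volume_representation                       |
| volume_representation | color                                       |
| primitives            | primitive                                   |

`focus` is allowed under the root (whole-scene focus) as well as under a
component, because the builder explicitly supports both. A state may hold
at most one `camera` node; a second is a validation error rather than
last-wins, because silent override is the harder bug to find. Whether
multiple cameras should instead be tolerated is a known divergence risk
against other implementations of the format.

## Builder semantics

`mvs_builder()` returns a context holding the tree and a cursor; each
operation validates its arguments and the cursor's kind *before* touching
the tree, so a failed call leaves the context unchanged. R's value
semantics make this strong exception safety free of charge — and also make
true cycles unrepresentable, which is why traversal guards only against
runaway depth (512 levels).

Defaults are identity-like: `model_index = 0` (first model),
`radius_factor = 1`, `opacity = 1` (by omission), no timestamp in metadata
(so equal trees serialize to equal bytes). `mvs_at_root()` and `mvs_up()`
are pure cursor moves so fluent chains can return to the root for a second
`download` branch or a camera.

### Selectors

Selector field names copy mmCIF `_atom_site` item names verbatim, keeping
`label_*` and `auth_*` distinct; the two numbering schemes frequently
disagree in deposited entries, and silent fallback from one to the other
is a classic correctness trap, so a selector matches only the scheme the
user set. Expression semantics are union-across-expressions,
conjunction-within-expression, with inclusive `beg_*`/`end_*` ranges.
Static component membership: `protein`/`nucleic`/`branched` by entity
polymer type, `water` by entity type, `ion` as non-polymer entities whose
residues each contain a single atom (a proxy for single-element formulas
that needs no `_chem_comp` category), `ligand` as the remaining
non-polymer entities.

## Validation

`validate_state()` is table-driven (hierarchy table + per-kind parameter
schemas) and returns issues as data — path, breadcrumb such as
`root/download[0]/parse[0]`, severity, stable code, message — never
exceptions, and never mutates or coerces the tree. Anything that would
change rendering is an error; unknown parameter keys are errors unless
prefixed `x_` (the extension-key convention, demoted to warning), and
`--lenient` / `lenient = TRUE` downgrades unknown-key errors wholesale. A
document whose minor version exceeds the supported `1.0` within the same
major is accepted with a warning; a higher major version is refused at
read time.

The test suite confronts the table-driven validator with an independently
written rule-by-rule scanner on hundreds of randomly mutated fixtures;
they must agree on validity for every trial. This dual-route check is why
the validator's rules live in a table: a second, naive implementation of
the same prose is cheap, and disagreement pinpoints specification
ambiguities.

## Serialization choices

**Canonical MVSJ.** Object keys sorted, two-space indent, colors
normalized to lowercase `#rrggbb` (via the X11 table R ships), numbers
rendered as the shortest decimal string that round-trips to the identical
double — verified against both `strtod` and the JSON parser used on read,
which occasionally disagree by one ulp on shortest forms. Canonical bytes
make `write(read(write(s)))` a byte fixed point and let archives be
compared byte-for-byte. Readers must not require canonical input; any
strict-JSON document is accepted.

**MVSX.** A ZIP container whose first member is `index.mvsj`, then assets
in sorted path order, stored uncompressed with fixed timestamps — the
writer is deliberately minimal so identical inputs give identical bytes on
any platform. Member paths are confined to the archive root (no `..`, no
absolute paths) on both pack and unpack. Relative URLs (`./model.cif`)
must resolve to members; absolute URLs pass through untouched.

**URL fragments.** `"mvs:"` + unpadded base64url of the gzip-compressed
canonical MVSJ bytes. The standard names the capability (embedding a
state in a browser URL) but not the codec, so this encoding is
implementation-defined and documented as such. A 55-node state compresses
to about 5% of its MVSJ text.

## Geometry

* `check_rotation()`: a matrix is a rotation iff
  the infinity norm of `t(M) %*% M - I` is at most 1e-6 and `det(M)` is
  within 1e-6 of +1. Reflections (det −1) are rejected — a superposition
  transform must never mirror a chiral molecule.
* `transform_points()` applies `p' = R p + t`; the isometry property
  (pairwise distances preserved to 1e-9 relative) is tested over random
  clouds and rotations.
* Camera convention: right-handed coordinates, `fov` is the full vertical
  angle, the camera looks from `position` toward `target`.
  `camera_from_focus()` places the camera at distance `r / sin(fov/2)`
  from the target sphere's center — the sphere-in-*cone* fit, not the
  commoner `r / tan(fov/2)` great-circle approximation, so the whole
  sphere is inside the view cone, verified by sampling sphere-surface
  points over random configurations. The effective radius
  `radius_factor * r + radius_extent` is floored at 0.01 Å so a
  single-atom focus still yields a finite camera. The up vector is
  Gram–Schmidt re-orthogonalized against the view direction. Focus
  adjusts position only, never the field of view.
* `bounding_sphere()` seeds with a Ritter-style diameter estimate and
  tightens it with a few bouncing-bubble passes followed by an exact
  covering pass. Plain two-pass Ritter can exceed 10% over the optimal
  radius on flat or elongated clouds; with refinement the observed excess
  stays under ~4%, and the tested contract is containment plus radius ≤
  1.1 × the exact minimum (computed by a Welzl solver kept in the test
  code, never used by the implementation).
* `measure_angle()` clamps the cosine into [−1, 1] before `acos`, so
  rounding on near-collinear triples yields 0° or 180°, never `NaN`.

## Synthetic fixtures: what they emulate, what they do not

`make_mmcif()` generates valid PDBx/mmCIF with `_entity`, `_entity_poly`
and `_atom_site` categories: poly-glycine-like chains of backbone atoms on
a jittered 3.8 Å grid, optional water and a 3-atom ligand. Chains are
exact translated copies (the jitter stream restarts per chain), so
inter-chain centroid distances equal the configured `chain_offset` — that
is what makes the audit's distance-primitive check exact by construction.
The declared counts are embedded in a comment header, giving tests a
count oracle that does not pass through the parser being tested.

The generator's jitter comes from a private linear congruential generator,
never R's global RNG, so equal specs are byte-identical regardless of the
session's RNG state.

What fixtures deliberately do not have: realistic stereochemistry or
secondary structure, occupancies and B-factors, altlocs, multi-model
ensembles, assembly operators, or volumetric maps (the isosurface example
references a map by external URL and the audit flags it as
unresolvable-by-design). Passing tests therefore demonstrate that the
*description layer* — selection semantics, counts, geometry, container
formats — behaves exactly; they say nothing about rendering fidelity or
about parsing the full diversity of deposited mmCIF (the reader covers
the categories above, quoting, comments and semicolon text fields, not
the entire dialect).

## Problem sizes

The shipped checks run at desk scale, chosen to finish in well under a
minute each while exercising every code path: 500 serialization round
trips, 1000 random legal builder chains, 200 single-field mutations, 300
random selectors against a brute-force filter, 500 camera configurations
with 1000 sampled surface points each, 100 random clouds for the isometry
property. `scripts/acceptance.R` recomputes all of these from scratch at
the same sizes.

## Known limitations

* BinaryCIF is representable as a format tag but payloads are opaque; no
  decoding.
* PDB-format references validate but the resolver declines to read them.
* Assembly and symmetry expansion parameters are carried, validated and
  serialized, but the resolver audits asymmetric-unit coordinates only and
  its report says so.
* Selector behaviour across assembly-generated copies is unspecified
  upstream and therefore undefined here.
* Color themes and palettes beyond single colors, and automatic
  computation of superposition matrices from two structures, are out of
  scope: users supply the transform.
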