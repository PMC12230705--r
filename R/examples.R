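# Canned example states exercising the standard's feature families:
# superposition, per-residue coloring, isosurfaces, measurement
# primitives, and a multi-snapshot narrative. Every example validates
# clean and references fixture-relative URLs so mvs_demo() can pack fully
# self-contained archives with zero network use.

.EXAMPLE_NAMES <- c("superposition", "plddt_coloring", "isosurface",
                    "measurements", "story")

chain_sel <- function(chain) {
  mvs_selector(expressions = list(list(label_asym_id = chain)))
}

example_superposition <- function() {
  rot <- rotation_about_axis(c(0, 0, 1), 0.35)
  mvs_builder() |>
    mvs_download("./apo.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(chain_sel("A")) |>
    mvs_representation("cartoon") |> mvs_color("#4577b5") |>
    mvs_at_root() |>
    mvs_download("./holo.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_transform(rot, translation = c(1.5, 0, 0)) |>
    mvs_component(chain_sel("A")) |>
    mvs_representation("cartoon") |> mvs_color("#d98032") |>
    mvs_state(title = "Superposed apo and bound forms",
              description = paste("Two structures, chain A each, the",
                                  "second rigid-body transformed onto the",
                                  "first."))
}

# confidence-band palette in the AlphaFold style: very high, confident,
# low, very low
.PLDDT_BANDS <- list(
  list(beg = 1, end = 2, color = "#0053d6"),
  list(beg = 3, end = 4, color = "#64cbf3"),
  list(beg = 5, end = 6, color = "#ffdb13"),
  list(beg = 7, end = 8, color = "#ff7d45")
)

example_plddt <- function() {
  b <- mvs_builder() |>
    mvs_download("./predicted.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(mvs_selector("protein")) |>
    mvs_tooltip("residue-wise model confidence (pLDDT)") |>
    mvs_representation("cartoon")
  for (band in .PLDDT_BANDS) {
    b <- mvs_color(b, band$color,
                   selector = mvs_selector(expressions = list(
                     list(beg_label_seq_id = band$beg,
                          end_label_seq_id = band$end))))
  }
  mvs_state(b, title = "Predicted structure colored by confidence")
}

example_isosurface <- function() {
  mvs_builder() |>
    mvs_download("./model.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(mvs_selector("ligand")) |>
    mvs_representation("ball_and_stick") |> mvs_color("#cccccc") |>
    mvs_up(2) |> mvs_component(mvs_selector("ligand")) |> mvs_focus() |>
    mvs_at_root() |>
    mvs_download("https://maps.example.org/density/xray.map") |>
    mvs_parse("map") |>
    mvs_volume_isosurface(relative_isovalue = 1.5, show_wireframe = TRUE) |>
    mvs_color("#3362b2") |>
    mvs_state(title = "Density map around a ligand",
              description = paste("The map is referenced by an external",
                                  "URL and deliberately not bundled into",
                                  "demo archives."))
}

example_measurements <- function() {
  mvs_builder() |>
    mvs_download("./model.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(mvs_selector("all")) |>
    mvs_representation("ball_and_stick") |>
    mvs_up(2) |>
    mvs_primitive(primitive_distance(chain_sel("A"), chain_sel("B"),
                                     label_template = "{{distance}} A",
                                     color = "#222222", dash = "dotted")) |>
    mvs_primitive(primitive_angle(c(3.8, 0, 0), c(0, 0, 0), c(0, 1.4, 0),
                                  label_template = "{{angle}} deg",
                                  color = "#B22222")) |>
    mvs_primitive(primitive_sphere(c(0, 0, 0), 2.5, color = "#2ca02c",
                                   opacity = 0.5)) |>
    mvs_state(title = "Measurement primitives",
              description = paste("A crosslink-style dotted distance",
                                  "between chain centroids, an angle, and",
                                  "a marker sphere."))
}

example_story <- function() {
  overview <- mvs_builder() |>
    mvs_download("./model.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(mvs_selector("protein")) |>
    mvs_representation("cartoon") |> mvs_color("#4577b5") |>
    mvs_state(title = "Overview")
  zoom <- mvs_builder() |>
    mvs_download("./model.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(mvs_selector("protein")) |>
    mvs_representation("cartoon") |> mvs_color("#cccccc") |>
    mvs_up(2) |>
    mvs_component(mvs_selector("ligand")) |>
    mvs_representation("ball_and_stick") |> mvs_color("#d98032") |>
    mvs_up(1) |> mvs_focus(radius_extent = 2) |>
    mvs_state(title = "Ligand site")
  annotated <- mvs_builder() |>
    mvs_download("./model.cif") |> mvs_parse("mmcif") |>
    mvs_structure("model") |>
    mvs_component(mvs_selector("ligand")) |>
    mvs_representation("ball_and_stick") |> mvs_up(1) |>
    mvs_label("bound ligand") |> mvs_tooltip("synthetic 3-atom ligand") |>
    mvs_state(title = "Annotated ligand")
  mvs_snapshots(list(overview, zoom, annotated),
                keys = c("overview", "zoom", "annotated"),
                linger_duration_ms = 1000, transition_duration_ms = 500,
                title = "A three-scene narrative")
}

#' Build a canned example state
#'
#' Each example validates clean and exercises one feature family of the
#' standard: `superposition` (two downloads, one rigid-body transform),
#' `plddt_coloring` (per-residue-band color list on one chain),
#' `isosurface` (a volume branch parallel to the structure branch),
#' `measurements` (distance/angle/sphere primitives, crosslink-style
#' dotted distance), `story` (a three-snapshot narrative with timing
#' metadata).
#'
#' @param name One of `superposition`, `plddt_coloring`, `isosurface`,
#'   `measurements`, `story`.
#' @return An `mvs_state` (or `mvs_snapshot_list` for `"story"`).
#' @export
#' @examples
#' s <- make_example_state("superposition")
#' length(find_nodes(s$root, "download"))  # 2
make_example_state <- function(name) {
  switch(match.arg(name, .EXAMPLE_NAMES),
         superposition = example_superposition(),
         plddt_coloring = example_plddt(),
         isosurface = example_isosurface(),
         measurements = example_measurements(),
         story = example_story())
}

demo_assets <- function(name) {
  switch(name,
    superposition = list(
      "./apo.cif" = make_mmcif(fixture_spec(seed = 1L)),
      "./holo.cif" = make_mmcif(fixture_spec(seed = 2L))),
    plddt_coloring = list(
      "./predicted.cif" = make_mmcif(fixture_spec(
        n_chains = 1L, residues_per_chain = 8L, seed = 3L))),
    isosurface = list(
      "./model.cif" = make_mmcif(fixture_spec(
        n_chains = 1L, include_ligand = TRUE, seed = 4L))),
    measurements = list(
      "./model.cif" = make_mmcif(fixture_spec(seed = 5L))),
    story = list(
      "./model.cif" = make_mmcif(fixture_spec(
        include_ligand = TRUE, seed = 6L))),
    stop("unknown demo name '", name, "'", call. = FALSE))
}

#' Pack a self-contained demo archive
#'
#' Builds the named example state, generates its fixture structures, and
#' packs everything into an MVSX archive. The result is fully
#' self-contained (the isosurface demo's external map URL excepted, by
#' design) and byte-deterministic.
#'
#' @param name An example name (see [make_example_state()]).
#' @return Raw vector of MVSX archive bytes.
#' @export
mvs_demo <- function(name) {
  name <- match.arg(name, .EXAMPLE_NAMES)
  pack_mvsx(make_example_state(name), assets = demo_assets(name))
}
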