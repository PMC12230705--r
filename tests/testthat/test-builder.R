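test_that("a fresh builder holds a single root node", {
  b <- mvs_builder()
  expect_identical(b$root$kind, "root")
  expect_length(mvs_traverse(b$root), 1L)
  # independent contexts diverge independently
  b1 <- mvs_download(mvs_builder(), "./a.cif")
  b2 <- mvs_download(mvs_builder(), "./b.cif")
  expect_false(tree_equal(b1$root, b2$root))
  # empty builder already yields a valid minimal state
  expect_s3_class(mvs_state(mvs_builder()), "mvs_state")
})

test_that("illegal parent/child calls raise hierarchy errors and leave the tree unchanged", {
  b <- mvs_builder() |> mvs_download("./m.cif") |> mvs_parse("mmcif") |>
    mvs_structure() |> mvs_component("protein")
  before <- b$root
  illegal <- list(
    function(x) mvs_download(x, "./again.cif"),      # under component
    function(x) mvs_parse(x, "mmcif"),               # under component
    function(x) mvs_structure(x),                    # under component
    function(x) mvs_color(x, "#ff0000"),             # under component
    function(x) mvs_camera(x, c(0, 0, 0), c(0, 0, 1)),
    function(x) mvs_transform(x, diag(3)),
    function(x) mvs_volume(x)
  )
  for (f in illegal) {
    expect_error(f(b), class = "mvs_hierarchy_error")
    expect_true(tree_equal(b$root, before))
  }
})

test_that("download/parse/structure chain records formats and modes", {
  b <- mvs_builder() |>
    mvs_download("https://files.wwpdb.org/download/1tqn.cif") |>
    mvs_parse("mmcif")
  expect_length(mvs_traverse(b$root), 3L)
  expect_error(mvs_parse(mvs_download(mvs_builder(), "./x"), "xyz"),
               "legal formats")
  # relative URLs pass through untouched
  rel <- mvs_builder() |> mvs_download("./model.cif")
  expect_identical(find_nodes(rel$root, "download")[[1]]$params$url,
                   "./model.cif")
  b2 <- b |> mvs_structure("assembly", assembly_id = "1")
  st <- find_nodes(b2$root, "structure")[[1]]
  expect_identical(st$params$mode, "assembly")
  expect_identical(st$params$model_index, 0)
  expect_error(b |> mvs_structure("model", assembly_id = "1"),
               "only legal with")
  expect_error(b |> mvs_structure("model", radius = 5), "only legal with")
  # a map parse cannot grow a structure branch
  mp <- mvs_builder() |> mvs_download("./d.map") |> mvs_parse("map")
  expect_error(mvs_structure(mp), class = "mvs_hierarchy_error")
})

test_that("components, representations, labels and colors validate inputs", {
  st <- mvs_builder() |> mvs_download("./m.cif") |> mvs_parse("mmcif") |>
    mvs_structure()
  expect_error(mvs_component(st, mvs_selector(expressions = list())),
               "selects nothing")
  b <- st |> mvs_component(mvs_selector(expressions = list(
    list(label_asym_id = "A"))))
  expect_identical(find_nodes(b$root, "component")[[1]]$params$selector[[1]],
                   list(label_asym_id = "A"))
  expect_error(mvs_representation(b, "ribbon"), "supported types")
  r <- b |> mvs_representation("cartoon")
  expect_error(mvs_color(r, "#ggg"), "invalid color")
  expect_identical(
    find_nodes(mvs_color(r, "skyblue")$root, "color")[[1]]$params$color,
    "#87ceeb")
  expect_error(mvs_label(b, ""), "non-empty")
  expect_error(mvs_tooltip(b, ""), "non-empty")
  lt <- b |> mvs_label("Nup84") |> mvs_tooltip("crosslink 23-145")
  expect_length(find_nodes(lt$root, "label"), 1L)
  expect_length(find_nodes(lt$root, "tooltip"), 1L)
})

test_that("transforms require proper rotations", {
  st <- mvs_builder() |> mvs_download("./m.cif") |> mvs_parse("mmcif") |>
    mvs_structure()
  expect_s3_class(mvs_transform(st, diag(3)), "mvs_builder")
  rod <- rotation_about_axis(c(1, 1, 1) / sqrt(3), 0.7)
  expect_s3_class(mvs_transform(st, rod, c(1, 0, 0)), "mvs_builder")
  expect_error(mvs_transform(st, diag(c(1, 1, -1))), "proper rotation")
})

test_that("cameras and focus nodes enforce their geometric invariants", {
  b <- mvs_builder()
  expect_s3_class(mvs_camera(b, c(0, 0, 0), c(0, 0, 100), c(0, 1, 0)),
                  "mvs_builder")
  expect_error(mvs_camera(b, c(1, 2, 3), c(1, 2, 3)), "differ from target")
  expect_error(mvs_camera(b, c(0, 0, 0), c(0, 0, 100), c(0, 0, 2)),
               "parallel")
  comp <- b |> mvs_download("./m.cif") |> mvs_parse("mmcif") |>
    mvs_structure() |> mvs_component("ligand")
  f <- mvs_focus(comp)
  expect_length(find_nodes(f$root, "focus")[[1]]$params, 0L)
  expect_error(mvs_focus(comp, radius_factor = 0), "positive")
})

test_that("primitives validate payloads and share one group node", {
  b <- mvs_builder()
  expect_error(mvs_primitive(b, primitive_sphere(c(1, 2, 3), 0)),
               "positive")
  expect_silent(primitive_mesh(runif(9), c(0, 1, 2)))
  expect_error(primitive_mesh(runif(9), c(0, 1, 5)), "out of range")
  expect_error(primitive_distance(c(0, 0, 0), c(1, 1, 1),
                                  label_template = "{{foo}}"),
               "unknown placeholder")
  two <- b |>
    mvs_primitive(primitive_distance(c(0, 0, 0), c(3, 4, 0),
                                     label_template = "{{distance}} A",
                                     dash = "dashed")) |>
    mvs_primitive(primitive_sphere(c(0, 0, 0), 1))
  expect_length(find_nodes(two$root, "primitives"), 1L)
  expect_length(find_nodes(two$root, "primitive"), 2L)
})

test_that("volume branch requires a map parse and exactly one isovalue", {
  mp <- mvs_builder() |> mvs_download("./d.map") |> mvs_parse("map")
  expect_error(mvs_volume_isosurface(mp, relative_isovalue = 1,
                                     absolute_isovalue = 1),
               "exactly one")
  expect_error(mvs_volume_isosurface(mp), "exactly one")
  v <- mvs_volume_isosurface(mp, relative_isovalue = 1.5)
  expect_length(find_nodes(v$root, "volume"), 1L)
  expect_length(find_nodes(v$root, "volume_representation"), 1L)
  s <- mvs_state(v)
  expect_identical(nrow(validate_state(s)), 0L)
  cif <- mvs_builder() |> mvs_download("./m.cif") |> mvs_parse("mmcif")
  expect_error(mvs_volume(cif), class = "mvs_hierarchy_error")
})

test_that("snapshot composition preserves order and refuses empties", {
  states <- lapply(c("one", "two", "three"), function(t) {
    mvs_builder() |> mvs_state(title = t)
  })
  sl <- mvs_snapshots(states, linger_duration_ms = 1000)
  expect_length(sl$snapshots, 3L)
  expect_identical(vapply(sl$snapshots,
                          function(s) s$state$metadata$title, character(1)),
                   c("one", "two", "three"))
  expect_identical(sl$snapshots[[2]]$linger_duration_ms, 1000)
  expect_error(mvs_snapshots(list()), "at least one")
})

test_that("the two-structure superposition scenario has the expected shape", {
  s <- make_example_state("superposition")
  expect_length(find_nodes(s$root, "download"), 2L)
  expect_gte(length(find_nodes(s$root, "transform")), 1L)
  expect_length(find_nodes(s$root, "component"), 2L)
})

test_that("random legal builder chains always validate clean", {
  set.seed(101)
  for (i in 1:150) {
    s <- random_builder_state()
    iss <- validate_state(s)
    expect_identical(sum(iss$severity == "error"), 0L)
  }
})
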