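test_that("fixture generation is deterministic and count-exact", {
  spec <- fixture_spec(n_chains = 2, residues_per_chain = 3,
                       atoms_per_residue = 4)
  expect_identical(make_mmcif(spec), make_mmcif(spec))
  expect_identical(nrow(read_mmcif_atoms(make_mmcif(spec))), 24L)
  with_water <- fixture_spec(include_water = TRUE)
  expect_identical(nrow(read_mmcif_atoms(make_mmcif(with_water))), 25L)
  # declared header equals parsed reality across random specs
  set.seed(606)
  for (i in 1:10) {
    txt <- make_mmcif(random_fixture_spec())
    expect_identical(nrow(read_mmcif_atoms(txt)),
                     fixture_declared_counts(txt)$total_atoms)
  }
})

test_that("example states expose their defining node signatures", {
  sup <- make_example_state("superposition")
  expect_length(find_nodes(sup$root, "download"), 2L)
  expect_length(find_nodes(sup$root, "transform"), 1L)
  expect_length(find_nodes(sup$root, "component"), 2L)

  pl <- make_example_state("plddt_coloring")
  expect_gte(length(find_nodes(pl$root, "color")), 4L)

  iso <- make_example_state("isosurface")
  vr <- find_nodes(iso$root, "volume_representation")
  expect_length(vr, 1L)
  iso_keys <- intersect(names(vr[[1]]$params),
                        c("relative_isovalue", "absolute_isovalue"))
  expect_length(iso_keys, 1L)

  me <- make_example_state("measurements")
  prim_kinds <- vapply(find_nodes(me$root, "primitive"),
                       function(n) n$params$kind, character(1))
  expect_true(all(c("distance_measurement", "angle_measurement",
                    "sphere") %in% prim_kinds))

  story <- make_example_state("story")
  expect_s3_class(story, "mvs_snapshot_list")
  expect_length(story$snapshots, 3L)
  for (s in story$snapshots) {
    expect_identical(sum(validate_state(s$state)$severity == "error"), 0L)
  }
  expect_error(make_example_state("nope"))
})

test_that("every example round-trips losslessly through MVSJ and the URL codec", {
  for (nm in c("superposition", "plddt_coloring", "isosurface",
               "measurements")) {
    s <- make_example_state(nm)
    expect_identical(sum(validate_state(s)$severity == "error"), 0L)
    expect_true(tree_equal(read_mvsj(write_mvsj(s))$root, s$root))
    expect_true(tree_equal(decode_url_fragment(encode_url_fragment(s))$root,
                           s$root))
  }
  story <- make_example_state("story")
  back <- decode_url_fragment(encode_url_fragment(story))
  expect_length(back$snapshots, 3L)
})

test_that("demo archives are self-contained and audit clean", {
  for (nm in c("superposition", "plddt_coloring", "isosurface",
               "measurements", "story")) {
    arc <- mvs_demo(nm)
    expect_identical(mvs_demo(nm), arc)  # byte determinism
    u <- unpack_mvsx(arc)
    expect_true(all(u$audit$resolved))
    expect_identical(sum(validate_state(u$state)$severity == "error"), 0L)
    states <- if (inherits(u$state, "mvs_snapshot_list")) {
      lapply(u$state$snapshots, `[[`, "state")
    } else {
      list(u$state)
    }
    structures <- lapply(u$assets, function(b) read_mmcif_atoms(rawToChar(b)))
    names(structures) <- paste0("./", names(u$assets))
    for (s in states) {
      report <- audit_state_against_structures(s, structures = structures)
      expect_false("empty_selection" %in% report$warnings$code)
      solid <- report$references[report$references$format != "map", ,
                                 drop = FALSE]
      expect_true(all(solid$status == "resolved"))
      if (nm == "isosurface") {
        maps <- report$references[report$references$format == "map", ,
                                  drop = FALSE]
        expect_identical(maps$status, "external_by_design")
      }
    }
  }
})
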