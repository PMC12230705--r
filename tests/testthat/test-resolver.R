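fixture_atoms <- function(...) read_mmcif_atoms(make_mmcif(fixture_spec(...)))

test_that("the mmCIF reader recovers the generator's declared composition", {
  spec <- fixture_spec(n_chains = 2, residues_per_chain = 3,
                       atoms_per_residue = 4, include_water = TRUE)
  txt <- make_mmcif(spec)
  atoms <- read_mmcif_atoms(txt)
  declared <- fixture_declared_counts(txt)
  expect_identical(nrow(atoms), declared$total_atoms)
  expect_identical(nrow(atoms), 25L)
  expect_identical(atoms$atom_index, 0:24)
  expect_identical(sum(atoms$entity_type == "water"), 1L)
  # "." insertion codes parse to NA
  expect_true(all(is.na(atoms$pdbx_PDB_ins_code)))
  # polymer typing from _entity_poly
  expect_identical(unique(atoms$entity_type[atoms$label_asym_id == "A"]),
                   "polymer_protein")
  expect_error(read_mmcif_atoms("data_x\n_cell.length_a 10\n"),
               "_atom_site")
})

test_that("static selectors partition the fixture by entity class", {
  atoms <- fixture_atoms(include_water = TRUE, include_ligand = TRUE)
  expect_length(resolve_selector(atoms, "all"), nrow(atoms))
  expect_length(resolve_selector(atoms, "protein"), 24L)
  expect_length(resolve_selector(atoms, "water"), 1L)
  expect_length(resolve_selector(atoms, "ligand"), 3L)
  expect_length(resolve_selector(atoms, "nucleic"), 0L)
})

test_that("expression selectors match the brute-force row filter", {
  atoms <- fixture_atoms()
  chainA <- resolve_selector(atoms, mvs_selector(expressions = list(
    list(label_asym_id = "A"))))
  expect_length(chainA, 12L)
  expect_identical(chainA,
                   sort(atoms$atom_index[atoms$label_asym_id == "A"]))
  # overlapping ranges union without duplicates
  sel <- mvs_selector(expressions = list(
    list(beg_label_seq_id = 1, end_label_seq_id = 2),
    list(beg_label_seq_id = 2, end_label_seq_id = 3)))
  got <- resolve_selector(atoms, sel)
  expect_identical(got, brute_selector(atoms, sel))
  expect_identical(anyDuplicated(got), 0L)
  # order of expressions is irrelevant
  rev_sel <- mvs_selector(expressions = rev(sel$expressions))
  expect_identical(resolve_selector(atoms, rev_sel), got)
})

test_that("random selectors agree with the oracle across random fixtures", {
  set.seed(505)
  for (i in 1:100) {
    atoms <- read_mmcif_atoms(make_mmcif(random_fixture_spec()))
    for (j in 1:3) {
      sel <- random_selector()
      expect_identical(resolve_selector(atoms, sel),
                       brute_selector(atoms, sel))
    }
  }
})

test_that("auth and label numbering schemes never alias", {
  # shift auth_seq_id away from label_seq_id by rewriting the column
  txt <- make_mmcif(fixture_spec(n_chains = 1))
  atoms <- read_mmcif_atoms(txt)
  atoms$auth_seq_id <- atoms$auth_seq_id + 100L
  lab <- resolve_selector(atoms, mvs_selector(expressions = list(
    list(label_seq_id = 1))))
  aut <- resolve_selector(atoms, mvs_selector(expressions = list(
    list(auth_seq_id = 1))))
  expect_gt(length(lab), 0L)
  expect_length(aut, 0L)
})

test_that("component spheres cover selections and refuse empty ones", {
  atoms <- fixture_atoms()
  one <- component_sphere(atoms, 0L)
  expect_identical(one$radius, 0)
  expect_equal(one$center, c(atoms$x[1], atoms$y[1], atoms$z[1]))
  all_idx <- resolve_selector(atoms, "all")
  sph <- component_sphere(atoms, all_idx)
  exact <- min_enclosing_sphere(cbind(atoms$x, atoms$y, atoms$z))
  expect_lte(sph$radius, exact$radius * 1.1)
  expect_error(component_sphere(atoms, integer(0)), "empty selection")
})

test_that("the audit reports counts, empty selections and known distances", {
  spec <- fixture_spec(n_chains = 2, chain_offset = c(20, 0, 0))
  atoms <- read_mmcif_atoms(make_mmcif(spec))
  s <- make_example_state("measurements")
  report <- audit_state_against_structures(
    s, structures = list("./model.cif" = atoms))
  expect_identical(report$components$atom_count, nrow(atoms))
  expect_false("empty_selection" %in% report$warnings$code)
  # chains are exact translated copies: centroid distance == |offset|
  expect_identical(nrow(report$distances), 1L)
  expect_equal(report$distances$distance[1], 20, tolerance = 1e-3)
  expect_match(report$distances$label[1], "^20\\.00 A$")

  ghost <- mvs_builder() |> mvs_download("./model.cif") |>
    mvs_parse("mmcif") |> mvs_structure() |>
    mvs_component(mvs_selector(expressions = list(
      list(label_asym_id = "Z")))) |>
    mvs_representation("cartoon") |> mvs_state()
  rep2 <- audit_state_against_structures(
    ghost, structures = list("./model.cif" = atoms))
  expect_true("empty_selection" %in% rep2$warnings$code)
  expect_error(audit_state_against_structures(ghost, structures = list()),
               "no structure supplied")
})
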