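minimal_state <- function() mvs_builder() |> mvs_state()

test_that("a minimal state validates clean and issues are deterministic", {
  s <- minimal_state()
  expect_identical(nrow(validate_state(s)), 0L)
  # idempotence on a broken state
  bad <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("representation", list(type = "cartoon")))))
  i1 <- validate_state(bad)
  i2 <- validate_state(bad)
  expect_identical(i1, i2)
})

test_that("hierarchy violations are reported with stable codes and breadcrumbs", {
  bad <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("representation", list(type = "cartoon")))))
  iss <- validate_state(bad)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$code, "hierarchy.illegal_parent")
  expect_identical(iss$breadcrumb, "root/representation[0]")
  unknown <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("frobnicate"))))
  expect_identical(validate_state(unknown)$code, "kind.unknown")
})

test_that("parameter checking flags types, enums, bounds and conflicts", {
  expect_identical(nrow(check_params("parse", list(format = "mmcif"))), 0L)
  expect_identical(check_params("parse", list(format = 7))$code,
                   "params.type_mismatch")
  expect_identical(check_params("parse", list(format = "xyz"))$code,
                   "params.out_of_enum")
  conflict <- check_params("structure",
                           list(mode = "model", assembly_id = "1"))
  expect_true("params.conflict" %in% conflict$code)
  both <- check_params("volume_representation",
                       list(type = "isosurface", relative_isovalue = 1,
                            absolute_isovalue = 2))
  expect_true("params.conflict" %in% both$code)
  missing <- check_params("download", list())
  expect_identical(missing$code, "params.missing_required")
  unknown <- check_params("download", list(url = "./x", shiny = TRUE))
  expect_identical(unknown$code, "params.unknown_key")
  expect_identical(unknown$severity, "error")
  lenient <- check_params("download", list(url = "./x", shiny = TRUE),
                          lenient = TRUE)
  expect_identical(lenient$severity, "warning")
})

test_that("metadata version is required and the version policy is enforced", {
  no_version <- new_mvs_state(mvs_node("root"), metadata = list())
  expect_true("metadata.version_missing" %in% validate_state(no_version)$code)
  newer_minor <- new_mvs_state(mvs_node("root"),
                               metadata = list(version = "1.99"))
  iss <- validate_state(newer_minor)
  expect_identical(iss$severity, "warning")
  expect_identical(sum(iss$severity == "error"), 0L)
})

test_that("assert_valid passes valid states through and aggregates failures", {
  s <- minimal_state()
  expect_true(tree_equal(assert_valid(s)$root, s$root))
  # three injected errors -> failure listing exactly 3 issues
  bad <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("representation", list(type = "cartoon")),
    mvs_node("download", list()),
    mvs_node("frobnicate"))))
  err <- tryCatch(assert_valid(bad), error = function(e) e)
  expect_s3_class(err, "mvs_validation_error")
  expect_match(conditionMessage(err), "3 issue\\(s\\)")
  # warning-only states pass through (extension-prefixed key)
  warn_only <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("download", list(url = "./m.cif", x_note = "hi")))))
  expect_s3_class(assert_valid(warn_only), "mvs_state")
  expect_identical(validate_state(warn_only)$severity, "warning")
})

test_that("at most one camera node is permitted per state", {
  two_cams <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("camera", list(target = c(0, 0, 0), position = c(0, 0, 1),
                            up = c(0, 1, 0))),
    mvs_node("camera", list(target = c(0, 0, 0), position = c(0, 0, 2),
                            up = c(0, 1, 0))))))
  expect_true("hierarchy.multiple_cameras" %in% validate_state(two_cams)$code)
})

test_that("mutated fixtures always fail and agree with the naive scanner", {
  set.seed(202)
  fx <- mutation_fixture_state()
  expect_identical(naive_scan_state(fx), 0L)
  for (i in 1:200) {
    m <- mutate_state(fx)
    nerr <- sum(validate_state(m)$severity == "error")
    expect_gte(nerr, 1L)
    expect_identical(nerr >= 1L, naive_scan_state(m) >= 1L)
  }
})

test_that("issue lists serialize to machine-readable JSON lines", {
  bad <- new_mvs_state(mvs_node("root", children = list(
    mvs_node("frobnicate"))))
  lines <- issues_to_json_lines(validate_state(bad))
  expect_length(lines, 1L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$code, "kind.unknown")
  expect_identical(rec$severity, "error")
})
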