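test_that("traversal is depth-first pre-order with exact paths", {
  lone <- mvs_node("root")
  out <- mvs_traverse(lone)
  expect_length(out, 1L)
  expect_identical(out[[1]]$path, integer(0))

  # root with children A, B; A has child C -> order root, A, C, B
  tree <- mvs_node("root", children = list(
    mvs_node("download", list(url = "a"), children = list(
      mvs_node("parse", list(format = "mmcif")))),
    mvs_node("canvas")))
  kinds <- vapply(mvs_traverse(tree), function(e) e$node$kind, character(1))
  expect_identical(kinds, c("root", "download", "parse", "canvas"))

  set.seed(7)
  big <- random_raw_tree(50L)
  entries <- mvs_traverse(big)
  expect_length(entries, 50L)
  oracle <- enumerate_tree(big)
  expect_length(oracle, 50L)
  for (i in seq_along(entries)) {
    expect_identical(entries[[i]]$path, oracle[[i]]$path)
    # every reported path resolves back to its node
    n <- big
    for (j in entries[[i]]$path) n <- n$children[[j]]
    expect_true(tree_equal(n, entries[[i]]$node))
  }
})

test_that("traversal count matches construction for random trees", {
  set.seed(123)
  for (n in c(1L, 5L, 20L, 80L)) {
    tr <- random_raw_tree(n)
    expect_length(mvs_traverse(tr), n)
  }
})

test_that("tree equality is an order-sensitive equivalence relation", {
  set.seed(21)
  corpus <- lapply(1:10, function(i) random_raw_tree(sample(3:30, 1)))
  for (t in corpus) expect_true(tree_equal(t, t))
  for (i in 1:5) {
    a <- corpus[[sample(10, 1)]]
    b <- corpus[[sample(10, 1)]]
    expect_identical(tree_equal(a, b), tree_equal(b, a))
  }
  # transitivity on equal copies
  a <- corpus[[1]]
  b <- a
  c <- a
  expect_true(tree_equal(a, b) && tree_equal(b, c) && tree_equal(a, c))

  # differing only in child order -> unequal
  ab <- mvs_node("root", children = list(mvs_node("download", list(url = "a")),
                                         mvs_node("canvas")))
  ba <- mvs_node("root", children = list(mvs_node("canvas"),
                                         mvs_node("download", list(url = "a"))))
  expect_false(tree_equal(ab, ba))
})

test_that("every single-field mutation flips tree equality", {
  base <- make_example_state("superposition")$root
  set.seed(31)
  for (i in 1:25) {
    mutated <- mutate_state(new_mvs_state(base))$root
    expect_false(tree_equal(base, mutated))
  }
})

test_that("find_nodes equals traverse-plus-filter for every kind", {
  s <- make_example_state("superposition")
  expect_length(find_nodes(s$root, "component"), 2L)
  expect_length(find_nodes(s$root, "volume"), 0L)
  expect_identical(find_nodes(s$root, "root")[[1]]$kind, "root")
  set.seed(5)
  tr <- random_raw_tree(60L)
  for (k in node_kinds()) {
    via_filter <- Filter(function(e) identical(e$node$kind, k),
                         mvs_traverse(tr))
    found <- find_nodes(tr, k)
    expect_length(found, length(via_filter))
    for (i in seq_along(found)) {
      expect_true(tree_equal(found[[i]], via_filter[[i]]$node))
    }
  }
})

test_that("parameter normalization makes built and parsed values identical", {
  n1 <- mvs_node("transform", list(translation = c(1L, 2L, 3L)))
  n2 <- mvs_node("transform", list(translation = list(1, 2, 3)))
  expect_true(tree_equal(n1, n2))
  expect_identical(n1$params$translation, c(1, 2, 3))
})
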