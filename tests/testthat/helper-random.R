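# Randomized-case generators shared by the property tests and
# scripts/acceptance.R. All draw from R's RNG: callers set.seed().

# arbitrary (not necessarily schema-valid) node trees, for the generic
# tree operations
random_raw_tree <- function(n_nodes = 50L) {
  kinds <- node_kinds()
  nodes <- lapply(seq_len(n_nodes), function(i) {
    mvs_node(sample(kinds, 1),
             params = if (runif(1) < 0.5) list(x_i = as.double(i)) else list())
  })
  # node i hangs under a uniformly random earlier node: always a tree
  parent_of <- c(NA_integer_, vapply(seq_len(n_nodes)[-1], function(i) {
    sample(i - 1L, 1)
  }, integer(1)))
  build <- function(i) {
    kids <- which(parent_of == i)
    node <- nodes[[i]]
    node$children <- lapply(kids, build)
    node
  }
  build(1L)
}

random_hex_color <- function() {
  if (runif(1) < 0.5) {
    sprintf("#%02x%02x%02x", sample(0:255, 1), sample(0:255, 1),
            sample(0:255, 1))
  } else {
    sample(c("red", "skyblue", "tomato", "steelblue", "gold"), 1)
  }
}

random_expression <- function() {
  out <- list()
  picks <- sample(c("chain", "range", "atom", "elem", "index"),
                  sample(1:2, 1))
  if ("chain" %in% picks) {
    out[[sample(c("label_asym_id", "auth_asym_id"), 1)]] <-
      sample(c("A", "B", "C", "W", "L", "Z"), 1)
  }
  if ("range" %in% picks) {
    lo <- sample(1:4, 1)
    hi <- lo + sample(0:3, 1)
    if (runif(1) < 0.5) {
      out$beg_label_seq_id <- lo
      out$end_label_seq_id <- hi
    } else {
      out$beg_auth_seq_id <- lo
      out$end_auth_seq_id <- hi
    }
  }
  if ("atom" %in% picks) {
    out[[sample(c("label_atom_id", "auth_atom_id"), 1)]] <-
      sample(c("N", "CA", "C", "O", "C1", "OXT"), 1)
  }
  if ("elem" %in% picks) out$type_symbol <- sample(c("C", "N", "O", "S"), 1)
  if ("index" %in% picks) out$atom_index <- sample(0:30, 1)
  out
}

random_selector <- function() {
  if (runif(1) < 0.35) {
    mvs_selector(sample(c("all", "protein", "nucleic", "branched", "ligand",
                          "ion", "water"), 1))
  } else {
    mvs_selector(expressions = lapply(seq_len(sample(1:3, 1)),
                                      function(i) random_expression()))
  }
}

random_primitive <- function() {
  switch(sample(4, 1),
    primitive_sphere(runif(3, -10, 10), runif(1, 0.5, 3),
                     color = random_hex_color(),
                     opacity = round(runif(1), 2)),
    primitive_distance(runif(3, -10, 10), runif(3, -10, 10),
                       dash = sample(c("dashed", "dotted"), 1)),
    primitive_angle(runif(3, -10, 10), runif(3, 1, 10), runif(3, -10, -1)),
    primitive_mesh(round(runif(9, -5, 5), 2), c(0, 1, 2)))
}

# a random *legal* builder call chain; by construction it must validate
# clean (builder soundness)
random_builder_state <- function() {
  b <- mvs_builder()
  for (branch in seq_len(sample(1:3, 1))) {
    b <- mvs_at_root(b)
    is_map <- runif(1) < 0.15
    b <- mvs_download(b, sample(c("./model.cif", "./other.cif",
                                  "https://files.example.org/1abc.cif"), 1))
    if (is_map) {
      b <- mvs_parse(b, "map")
      b <- mvs_volume_isosurface(b, relative_isovalue = round(runif(1, 0.5, 3), 2))
      if (runif(1) < 0.5) b <- mvs_color(b, random_hex_color())
      next
    }
    b <- mvs_parse(b, sample(c("mmcif", "mmcif", "bcif", "pdb"), 1))
    mode <- sample(c("model", "assembly", "symmetry_mates"), 1,
                   prob = c(0.7, 0.2, 0.1))
    b <- switch(mode,
      model = mvs_structure(b, "model",
                            model_index = sample(0:2, 1)),
      assembly = mvs_structure(b, "assembly", assembly_id = "1"),
      symmetry_mates = mvs_structure(b, "symmetry_mates", radius = 5))
    if (runif(1) < 0.3) {
      b <- mvs_transform(b, rotation_about_axis(runif(3, -1, 1) + 1e-3,
                                                runif(1, -pi, pi)),
                         translation = runif(3, -20, 20))
    }
    for (comp in seq_len(sample(0:2, 1))) {
      b <- mvs_component(b, random_selector())
      if (runif(1) < 0.7) {
        b <- mvs_representation(b, sample(c("cartoon", "ball_and_stick",
                                            "spacefill", "surface"), 1))
        for (cl in seq_len(sample(0:2, 1))) {
          b <- if (runif(1) < 0.5) {
            mvs_color(b, random_hex_color())
          } else {
            mvs_color(b, random_hex_color(),
                      selector = random_selector())
          }
        }
        b <- mvs_up(b, 1)  # back to component
      }
      if (runif(1) < 0.3) b <- mvs_label(b, paste0("label-", comp))
      if (runif(1) < 0.3) b <- mvs_tooltip(b, paste0("tip-", comp))
      if (runif(1) < 0.2) b <- mvs_focus(b, radius_extent = runif(1, 0, 5))
      b <- mvs_up(b, 1)  # back to structure
    }
    if (runif(1) < 0.3) {
      for (k in seq_len(sample(1:2, 1))) {
        b <- mvs_primitive(b, random_primitive())
      }
    }
  }
  b <- mvs_at_root(b)
  if (runif(1) < 0.3) {
    b <- mvs_camera(b, target = runif(3, -5, 5),
                    position = runif(3, 20, 40), up = c(0, 1, 0))
  } else if (runif(1) < 0.2) {
    b <- mvs_focus(b, radius_factor = runif(1, 0.5, 2))
  }
  if (runif(1) < 0.25) {
    b <- mvs_primitive(b, random_primitive())
  }
  mvs_state(b, title = if (runif(1) < 0.5) "random scene" else NULL)
}

# a valid mid-sized fixture state used as the mutation target
mutation_fixture_state <- function() {
  make_example_state("superposition")
}

# single-field mutations, each guaranteed to break exactly one rule class
mutate_state <- function(state) {
  root <- state$root
  entries <- mvs_traverse(root)
  set_node <- function(root, path, f) {
    if (length(path) == 0L) return(f(root))
    root$children[[path[1]]] <- set_node(root$children[[path[1]]],
                                         path[-1], f)
    root
  }
  kind_of <- function(k) {
    idx <- which(vapply(entries, function(e) e$node$kind == k, logical(1)))
    entries[[sample(idx, 1)]]
  }
  choice <- sample(9, 1)
  new_root <- switch(choice,
    { # 1: rename a node to an unknown kind
      e <- entries[[sample(length(entries), 1)]]
      set_node(root, e$path, function(n) { n$kind <- "frobnicate"; n })
    },
    { # 2: graft a representation directly under root
      root$children <- c(root$children,
                         list(mvs_node("representation",
                                       list(type = "cartoon"))))
      root
    },
    { # 3: drop a required parameter
      e <- kind_of("parse")
      set_node(root, e$path, function(n) { n$params$format <- NULL; n })
    },
    { # 4: out-of-enum value
      e <- kind_of("parse")
      set_node(root, e$path, function(n) { n$params$format <- "xyz"; n })
    },
    { # 5: type mismatch
      e <- kind_of("download")
      set_node(root, e$path, function(n) { n$params$url <- 7; n })
    },
    { # 6: conflicting parameters on a model structure
      e <- kind_of("structure")
      set_node(root, e$path, function(n) {
        n$params$mode <- "model"
        n$params$assembly_id <- "1"
        n
      })
    },
    { # 7: malformed color
      e <- kind_of("color")
      set_node(root, e$path, function(n) { n$params$color <- "#ggg"; n })
    },
    { # 8: unknown parameter key
      e <- entries[[sample(length(entries), 1)]]
      set_node(root, e$path, function(n) { n$params$bogus_key <- 1; n })
    },
    { # 9: break the rotation matrix
      e <- kind_of("transform")
      set_node(root, e$path, function(n) {
        n$params$rotation <- as.double(c(1, 0, 0, 0, 1, 0, 0, 0, -1))
        n
      })
    })
  new_mvs_state(new_root, state$metadata)
}

random_fixture_spec <- function() {
  fixture_spec(n_chains = sample(1:3, 1),
               residues_per_chain = sample(2:5, 1),
               atoms_per_residue = sample(2:5, 1),
               chain_offset = c(sample(10:30, 1), sample(-5:5, 1), 0),
               include_water = runif(1) < 0.5,
               include_ligand = runif(1) < 0.5,
               seed = sample(1:10000, 1))
}
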