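# Independent oracles, written deliberately without reference to the
# package internals they check:
#  - naive_scan_state(): a rule-by-rule validity scanner (vs the
#    table-driven validator)
#  - brute_selector(): a plain row-predicate filter (vs resolve_selector)
#  - min_enclosing_sphere(): exact Welzl solver (vs the Ritter bound)
#  - enumerate_tree(): plain recursive enumeration (vs mvs_traverse)
# Also sourced by scripts/acceptance.R so both graded paths share them.

# ---- traversal oracle -------------------------------------------------

enumerate_tree <- function(node, path = integer(0)) {
  out <- list(list(path = path, node = node))
  for (i in seq_along(node$children)) {
    out <- c(out, enumerate_tree(node$children[[i]], c(path, i)))
  }
  out
}

# ---- naive validity scanner ------------------------------------------

# returns the number of rule violations found (0 == valid), using
# hard-coded if-chains rather than a schema table
naive_scan_state <- function(state) {
  errs <- 0L
  kinds <- c("root", "download", "parse", "structure", "component",
             "representation", "color", "label", "tooltip", "transform",
             "camera", "canvas", "focus", "volume", "volume_representation",
             "primitives", "primitive")
  md <- state$metadata
  if (!is.list(md) || !is.character(md$version) ||
      length(md$version) != 1L || !nzchar(md$version)) {
    errs <- errs + 1L
  }
  is_num <- function(v, n) is.numeric(v) && length(v) == n && all(is.finite(v))
  is_str <- function(v) is.character(v) && length(v) == 1L && !is.na(v)
  color_ok <- function(v) {
    is_str(v) && (grepl("^#[0-9a-fA-F]{6}$", v) || grepl("^#[0-9a-fA-F]{3}$", v) ||
                    v %in% grDevices::colors())
  }
  scan <- function(node, parent_kind) {
    if (!node$kind %in% kinds) {
      errs <<- errs + 1L
      return(invisible())
    }
    ok_parent <- switch(node$kind,
      root = is.null(parent_kind),
      download = identical(parent_kind, "root"),
      camera = identical(parent_kind, "root"),
      canvas = identical(parent_kind, "root"),
      focus = identical(parent_kind, "root") ||
        identical(parent_kind, "component"),
      primitives = identical(parent_kind, "root") ||
        identical(parent_kind, "structure"),
      parse = identical(parent_kind, "download"),
      structure = identical(parent_kind, "parse"),
      volume = identical(parent_kind, "parse"),
      component = identical(parent_kind, "structure"),
      transform = identical(parent_kind, "structure"),
      representation = identical(parent_kind, "component"),
      label = identical(parent_kind, "component"),
      tooltip = identical(parent_kind, "component"),
      color = identical(parent_kind, "representation") ||
        identical(parent_kind, "volume_representation"),
      volume_representation = identical(parent_kind, "volume"),
      primitive = identical(parent_kind, "primitives"),
      FALSE)
    if (!ok_parent) errs <<- errs + 1L
    p <- node$params
    if (node$kind == "download" && !(is_str(p$url) && nzchar(p$url))) {
      errs <<- errs + 1L
    }
    if (node$kind == "parse" &&
        !(is_str(p$format) && p$format %in% c("mmcif", "bcif", "pdb", "map"))) {
      errs <<- errs + 1L
    }
    if (node$kind == "structure") {
      if (!(is_str(p$mode) &&
            p$mode %in% c("model", "assembly", "symmetry", "symmetry_mates"))) {
        errs <<- errs + 1L
      } else {
        if (!is.null(p$assembly_id) && p$mode != "assembly") errs <<- errs + 1L
        if (!is.null(p$radius) && p$mode != "symmetry_mates") errs <<- errs + 1L
      }
      if (!is.null(p$model_index) &&
          !(is_num(p$model_index, 1) && p$model_index >= 0 &&
            p$model_index == floor(p$model_index))) {
        errs <<- errs + 1L
      }
    }
    if (node$kind == "component" && is.null(p$selector)) errs <<- errs + 1L
    if (node$kind == "component" && !is.null(p$selector)) {
      s <- p$selector
      sel_ok <- if (is.character(s)) {
        length(s) == 1L && s %in% c("all", "protein", "nucleic", "branched",
                                    "ligand", "ion", "water")
      } else {
        is.list(s) && length(s) >= 1L
      }
      if (!sel_ok) errs <<- errs + 1L
    }
    if (node$kind == "representation" &&
        !(is_str(p$type) && p$type %in% c("cartoon", "ball_and_stick",
                                          "spacefill", "surface"))) {
      errs <<- errs + 1L
    }
    if (node$kind == "color" && !color_ok(p$color)) errs <<- errs + 1L
    if (node$kind %in% c("label", "tooltip") &&
        !(is_str(p$text) && nzchar(p$text))) {
      errs <<- errs + 1L
    }
    if (node$kind == "transform") {
      if (!is_num(p$rotation, 9)) {
        errs <<- errs + 1L
      } else {
        m <- matrix(p$rotation, 3, byrow = TRUE)
        if (max(abs(t(m) %*% m - diag(3))) > 1e-6 || abs(det(m) - 1) > 1e-6) {
          errs <<- errs + 1L
        }
      }
      if (!is.null(p$translation) && !is_num(p$translation, 3)) {
        errs <<- errs + 1L
      }
    }
    if (node$kind == "camera") {
      if (!is_num(p$target, 3) || !is_num(p$position, 3) || !is_num(p$up, 3)) {
        errs <<- errs + 1L
      } else if (sqrt(sum((p$target - p$position)^2)) < 1e-12) {
        errs <<- errs + 1L
      }
    }
    if (node$kind == "volume_representation") {
      if (is.null(p$relative_isovalue) == is.null(p$absolute_isovalue)) {
        errs <<- errs + 1L
      }
      if (!identical(p$type, "isosurface")) errs <<- errs + 1L
    }
    if (node$kind == "primitive") {
      k <- p$kind
      if (!is_str(k) || !k %in% c("mesh", "lines", "sphere",
                                  "distance_measurement",
                                  "angle_measurement", "label")) {
        errs <<- errs + 1L
      } else {
        if (k == "sphere" &&
            !(is_num(p$radius, 1) && p$radius > 0 && is_num(p$center, 3))) {
          errs <<- errs + 1L
        }
        if (k == "mesh") {
          if (!is.numeric(p$vertices) || !is.numeric(p$indices) ||
              length(p$vertices) %% 3 != 0 || length(p$vertices) == 0 ||
              length(p$indices) %% 3 != 0 || length(p$indices) == 0 ||
              any(p$indices < 0) ||
              any(p$indices >= length(p$vertices) / 3)) {
            errs <<- errs + 1L
          }
        }
      }
      if (!is.null(p$opacity) &&
          !(is_num(p$opacity, 1) && p$opacity >= 0 && p$opacity <= 1)) {
        errs <<- errs + 1L
      }
      if (!is.null(p$color) && !color_ok(p$color)) errs <<- errs + 1L
    }
    # unknown parameter names (extension keys excepted)
    legal <- switch(node$kind,
      root = character(0),
      download = "url",
      parse = "format",
      structure = c("mode", "model_index", "assembly_id", "radius",
                    "ijk_min", "ijk_max"),
      component = "selector",
      representation = "type",
      color = c("color", "selector"),
      label = "text", tooltip = "text",
      transform = c("rotation", "translation"),
      camera = c("target", "position", "up"),
      canvas = "background_color",
      focus = c("direction", "up", "radius_factor", "radius_extent"),
      volume = "channel_id",
      volume_representation = c("type", "relative_isovalue",
                                "absolute_isovalue", "show_wireframe"),
      primitives = character(0),
      primitive = c("kind", "vertices", "indices", "points", "center",
                    "radius", "start", "end", "a", "b", "c", "position",
                    "text", "label_template", "color", "opacity", "dash"),
      character(0))
    pn <- names(p)
    if (is.null(pn)) pn <- character(0)
    extra <- setdiff(pn, legal)
    extra <- extra[!startsWith(extra, "x_")]
    errs <<- errs + length(extra)
    for (ch in node$children) scan(ch, node$kind)
  }
  scan(state$root, NULL)
  errs
}

# ---- brute-force selector filter -------------------------------------

brute_selector <- function(atoms, sel) {
  if (!is.null(sel$static)) {
    keep <- switch(sel$static,
      all = rep(TRUE, nrow(atoms)),
      protein = atoms$entity_type == "polymer_protein",
      nucleic = atoms$entity_type == "polymer_nucleic",
      branched = atoms$entity_type == "polymer_branched",
      ligand = atoms$entity_type == "non_polymer",
      ion = atoms$entity_type == "ion",
      water = atoms$entity_type == "water")
    return(sort(atoms$atom_index[keep]))
  }
  hits <- integer(0)
  for (row in seq_len(nrow(atoms))) {
    for (e in sel$expressions) {
      match_all <- TRUE
      for (f in names(e)) {
        v <- e[[f]]
        cell <- switch(f,
          beg_label_seq_id = , end_label_seq_id = atoms$label_seq_id[row],
          beg_auth_seq_id = , end_auth_seq_id = atoms$auth_seq_id[row],
          atoms[[f]][row])
        ok <- if (is.na(cell)) {
          FALSE
        } else if (f %in% c("beg_label_seq_id", "beg_auth_seq_id")) {
          cell >= v
        } else if (f %in% c("end_label_seq_id", "end_auth_seq_id")) {
          cell <= v
        } else if (f == "label_entity_id") {
          as.character(cell) == as.character(v)
        } else {
          cell == v
        }
        if (!ok) { match_all <- FALSE; break }
      }
      if (match_all) { hits <- c(hits, atoms$atom_index[row]); break }
    }
  }
  sort(unique(hits))
}

# ---- exact minimal enclosing sphere (Welzl) --------------------------

sphere_of_boundary <- function(R) {
  k <- length(R)
  if (k == 0L) return(list(center = c(0, 0, 0), radius = -1))
  if (k == 1L) return(list(center = R[[1]], radius = 0))
  p1 <- R[[1]]
  if (k == 2L) {
    return(list(center = (R[[1]] + R[[2]]) / 2,
                radius = sqrt(sum((R[[1]] - R[[2]])^2)) / 2))
  }
  A <- t(vapply(R[-1], function(p) 2 * (p - p1), numeric(3)))
  b <- vapply(R[-1], function(p) sum(p^2) - sum(p1^2), numeric(1))
  if (k == 3L) {
    # constrain to the plane of the 3 points
    nrm <- pracma_cross(R[[2]] - p1, R[[3]] - p1)
    A <- rbind(A, nrm)
    b <- c(b, sum(nrm * p1))
  }
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  list(center = as.double(ctr), radius = sqrt(sum((ctr - p1)^2)))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

min_enclosing_sphere <- function(points) {
  pts <- lapply(seq_len(nrow(points)), function(i) as.double(points[i, ]))
  welzl <- function(P, R) {
    if (length(P) == 0L || length(R) == 4L) {
      s <- sphere_of_boundary(R)
      if (is.null(s)) s <- list(center = c(0, 0, 0), radius = Inf)
      return(s)
    }
    p <- P[[1]]
    s <- welzl(P[-1], R)
    if (sqrt(sum((p - s$center)^2)) <= s$radius + 1e-9) return(s)
    welzl(P[-1], c(R, list(p)))
  }
  welzl(pts, list())
}
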