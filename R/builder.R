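# Fluent builder: a cursor-carrying context whose operations can only
# produce hierarchy-legal trees. Every operation validates its inputs and
# the cursor's kind *before* touching the tree, so a failed call leaves the
# context unchanged (strong exception safety comes free with R's value
# semantics). Operations return a new context with the cursor on the node
# just added, which makes base-pipe chains natural:
#
#   mvs_builder() |>
#     mvs_download("./model.cif") |> mvs_parse("mmcif") |>
#     mvs_structure("model") |> mvs_component(mvs_selector("protein")) |>
#     mvs_representation("cartoon") |> mvs_color("#4577b5")

.PARSE_FORMATS <- c("mmcif", "bcif", "pdb", "map")
.STRUCTURE_FORMATS <- c("mmcif", "bcif", "pdb")
.STRUCTURE_MODES <- c("model", "assembly", "symmetry", "symmetry_mates")
.REPRESENTATION_TYPES <- c("cartoon", "ball_and_stick", "spacefill", "surface")

#' Create a fresh scene builder
#'
#' @return An object of class `mvs_builder` holding the tree root and a
#'   cursor (the node new children attach to, initially the root).
#' @export
#' @examples
#' b <- mvs_builder()
#' b$root$kind
mvs_builder <- function() {
  structure(list(root = mvs_node("root"), cursor = integer(0)),
            class = "mvs_builder")
}

#' @export
print.mvs_builder <- function(x, ...) {
  cat("<mvs_builder> cursor at", cursor_node(x)$kind, "\n")
  print(x$root)
  invisible(x)
}

cursor_node <- function(ctx) {
  n <- ctx$root
  for (i in ctx$cursor) n <- n$children[[i]]
  n
}

modify_at <- function(node, path, f) {
  if (length(path) == 0L) return(f(node))
  node$children[[path[1]]] <- modify_at(node$children[[path[1]]],
                                        path[-1], f)
  node
}

stop_hierarchy <- function(op, have, want) {
  stop(structure(class = c("mvs_hierarchy_error", "error", "condition"),
                 list(message = paste0("`", op, "` is not legal here: cursor is at a '",
                                       have, "' node, expected ",
                                       paste0("'", want, "'", collapse = " or ")),
                      call = NULL)))
}

check_builder <- function(ctx) {
  if (!inherits(ctx, "mvs_builder")) {
    stop("first argument must be an mvs_builder context", call. = FALSE)
  }
  ctx
}

# append `child` under the cursor (which must be one of `allowed`) and
# descend onto it
builder_append <- function(ctx, child, allowed, op, descend = TRUE) {
  cur <- cursor_node(ctx)
  if (!cur$kind %in% allowed) stop_hierarchy(op, cur$kind, allowed)
  idx <- length(cur$children) + 1L
  ctx$root <- modify_at(ctx$root, ctx$cursor, function(n) {
    n$children[[idx]] <- child
    n
  })
  if (descend) ctx$cursor <- c(ctx$cursor, idx)
  ctx
}

#' Add a data-download node
#'
#' Records the source of structural (or volumetric) data: an absolute URL,
#' or a relative path resolved later against an MVSX archive. The library
#' never dereferences network URLs itself.
#'
#' @param ctx Builder context (cursor must be at the root).
#' @param url Non-empty URL string.
#' @return Updated builder, cursor on the new `download` node.
#' @export
mvs_download <- function(ctx, url) {
  check_builder(ctx)
  if (!is.character(url) || length(url) != 1L || !nzchar(url)) {
    stop("url must be a non-empty string", call. = FALSE)
  }
  builder_append(ctx, mvs_node("download", list(url = url)), "root",
                 "mvs_download")
}

#' Add a parse node declaring the data format
#'
#' @param ctx Builder context (cursor at a `download` node).
#' @param format One of `mmcif`, `bcif`, `pdb` (structures) or `map`
#'   (volumetric data).
#' @return Updated builder, cursor on the new `parse` node.
#' @export
mvs_parse <- function(ctx, format) {
  check_builder(ctx)
  if (!is.character(format) || length(format) != 1L ||
      !format %in% .PARSE_FORMATS) {
    stop("unknown format '", paste(format, collapse = ","),
         "'; legal formats: ", paste(.PARSE_FORMATS, collapse = ", "),
         call. = FALSE)
  }
  builder_append(ctx, mvs_node("parse", list(format = format)), "download",
                 "mvs_parse")
}

#' Add a structure node (asymmetric unit, assembly or symmetry expansion)
#'
#' @param ctx Builder context (cursor at a `parse` node of a structure
#'   format, i.e. not `map`).
#' @param mode One of `model` (asymmetric unit), `assembly`, `symmetry`,
#'   `symmetry_mates`.
#' @param assembly_id Assembly identifier; only legal with
#'   `mode = "assembly"`.
#' @param model_index 0-based model number (defaults to 0, the first
#'   model).
#' @param radius Expansion radius in Angstrom; only legal with
#'   `mode = "symmetry_mates"`.
#' @param ijk_min,ijk_max Integer 3-vectors bounding the unit-cell range;
#'   only legal with `mode = "symmetry"`.
#' @return Updated builder, cursor on the new `structure` node.
#' @export
mvs_structure <- function(ctx, mode = "model", assembly_id = NULL,
                          model_index = NULL, radius = NULL,
                          ijk_min = NULL, ijk_max = NULL) {
  check_builder(ctx)
  if (!is.character(mode) || length(mode) != 1L ||
      !mode %in% .STRUCTURE_MODES) {
    stop("unknown structure mode '", paste(mode, collapse = ","),
         "'; legal modes: ", paste(.STRUCTURE_MODES, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(assembly_id) && mode != "assembly") {
    stop("assembly_id is only legal with mode = \"assembly\"", call. = FALSE)
  }
  if (!is.null(radius) && mode != "symmetry_mates") {
    stop("radius is only legal with mode = \"symmetry_mates\"", call. = FALSE)
  }
  if ((!is.null(ijk_min) || !is.null(ijk_max)) && mode != "symmetry") {
    stop("ijk_min/ijk_max are only legal with mode = \"symmetry\"",
         call. = FALSE)
  }
  model_index <- model_index %||% 0
  if (!is.numeric(model_index) || length(model_index) != 1L ||
      model_index < 0 || model_index != floor(model_index)) {
    stop("model_index must be a non-negative integer", call. = FALSE)
  }
  cur <- cursor_node(ctx)
  if (cur$kind == "parse" && !identical(cur$params$format %in%
                                        .STRUCTURE_FORMATS, TRUE)) {
    stop_hierarchy("mvs_structure", paste0("parse[", cur$params$format, "]"),
                   "parse of a structure format (mmcif/bcif/pdb)")
  }
  params <- list(mode = mode, model_index = model_index,
                 assembly_id = assembly_id, radius = radius,
                 ijk_min = ijk_min, ijk_max = ijk_max)
  params <- params[!vapply(params, is.null, logical(1))]
  builder_append(ctx, mvs_node("structure", params), "parse",
                 "mvs_structure")
}

#' Route a map-format parse into the volume branch
#'
#' @param ctx Builder context (cursor at a `parse` node with
#'   `format = "map"`).
#' @param channel_id Optional channel identifier for multi-channel maps.
#' @return Updated builder, cursor on the new `volume` node.
#' @export
mvs_volume <- function(ctx, channel_id = NULL) {
  check_builder(ctx)
  cur <- cursor_node(ctx)
  if (cur$kind == "parse" && !identical(cur$params$format, "map")) {
    stop_hierarchy("mvs_volume", paste0("parse[", cur$params$format, "]"),
                   "parse of format map")
  }
  params <- if (is.null(channel_id)) list() else list(channel_id = channel_id)
  builder_append(ctx, mvs_node("volume", params), "parse", "mvs_volume")
}

#' Add a component (an atom selection)
#'
#' @param ctx Builder context (cursor at a `structure` node).
#' @param selector An [mvs_selector()], or a bare static name string.
#' @return Updated builder, cursor on the new `component` node.
#' @export
mvs_component <- function(ctx, selector) {
  check_builder(ctx)
  if (is.character(selector)) selector <- mvs_selector(static = selector)
  if (!inherits(selector, "mvs_selector")) {
    stop("selector must be an mvs_selector or a static component name",
         call. = FALSE)
  }
  builder_append(ctx,
                 mvs_node("component", list(selector = selector_to_param(selector))),
                 "structure", "mvs_component")
}

#' Add a visual representation to a component
#'
#' @param ctx Builder context (cursor at a `component` node).
#' @param type One of `cartoon`, `ball_and_stick`, `spacefill`, `surface`.
#' @return Updated builder, cursor on the new `representation` node.
#' @export
mvs_representation <- function(ctx, type) {
  check_builder(ctx)
  if (!is.character(type) || length(type) != 1L ||
      !type %in% .REPRESENTATION_TYPES) {
    stop("unknown representation type '", paste(type, collapse = ","),
         "'; supported types: ", paste(.REPRESENTATION_TYPES, collapse = ", "),
         call. = FALSE)
  }
  builder_append(ctx, mvs_node("representation", list(type = type)),
                 "component", "mvs_representation")
}

#' Color a representation (optionally restricted to a sub-selection)
#'
#' The color string is validated here but normalized to "#rrggbb" only at
#' serialization.
#'
#' @param ctx Builder context (cursor at a `representation` or
#'   `volume_representation` node).
#' @param color "#RRGGBB" / "#RGB" hex or an X11 color name.
#' @param selector Optional [mvs_selector()] restricting the color to part
#'   of the parent component; absent means the whole component.
#' @return Updated builder; the cursor *stays on the parent* so several
#'   color nodes can be chained onto one representation.
#' @export
mvs_color <- function(ctx, color, selector = NULL) {
  check_builder(ctx)
  if (!is_valid_color(color)) {
    stop("invalid color '", color,
         "' (expected #RRGGBB, #RGB, or an X11 color name)", call. = FALSE)
  }
  # store the canonical hex form so serialization is the identity on
  # builder output (hand-written trees are normalized at write time)
  params <- list(color = normalize_color(color))
  if (!is.null(selector)) {
    if (is.character(selector)) selector <- mvs_selector(static = selector)
    params$selector <- selector_to_param(selector)
  }
  builder_append(ctx, mvs_node("color", params),
                 c("representation", "volume_representation"), "mvs_color",
                 descend = FALSE)
}

#' Attach a rendered text label to a component
#' @param ctx Builder context (cursor at a `component` node).
#' @param text Non-empty label text.
#' @return Updated builder; cursor stays on the component.
#' @export
mvs_label <- function(ctx, text) {
  check_builder(ctx)
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("label text must be a non-empty string", call. = FALSE)
  }
  builder_append(ctx, mvs_node("label", list(text = text)), "component",
                 "mvs_label", descend = FALSE)
}

#' Attach hover-text (a tooltip) to a component
#' @inheritParams mvs_label
#' @return Updated builder; cursor stays on the component.
#' @export
mvs_tooltip <- function(ctx, text) {
  check_builder(ctx)
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("tooltip text must be a non-empty string", call. = FALSE)
  }
  builder_append(ctx, mvs_node("tooltip", list(text = text)), "component",
                 "mvs_tooltip", descend = FALSE)
}

#' Apply a rigid-body coordinate transform to a structure
#'
#' The canonical use is structural superposition: transform one structure
#' onto another with a precomputed rotation + translation. The rotation is
#' checked with [check_rotation()] (orthonormal, det +1, tolerance 1e-6);
#' reflections are rejected.
#'
#' @param ctx Builder context (cursor at a `structure` node).
#' @param rotation 3x3 matrix or length-9 row-major vector.
#' @param translation Length-3 vector in Angstrom (default no shift).
#' @return Updated builder; cursor stays on the structure so components
#'   can still be added after the transform.
#' @export
mvs_transform <- function(ctx, rotation, translation = c(0, 0, 0)) {
  check_builder(ctx)
  m <- as_matrix3(rotation)
  if (!check_rotation(m)) {
    stop("rotation is not a proper rotation matrix (orthonormal, det +1 ",
         "within 1e-6)", call. = FALSE)
  }
  translation <- as.double(translation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stop("translation must be a finite 3-vector", call. = FALSE)
  }
  builder_append(ctx,
                 mvs_node("transform",
                          list(rotation = as.double(t(m)),  # row-major flat
                               translation = translation)),
                 "structure", "mvs_transform", descend = FALSE)
}

#' Set an explicit camera for the scene
#'
#' @param ctx Builder context (cursor at the root; see [mvs_at_root()]).
#' @param target Length-3 look-at point (Angstrom).
#' @param position Length-3 camera position; must differ from `target`.
#' @param up Up vector; must not be parallel to `target - position`.
#' @return Updated builder; cursor stays at the root. A state may contain
#'   at most one camera node (a second one is a validation error).
#' @export
mvs_camera <- function(ctx, target, position, up = c(0, 1, 0)) {
  check_builder(ctx)
  target <- as_point3(target, "target")
  position <- as_point3(position, "position")
  up <- as_point3(up, "up")
  check_camera_geometry(target, position, up)
  builder_append(ctx,
                 mvs_node("camera", list(target = target, position = position,
                                         up = up)),
                 "root", "mvs_camera", descend = FALSE)
}

check_camera_geometry <- function(target, position, up) {
  view <- target - position
  if (sqrt(sum(view^2)) < 1e-12) {
    stop("camera position must differ from target", call. = FALSE)
  }
  view <- view / sqrt(sum(view^2))
  un <- sqrt(sum(up^2))
  if (un < 1e-12 || sqrt(sum((up / un - sum(up / un * view) * view)^2)) < 1e-9) {
    stop("up vector is parallel to the view direction", call. = FALSE)
  }
  invisible(TRUE)
}

#' Request automatic focus on a selection (or the whole scene)
#'
#' At interpretation time the camera is derived from the bounding sphere of
#' the focused selection via [camera_from_focus()].
#'
#' @param ctx Builder context (cursor at a `component` node, or at the
#'   root for whole-scene focus).
#' @param direction Optional view direction.
#' @param up Optional up vector.
#' @param radius_factor Optional positive multiplier on the focus radius.
#' @param radius_extent Optional additive radius margin (Angstrom, >= 0).
#' @return Updated builder; cursor stays on the parent.
#' @export
mvs_focus <- function(ctx, direction = NULL, up = NULL, radius_factor = NULL,
                      radius_extent = NULL) {
  check_builder(ctx)
  params <- list()
  if (!is.null(direction)) params$direction <- as_point3(direction, "direction")
  if (!is.null(up)) params$up <- as_point3(up, "up")
  if (!is.null(radius_factor)) {
    if (!is.numeric(radius_factor) || radius_factor <= 0) {
      stop("radius_factor must be positive", call. = FALSE)
    }
    params$radius_factor <- as.double(radius_factor)
  }
  if (!is.null(radius_extent)) {
    if (!is.numeric(radius_extent) || radius_extent < 0) {
      stop("radius_extent must be >= 0", call. = FALSE)
    }
    params$radius_extent <- as.double(radius_extent)
  }
  builder_append(ctx, mvs_node("focus", params), c("component", "root"),
                 "mvs_focus", descend = FALSE)
}

#' Add a geometrical primitive
#'
#' Primitives live in a `primitives` group node under the root or a
#' structure; the group is created on first use and reused afterwards. The
#' cursor ends on the group, so successive calls accumulate primitives.
#'
#' @param ctx Builder context (cursor at the root, a `structure` node, or
#'   an existing `primitives` group).
#' @param p An `mvs_primitive_spec` from one of the `primitive_*()`
#'   constructors.
#' @return Updated builder; cursor on the `primitives` group.
#' @export
#' @examples
#' mvs_builder() |>
#'   mvs_primitive(primitive_sphere(c(0, 0, 0), 1.5, color = "red"))
mvs_primitive <- function(ctx, p) {
  check_builder(ctx)
  if (!inherits(p, "mvs_primitive_spec")) {
    stop("p must be built with a primitive_*() constructor", call. = FALSE)
  }
  cur <- cursor_node(ctx)
  if (cur$kind %in% c("root", "structure")) {
    kinds <- vapply(cur$children, `[[`, character(1), "kind")
    at <- which(kinds == "primitives")
    if (length(at)) {
      ctx$cursor <- c(ctx$cursor, at[length(at)])
    } else {
      ctx <- builder_append(ctx, mvs_node("primitives"),
                            c("root", "structure"), "mvs_primitive")
    }
  }
  builder_append(ctx, mvs_node("primitive", unclass(p)), "primitives",
                 "mvs_primitive", descend = FALSE)
}

#' Add an isosurface rendering of a volume
#'
#' Exactly one of `relative_isovalue` (in sigma units of the map) or
#' `absolute_isovalue` (in map units) must be given. If the cursor is at a
#' map-format `parse` node, the intermediate `volume` node is created
#' automatically.
#'
#' @param ctx Builder context (cursor at a `volume` node or a map-format
#'   `parse` node).
#' @param relative_isovalue Contour level relative to the map sigma.
#' @param absolute_isovalue Contour level in absolute map units.
#' @param show_wireframe Optional flag for wireframe rendering.
#' @return Updated builder, cursor on the new `volume_representation`.
#' @export
mvs_volume_isosurface <- function(ctx, relative_isovalue = NULL,
                                  absolute_isovalue = NULL,
                                  show_wireframe = NULL) {
  check_builder(ctx)
  if (is.null(relative_isovalue) == is.null(absolute_isovalue)) {
    stop("give exactly one of relative_isovalue or absolute_isovalue",
         call. = FALSE)
  }
  if (!is.null(show_wireframe) && !is.logical(show_wireframe)) {
    stop("show_wireframe must be logical", call. = FALSE)
  }
  cur <- cursor_node(ctx)
  if (cur$kind == "parse") ctx <- mvs_volume(ctx)
  params <- list(type = "isosurface",
                 relative_isovalue = relative_isovalue,
                 absolute_isovalue = absolute_isovalue,
                 show_wireframe = show_wireframe)
  params <- params[!vapply(params, is.null, logical(1))]
  builder_append(ctx, mvs_node("volume_representation", params), "volume",
                 "mvs_volume_isosurface")
}

#' Move the builder cursor back to the root
#'
#' A pure cursor move (no tree edit), so operations whose precondition is
#' "cursor at root" ([mvs_download()], [mvs_camera()]) can follow a deep
#' fluent chain.
#'
#' @param ctx Builder context.
#' @return Updated builder with cursor at the root.
#' @export
mvs_at_root <- function(ctx) {
  check_builder(ctx)
  ctx$cursor <- integer(0)
  ctx
}

#' Move the builder cursor up `n` levels
#' @param ctx Builder context.
#' @param n Number of levels (capped at the root).
#' @return Updated builder.
#' @export
mvs_up <- function(ctx, n = 1L) {
  check_builder(ctx)
  keep <- max(0L, length(ctx$cursor) - as.integer(n))
  ctx$cursor <- ctx$cursor[seq_len(keep)]
  ctx
}

#' Finalize a builder into a state
#'
#' Validates the tree ([assert_valid()]); construction is refused with an
#' aggregated issue listing if validation fails.
#'
#' @param ctx Builder context.
#' @param title,description Optional metadata strings.
#' @param description_format `"markdown"` or `"plaintext"` if given.
#' @param timestamp Optional ISO-8601 string (omitted by default so equal
#'   trees serialize to identical bytes).
#' @return An `mvs_state`.
#' @export
mvs_state <- function(ctx, title = NULL, description = NULL,
                      description_format = NULL, timestamp = NULL) {
  check_builder(ctx)
  metadata <- list(version = MVS_VERSION, title = title,
                   description = description,
                   description_format = description_format,
                   timestamp = timestamp)
  metadata <- metadata[!vapply(metadata, is.null, logical(1))]
  assert_valid(new_mvs_state(ctx$root, metadata))
}

#' Compose states into a snapshot list (a visual narrative)
#'
#' @param states Non-empty list of `mvs_state` objects, in narrative
#'   order.
#' @param keys Optional character vector of per-snapshot keys.
#' @param linger_duration_ms,transition_duration_ms Non-negative timing
#'   metadata, recycled across snapshots.
#' @param title,description Optional narrative-level metadata.
#' @return An `mvs_snapshot_list`.
#' @export
mvs_snapshots <- function(states, keys = NULL, linger_duration_ms = 1000,
                          transition_duration_ms = 250, title = NULL,
                          description = NULL) {
  if (!is.list(states) || length(states) == 0L) {
    stop("snapshot list must contain at least one state", call. = FALSE)
  }
  if (!all(vapply(states, inherits, logical(1), "mvs_state"))) {
    stop("states must all be mvs_state objects", call. = FALSE)
  }
  n <- length(states)
  linger <- rep_len(as.double(linger_duration_ms), n)
  trans <- rep_len(as.double(transition_duration_ms), n)
  if (any(linger < 0) || any(trans < 0)) {
    stop("durations must be non-negative", call. = FALSE)
  }
  if (!is.null(keys)) stopifnot(is.character(keys), length(keys) == n)
  snaps <- lapply(seq_len(n), function(i) {
    list(state = states[[i]],
         key = if (is.null(keys)) NULL else keys[[i]],
         linger_duration_ms = linger[[i]],
         transition_duration_ms = trans[[i]])
  })
  metadata <- list(version = MVS_VERSION, title = title,
                   description = description)
  metadata <- metadata[!vapply(metadata, is.null, logical(1))]
  structure(list(snapshots = snaps, metadata = metadata),
            class = "mvs_snapshot_list")
}
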