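# Table-driven validation of arbitrary trees (built, hand-written or
# deserialized). Issues are data, never exceptions: validate_state() does
# not throw on malformed content. Normalization (e.g. color names -> hex)
# never happens here; validators that rewrite are untestable.

# The normative parent -> permitted-children table of this implementation.
# `focus` is permitted under root (whole-scene focus) as well as under
# component.
.HIERARCHY <- list(
  root = c("download", "camera", "canvas", "primitives", "focus"),
  download = "parse",
  parse = c("structure", "volume"),
  structure = c("component", "transform", "primitives"),
  component = c("representation", "label", "tooltip", "focus"),
  representation = "color",
  color = character(0),
  label = character(0),
  tooltip = character(0),
  transform = character(0),
  camera = character(0),
  canvas = character(0),
  focus = character(0),
  volume = "volume_representation",
  volume_representation = "color",
  primitives = "primitive",
  primitive = character(0)
)

#' The hierarchy table of permitted parent/child node kinds
#' @return Named list: for each kind, the character vector of kinds it may
#'   contain as children.
#' @export
hierarchy_table <- function() .HIERARCHY

# Parameter schema entries: type is one of string, number, integer,
# boolean, vector3, matrix3, numbers (any-length numeric), color,
# selector, endpoint. `check` on a kind runs cross-parameter rules.
ps <- function(type, required = FALSE, enum = NULL, min = NULL, max = NULL,
               nonempty = FALSE) {
  list(type = type, required = required, enum = enum, min = min, max = max,
       nonempty = nonempty)
}

.PARAM_SCHEMA <- list(
  root = list(),
  download = list(url = ps("string", required = TRUE, nonempty = TRUE)),
  parse = list(format = ps("string", required = TRUE,
                           enum = .PARSE_FORMATS)),
  structure = list(
    mode = ps("string", required = TRUE, enum = .STRUCTURE_MODES),
    model_index = ps("integer", min = 0),
    assembly_id = ps("string"),
    radius = ps("number", min = 0),
    ijk_min = ps("vector3"),
    ijk_max = ps("vector3")
  ),
  component = list(selector = ps("selector", required = TRUE)),
  representation = list(type = ps("string", required = TRUE,
                                  enum = .REPRESENTATION_TYPES)),
  color = list(color = ps("color", required = TRUE),
               selector = ps("selector")),
  label = list(text = ps("string", required = TRUE, nonempty = TRUE)),
  tooltip = list(text = ps("string", required = TRUE, nonempty = TRUE)),
  transform = list(rotation = ps("matrix3", required = TRUE),
                   translation = ps("vector3")),
  camera = list(target = ps("vector3", required = TRUE),
                position = ps("vector3", required = TRUE),
                up = ps("vector3", required = TRUE)),
  canvas = list(background_color = ps("color")),
  focus = list(direction = ps("vector3"), up = ps("vector3"),
               radius_factor = ps("number", min = 0),
               radius_extent = ps("number", min = 0)),
  volume = list(channel_id = ps("string")),
  volume_representation = list(
    type = ps("string", required = TRUE, enum = "isosurface"),
    relative_isovalue = ps("number"),
    absolute_isovalue = ps("number"),
    show_wireframe = ps("boolean")
  ),
  primitives = list(),
  primitive = list(
    kind = ps("string", required = TRUE,
              enum = c("mesh", "lines", "sphere", "distance_measurement",
                       "angle_measurement", "label")),
    vertices = ps("numbers"), indices = ps("numbers"),
    points = ps("numbers"),
    center = ps("vector3"), radius = ps("number"),
    start = ps("endpoint"), end = ps("endpoint"),
    a = ps("endpoint"), b = ps("endpoint"), c = ps("endpoint"),
    position = ps("vector3"), text = ps("string", nonempty = TRUE),
    label_template = ps("string"),
    color = ps("color"), opacity = ps("number", min = 0, max = 1),
    dash = ps("string", enum = c("dashed", "dotted"))
  )
)

issue <- function(path, breadcrumb, severity, code, message) {
  list(path = path, breadcrumb = breadcrumb, severity = severity,
       code = code, message = message)
}

issues_df <- function(lst) {
  df <- data.frame(
    breadcrumb = vapply(lst, `[[`, character(1), "breadcrumb"),
    severity = vapply(lst, `[[`, character(1), "severity"),
    code = vapply(lst, `[[`, character(1), "code"),
    message = vapply(lst, `[[`, character(1), "message"),
    stringsAsFactors = FALSE
  )
  df$path <- lapply(lst, `[[`, "path")
  class(df) <- c("mvs_issues", "data.frame")
  df
}

#' @export
print.mvs_issues <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No validation issues.\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %s at %s: %s\n", x$severity[i], x$code[i],
                x$breadcrumb[i], x$message[i]))
  }
  invisible(x)
}

type_ok <- function(v, type) {
  switch(type,
    string = is.character(v) && length(v) == 1L && !is.na(v),
    number = is.numeric(v) && length(v) == 1L && is.finite(v),
    integer = is.numeric(v) && length(v) == 1L && is.finite(v) &&
      v == floor(v),
    boolean = is.logical(v) && length(v) == 1L && !is.na(v),
    vector3 = is.numeric(v) && length(v) == 3L && all(is.finite(v)),
    matrix3 = is.numeric(v) && length(v) == 9L && all(is.finite(v)),
    numbers = is.numeric(v) && length(v) >= 1L && all(is.finite(v)),
    color = is.character(v) && length(v) == 1L && is_valid_color(v),
    selector = selector_param_ok(v),
    endpoint = endpoint_param_ok(v),
    FALSE)
}

selector_param_ok <- function(v) {
  if (is.character(v) && length(v) == 1L) return(v %in% .STATIC_COMPONENTS)
  if (is.list(v) && length(v) >= 1L) {
    ok <- tryCatch({
      lapply(v, check_selector_expression)
      TRUE
    }, error = function(e) FALSE)
    return(ok)
  }
  FALSE
}

endpoint_param_ok <- function(v) {
  if (is.numeric(v) && length(v) == 3L && all(is.finite(v))) return(TRUE)
  if (is.list(v) && identical(names(v), "selector")) {
    return(selector_param_ok(v$selector))
  }
  FALSE
}

#' Validate a parameter map against one node kind's schema
#'
#' Unknown keys are errors, except keys prefixed `"x_"` (the extension-key
#' convention), which are warnings; `lenient = TRUE` downgrades all
#' unknown-key errors to warnings.
#'
#' @param kind Node kind.
#' @param params Named list of parameters (possibly malformed; never
#'   throws).
#' @param lenient Downgrade unknown-parameter errors to warnings.
#' @return An `mvs_issues` data frame (path column empty).
#' @export
#' @examples
#' check_params("parse", list(format = "mmcif"))   # clean
#' check_params("parse", list(format = 7))         # type mismatch
check_params <- function(kind, params, lenient = FALSE) {
  issues_df(check_params_list(kind, params, integer(0), "", lenient))
}

check_params_list <- function(kind, params, path, crumb, lenient = FALSE) {
  schema <- .PARAM_SCHEMA[[kind]]
  if (is.null(schema)) return(list())  # unknown kind reported elsewhere
  out <- list()
  add <- function(severity, code, msg) {
    out[[length(out) + 1L]] <<- issue(path, crumb, severity, code, msg)
  }
  if (!is.list(params)) {
    add("error", "params.malformed", "params is not a map")
    return(out)
  }
  nms <- names(params)
  if (length(params) && (is.null(nms) || any(!nzchar(nms)))) {
    add("error", "params.malformed", "params map has unnamed entries")
    return(out)
  }
  for (key in setdiff(nms, names(schema))) {
    if (startsWith(key, "x_")) {
      add("warning", "params.unknown_extension_key",
          paste0("extension key '", key, "' is ignored by this schema"))
    } else {
      add(if (lenient) "warning" else "error", "params.unknown_key",
          paste0("unknown parameter '", key, "' for kind '", kind, "'"))
    }
  }
  for (key in names(schema)) {
    def <- schema[[key]]
    if (!key %in% nms) {
      if (def$required) {
        add("error", "params.missing_required",
            paste0("missing required parameter '", key, "'"))
      }
      next
    }
    v <- params[[key]]
    if (!type_ok(v, def$type)) {
      add("error", "params.type_mismatch",
          paste0("parameter '", key, "' is not a valid ", def$type))
      next
    }
    if (!is.null(def$enum) && !v %in% def$enum) {
      add("error", "params.out_of_enum",
          paste0("parameter '", key, "' must be one of: ",
                 paste(def$enum, collapse = ", ")))
      next
    }
    if (def$nonempty && is.character(v) && !nzchar(v)) {
      add("error", "params.invalid_value",
          paste0("parameter '", key, "' must be non-empty"))
    }
    if (!is.null(def$min) && is.numeric(v) && any(v < def$min)) {
      add("error", "params.out_of_bounds",
          paste0("parameter '", key, "' below minimum ", def$min))
    }
    if (!is.null(def$max) && is.numeric(v) && any(v > def$max)) {
      add("error", "params.out_of_bounds",
          paste0("parameter '", key, "' above maximum ", def$max))
    }
  }
  c(out, check_kind_rules(kind, params, path, crumb))
}

# cross-parameter rules per kind (conflicts, geometry invariants, payloads)
check_kind_rules <- function(kind, params, path, crumb) {
  out <- list()
  add <- function(severity, code, msg) {
    out[[length(out) + 1L]] <<- issue(path, crumb, severity, code, msg)
  }
  has <- function(k) !is.null(params[[k]])
  num1 <- function(k) is.numeric(params[[k]]) && length(params[[k]]) == 1L
  if (kind == "structure" && is.character(params$mode)) {
    if (has("assembly_id") && !identical(params$mode, "assembly")) {
      add("error", "params.conflict",
          "assembly_id is only legal with mode = \"assembly\"")
    }
    if (has("radius") && !identical(params$mode, "symmetry_mates")) {
      add("error", "params.conflict",
          "radius is only legal with mode = \"symmetry_mates\"")
    }
    if ((has("ijk_min") || has("ijk_max")) &&
        !identical(params$mode, "symmetry")) {
      add("error", "params.conflict",
          "ijk_min/ijk_max are only legal with mode = \"symmetry\"")
    }
  }
  if (kind == "volume_representation") {
    if (has("relative_isovalue") == has("absolute_isovalue")) {
      add("error", "params.conflict",
          "exactly one of relative_isovalue / absolute_isovalue must be set")
    }
  }
  if (kind == "transform" && is.numeric(params$rotation) &&
      length(params$rotation) == 9L) {
    if (!check_rotation(params$rotation)) {
      add("error", "params.invalid_value",
          "rotation is not a proper rotation matrix (orthonormal, det +1)")
    }
  }
  if (kind == "camera" &&
      all(vapply(c("target", "position", "up"),
                 function(k) is.numeric(params[[k]]) &&
                   length(params[[k]]) == 3L, logical(1)))) {
    ok <- tryCatch({
      check_camera_geometry(params$target, params$position, params$up)
      TRUE
    }, error = function(e) {
      add("error", "params.invalid_value", conditionMessage(e))
      FALSE
    })
  }
  if (kind == "focus" && has("radius_factor") && num1("radius_factor") &&
      params$radius_factor <= 0) {
    add("error", "params.out_of_bounds", "radius_factor must be positive")
  }
  if (kind == "primitive" && is.character(params$kind) &&
      length(params$kind) == 1L) {
    out <- c(out, check_primitive_payload(params, path, crumb))
  }
  out
}

check_primitive_payload <- function(params, path, crumb) {
  out <- list()
  add <- function(code, msg) {
    out[[length(out) + 1L]] <- issue(path, crumb, "error", code, msg)
  }
  need <- function(keys) {
    miss <- keys[!keys %in% names(params)]
    for (k in miss) {
      add("params.missing_required",
          paste0("primitive kind '", params$kind,
                 "' requires parameter '", k, "'"))
    }
    length(miss) == 0L
  }
  switch(params$kind,
    mesh = if (need(c("vertices", "indices")) &&
               is.numeric(params$vertices) && is.numeric(params$indices)) {
      nv <- length(params$vertices)
      ni <- length(params$indices)
      if (nv %% 3L != 0L || nv == 0L) {
        add("params.invalid_value", "mesh vertices length not divisible by 3")
      } else if (ni %% 3L != 0L || ni == 0L) {
        add("params.invalid_value", "mesh indices length not divisible by 3")
      } else if (any(params$indices != floor(params$indices)) ||
                 any(params$indices < 0) ||
                 any(params$indices >= nv / 3L)) {
        add("params.out_of_bounds", "mesh triangle index out of range")
      }
    },
    lines = if (need("points") && is.numeric(params$points)) {
      if (length(params$points) %% 6L != 0L || length(params$points) == 0L) {
        add("params.invalid_value",
            "lines points length not divisible by 6 (xyz pairs)")
      }
    },
    sphere = if (need(c("center", "radius")) && is.numeric(params$radius) &&
                 length(params$radius) == 1L) {
      if (!is.finite(params$radius) || params$radius <= 0) {
        add("params.out_of_bounds", "sphere radius must be positive")
      }
    },
    distance_measurement = {
      need(c("start", "end"))
      if (is.character(params$label_template)) {
        tryCatch(render_label_template(params$label_template, 0),
                 error = function(e) add("params.invalid_value",
                                         conditionMessage(e)))
      }
    },
    angle_measurement = {
      need(c("a", "b", "c"))
      if (is.character(params$label_template)) {
        tryCatch(render_label_template(params$label_template, 0),
                 error = function(e) add("params.invalid_value",
                                         conditionMessage(e)))
      }
    },
    label = need(c("position", "text")),
    NULL)
  out
}

breadcrumb_of <- function(root, path) {
  parts <- "root"
  n <- root
  for (i in path) {
    n <- n$children[[i]]
    parts <- c(parts, sprintf("%s[%d]", n$kind, i - 1L))  # 0-based display
  }
  paste(parts, collapse = "/")
}

#' Validate a state or snapshot list
#'
#' Walks the tree in pre-order and reports every structural or parametric
#' problem as a deterministic, complete list of issues: unknown kinds,
#' hierarchy violations, missing/unknown/ill-typed parameters, conflicting
#' parameters, and missing `metadata.version`. An empty result (no rows)
#' means the document is schema-conformant. Never throws on malformed
#' content.
#'
#' @param state An `mvs_state` or `mvs_snapshot_list` (possibly malformed
#'   below the root).
#' @param lenient Downgrade unknown-parameter errors to warnings.
#' @return An `mvs_issues` data frame, in traversal order.
#' @export
validate_state <- function(state, lenient = FALSE) {
  if (inherits(state, "mvs_snapshot_list")) {
    out <- check_metadata(state$metadata)
    if (length(state$snapshots) == 0L) {
      out <- c(out, list(issue(integer(0), "root", "error",
                               "snapshots.empty",
                               "snapshot list must be non-empty")))
    }
    for (i in seq_along(state$snapshots)) {
      s <- state$snapshots[[i]]
      sub <- validate_state(s$state, lenient = lenient)
      if (nrow(sub)) {
        for (j in seq_len(nrow(sub))) {
          out[[length(out) + 1L]] <- issue(
            sub$path[[j]],
            sprintf("snapshot[%d]/%s", i - 1L, sub$breadcrumb[j]),
            sub$severity[j], sub$code[j], sub$message[j])
        }
      }
      for (k in c("linger_duration_ms", "transition_duration_ms")) {
        v <- s[[k]]
        if (!is.numeric(v) || length(v) != 1L || v < 0) {
          out[[length(out) + 1L]] <- issue(
            integer(0), sprintf("snapshot[%d]", i - 1L), "error",
            "snapshots.bad_duration",
            paste0(k, " must be a non-negative number"))
        }
      }
    }
    return(issues_df(out))
  }
  if (!inherits(state, "mvs_state")) {
    return(issues_df(list(issue(integer(0), "root", "error",
                                "state.malformed",
                                "not an mvs_state or mvs_snapshot_list"))))
  }
  out <- check_metadata(state$metadata)
  root <- state$root
  if (!inherits(root, "mvs_node")) {
    out[[length(out) + 1L]] <- issue(integer(0), "root", "error",
                                     "state.malformed",
                                     "state root is not a node")
    return(issues_df(out))
  }
  if (!identical(root$kind, "root")) {
    out[[length(out) + 1L]] <- issue(integer(0), "root", "error",
                                     "hierarchy.bad_root",
                                     paste0("top node must be kind 'root', got '",
                                            root$kind, "'"))
  }
  entries <- mvs_traverse(root)
  for (e in entries) {
    node <- e$node
    crumb <- breadcrumb_of(root, e$path)
    if (!node$kind %in% .MVS_KINDS) {
      out[[length(out) + 1L]] <- issue(e$path, crumb, "error",
                                       "kind.unknown",
                                       paste0("unknown node kind '",
                                              node$kind, "'"))
      next
    }
    if (length(e$path) > 0L) {
      parent <- node_at_path(root, e$path[-length(e$path)])
      if (parent$kind %in% .MVS_KINDS &&
          !node$kind %in% .HIERARCHY[[parent$kind]]) {
        out[[length(out) + 1L]] <- issue(e$path, crumb, "error",
                                         "hierarchy.illegal_parent",
                                         paste0("'", node$kind,
                                                "' is not a legal child of '",
                                                parent$kind, "'"))
      }
    }
    out <- c(out, check_params_list(node$kind, node$params, e$path, crumb,
                                    lenient))
    if (!is.null(node$ref) &&
        (!is.character(node$ref) || length(node$ref) != 1L)) {
      out[[length(out) + 1L]] <- issue(e$path, crumb, "error",
                                       "node.bad_ref",
                                       "ref must be a single string")
    }
  }
  cams <- sum(vapply(entries, function(e) identical(e$node$kind, "camera"),
                     logical(1)))
  if (cams > 1L) {
    out[[length(out) + 1L]] <- issue(integer(0), "root", "error",
                                     "hierarchy.multiple_cameras",
                                     "a state may contain at most one camera node")
  }
  issues_df(out)
}

node_at_path <- function(root, path) {
  n <- root
  for (i in path) n <- n$children[[i]]
  n
}

check_metadata <- function(metadata) {
  out <- list()
  add <- function(severity, code, msg) {
    out[[length(out) + 1L]] <<- issue(integer(0), "metadata", severity, code,
                                      msg)
  }
  if (!is.list(metadata)) {
    add("error", "metadata.malformed", "metadata is not a map")
    return(out)
  }
  v <- metadata$version
  if (is.null(v) || !is.character(v) || length(v) != 1L || !nzchar(v)) {
    add("error", "metadata.version_missing",
        "metadata.version is missing or not a string")
  } else {
    sup <- parse_version(MVS_VERSION)
    got <- parse_version(v)
    if (is.null(got)) {
      add("error", "metadata.bad_version",
          paste0("unparseable version '", v, "'"))
    } else if (got[1] == sup[1] && got[2] > sup[2]) {
      add("warning", "metadata.newer_minor_version",
          paste0("document minor version ", v,
                 " is newer than supported ", MVS_VERSION))
    }
  }
  if (!is.null(metadata$description_format) &&
      !identical(metadata$description_format, "markdown") &&
      !identical(metadata$description_format, "plaintext")) {
    add("error", "metadata.bad_description_format",
        "description_format must be markdown or plaintext")
  }
  for (k in c("title", "description", "timestamp")) {
    if (!is.null(metadata[[k]]) &&
        (!is.character(metadata[[k]]) || length(metadata[[k]]) != 1L)) {
      add("error", "metadata.bad_field",
          paste0("metadata.", k, " must be a single string"))
    }
  }
  out
}

parse_version <- function(v) {
  if (!grepl("^[0-9]+\\.[0-9]+$", v)) return(NULL)
  as.integer(strsplit(v, ".", fixed = TRUE)[[1]])
}

#' Assert that a state is valid, returning it unchanged
#'
#' Passes the state through when it has no error-severity issues
#' (warnings are tolerated); otherwise raises one aggregated failure
#' listing every issue.
#'
#' @param state An `mvs_state` or `mvs_snapshot_list`.
#' @param lenient See [validate_state()].
#' @return The input, unchanged.
#' @export
assert_valid <- function(state, lenient = FALSE) {
  iss <- validate_state(state, lenient = lenient)
  errs <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    msg <- paste0("state failed validation with ", nrow(errs), " issue(s):\n",
                  paste(sprintf("  [%s] %s: %s", errs$code, errs$breadcrumb,
                                errs$message), collapse = "\n"))
    stop(structure(class = c("mvs_validation_error", "error", "condition"),
                   list(message = msg, call = NULL, issues = iss)))
  }
  state
}

#' Serialize validation issues as JSON lines
#'
#' One JSON object per line with keys `path`, `severity`, `code`,
#' `message` — the machine-readable output of the CLI `validate` command.
#'
#' @param issues An `mvs_issues` data frame.
#' @return Character vector, one JSON object per issue.
#' @export
issues_to_json_lines <- function(issues) {
  if (nrow(issues) == 0L) return(character(0))
  vapply(seq_len(nrow(issues)), function(i) {
    jsonlite::toJSON(list(path = issues$breadcrumb[i],
                          severity = issues$severity[i],
                          code = issues$code[i],
                          message = issues$message[i]),
                     auto_unbox = TRUE)
  }, character(1))
}
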