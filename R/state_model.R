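# Scene-tree model: node kinds, the tree data structure, generic tree ops.

#' Supported schema version of MVSJ documents written by this package
#' @keywords internal
MVS_VERSION <- "1.0"

.MVS_KINDS <- c(
  "root", "download", "parse", "structure", "component", "representation",
  "color", "label", "tooltip", "transform", "camera", "canvas", "focus",
  "volume", "volume_representation", "primitives", "primitive"
)

#' Node kinds of the scene-description vocabulary
#'
#' The closed set of node kinds a scene tree may contain. Unknown kind
#' strings are representable (so that deserialized documents can be
#' validated rather than rejected at parse time) but always fail
#' validation.
#'
#' @return Character vector of kind names.
#' @export
#' @examples
#' node_kinds()
node_kinds <- function() .MVS_KINDS

#' Construct a scene-tree node
#'
#' Low-level constructor. No parameter legality is enforced here; that is
#' the job of [validate_state()]. Child order is significant and preserved
#' by every operation in the package (later siblings may paint over earlier
#' ones in a renderer, matching JSON array semantics).
#'
#' @param kind Node kind string (see [node_kinds()]); unknown strings are
#'   allowed and flagged at validation time.
#' @param params Named list of node parameters (scalars, vectors, nested
#'   lists). Values are normalized to a canonical in-memory form so that
#'   serialization round trips are exact.
#' @param children List of child nodes, in order.
#' @param ref Optional string tag for cross-referencing the node.
#' @param custom Optional named list preserved verbatim through all
#'   transformations (forward-compatibility escape hatch).
#' @return An object of class `mvs_node`.
#' @export
#' @examples
#' n <- mvs_node("download", params = list(url = "./model.cif"))
#' n$kind
mvs_node <- function(kind, params = list(), children = list(), ref = NULL,
                     custom = NULL) {
  stopifnot(is.character(kind), length(kind) == 1L, !is.na(kind))
  if (!is.list(params)) stop("params must be a list", call. = FALSE)
  if (!is.list(children)) stop("children must be a list", call. = FALSE)
  if (!is.null(ref)) stopifnot(is.character(ref), length(ref) == 1L)
  node <- list(
    kind = kind,
    params = normalize_value(params),
    children = children,
    ref = ref,
    custom = if (is.null(custom)) NULL else normalize_value(custom)
  )
  class(node) <- "mvs_node"
  node
}

# Canonical in-memory form for parameter values:
#  - numerics (incl. integers) -> double vectors, names stripped
#  - unnamed lists of same-typed scalars -> atomic vectors
#  - named lists -> objects (NULL entries dropped, each value normalized)
# This makes builder-constructed and JSON-parsed trees structurally
# identical, so tree_equal() can compare with identical().
normalize_value <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "mvs_selector")) x <- unclass(x)
  if (is.atomic(x)) {
    x <- unname(x)
    if (is.numeric(x)) return(as.double(x))
    return(x)
  }
  if (is.list(x)) {
    nms <- names(x)
    named <- !is.null(nms) && length(x) > 0L && all(nzchar(nms))
    if (named) {
      x <- x[!vapply(x, is.null, logical(1))]
      out <- lapply(x, normalize_value)
      return(out[order(names(out))])
    }
    out <- lapply(x, normalize_value)
    if (length(out) > 0L &&
        all(vapply(out, function(e) is.atomic(e) && length(e) == 1L &&
                     !is.null(e), logical(1)))) {
      types <- vapply(out, function(e) class(e)[1], character(1))
      if (length(unique(types)) == 1L && types[1] %in%
          c("numeric", "character", "logical")) {
        return(unlist(out, use.names = FALSE))
      }
    }
    return(out)
  }
  stop("unsupported parameter value of class ", class(x)[1], call. = FALSE)
}

.MAX_TREE_DEPTH <- 512L

#' Depth-first pre-order traversal of a scene tree
#'
#' Visits the parent before its children; every node appears exactly once.
#' The path of the root is the empty integer vector; other paths are
#' 1-based child-index sequences.
#'
#' @param root An `mvs_node`.
#' @return A list of `list(path = <integer vector>, node = <mvs_node>)`
#'   entries in visit order.
#' @export
#' @examples
#' b <- mvs_builder() |> mvs_download("./m.cif") |> mvs_parse("mmcif")
#' length(mvs_traverse(b$root))
mvs_traverse <- function(root) {
  if (!inherits(root, "mvs_node")) stop("root must be an mvs_node", call. = FALSE)
  acc <- vector("list", 64L)
  count <- 0L
  push <- function(path, node) {
    count <<- count + 1L
    if (count > length(acc)) length(acc) <<- 2L * count
    acc[[count]] <<- list(path = path, node = node)
  }
  walk <- function(node, path, depth) {
    if (depth > .MAX_TREE_DEPTH) {
      stop("tree exceeds maximum depth ", .MAX_TREE_DEPTH,
           " (cycle or runaway nesting) at node kind '", node$kind, "'",
           call. = FALSE)
    }
    push(path, node)
    kids <- node$children
    for (i in seq_along(kids)) walk(kids[[i]], c(path, i), depth + 1L)
  }
  walk(root, integer(0), 1L)
  acc[seq_len(count)]
}

#' Deep structural equality of two scene trees
#'
#' Order-sensitive for children and for list-valued parameters,
#' order-insensitive for map keys; floating-point parameters are compared
#' exactly (no tolerance).
#'
#' @param a,b `mvs_node` objects.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equal <- function(a, b) {
  if (!inherits(a, "mvs_node") || !inherits(b, "mvs_node")) return(FALSE)
  if (!identical(a$kind, b$kind)) return(FALSE)
  if (!identical(a$ref, b$ref)) return(FALSE)
  if (!value_equal(a$params, b$params)) return(FALSE)
  if (!value_equal(a$custom, b$custom)) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  for (i in seq_along(a$children)) {
    if (!tree_equal(a$children[[i]], b$children[[i]])) return(FALSE)
  }
  TRUE
}

# exact deep equality on normalized parameter values
value_equal <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is.atomic(a) && is.atomic(b)) return(identical(a, b))
  if (is.list(a) && is.list(b)) {
    na <- names(a); nb <- names(b)
    named_a <- !is.null(na) && all(nzchar(na))
    named_b <- !is.null(nb) && all(nzchar(nb))
    if (named_a != named_b) return(FALSE)
    if (named_a) {
      if (!setequal(na, nb)) return(FALSE)
      for (k in na) if (!value_equal(a[[k]], b[[k]])) return(FALSE)
      return(TRUE)
    }
    if (length(a) != length(b)) return(FALSE)
    for (i in seq_along(a)) if (!value_equal(a[[i]], b[[i]])) return(FALSE)
    return(TRUE)
  }
  FALSE
}

#' Find all nodes of a given kind
#'
#' @param root An `mvs_node`.
#' @param kind Kind name to match.
#' @return List of matching `mvs_node`s in pre-order.
#' @export
find_nodes <- function(root, kind) {
  hits <- Filter(function(e) identical(e$node$kind, kind), mvs_traverse(root))
  lapply(hits, `[[`, "node")
}

#' @export
print.mvs_node <- function(x, ...) {
  entries <- mvs_traverse(x)
  cat("<mvs_node> tree with", length(entries), "node(s)\n")
  for (e in entries) {
    pad <- strrep("  ", length(e$path))
    p <- e$node$params
    ptxt <- if (length(p)) paste0(" {", paste(names(p), collapse = ", "), "}") else ""
    cat(pad, "- ", e$node$kind, ptxt, "\n", sep = "")
  }
  invisible(x)
}

#' Construct a state (a complete scene description)
#'
#' Usually produced by [mvs_state()] from a builder; this constructor is
#' for programmatic assembly of already-built trees.
#'
#' @param root Root `mvs_node` (kind `"root"`).
#' @param metadata Named list; `version` is required for a valid state.
#' @return An object of class `mvs_state`.
#' @export
new_mvs_state <- function(root, metadata = list(version = MVS_VERSION)) {
  stopifnot(inherits(root, "mvs_node"))
  structure(list(root = root, metadata = metadata), class = "mvs_state")
}

#' @export
print.mvs_state <- function(x, ...) {
  cat("<mvs_state> version", x$metadata$version %||% "<missing>", "\n")
  if (!is.null(x$metadata$title)) cat("  title:", x$metadata$title, "\n")
  kinds <- vapply(mvs_traverse(x$root), function(e) e$node$kind, character(1))
  tab <- table(kinds)
  cat("  nodes:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = " "), "\n")
  invisible(x)
}

#' @export
print.mvs_snapshot_list <- function(x, ...) {
  cat("<mvs_snapshot_list> with", length(x$snapshots), "snapshot(s)\n")
  for (i in seq_along(x$snapshots)) {
    s <- x$snapshots[[i]]
    cat(sprintf("  [%d] key=%s linger=%dms transition=%dms\n", i,
                s$key %||% "<none>", as.integer(s$linger_duration_ms),
                as.integer(s$transition_duration_ms)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
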