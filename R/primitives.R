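# Geometrical primitive payloads: meshes, lines, spheres, measurement
# primitives and free-standing labels. Constructors validate the payload
# invariants eagerly, so a primitive object is well-formed by construction.

new_primitive <- function(kind, payload, color = NULL, opacity = NULL,
                          dash = NULL) {
  if (!is.null(color)) {
    if (!is_valid_color(color)) {
      stop("invalid primitive color '", color, "'", call. = FALSE)
    }
    color <- normalize_color(color)
  }
  if (!is.null(opacity)) {
    if (!is.numeric(opacity) || length(opacity) != 1L ||
        opacity < 0 || opacity > 1) {
      stop("opacity must be a number in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(dash)) {
    if (!is.character(dash) || !dash %in% c("dashed", "dotted")) {
      stop("dash must be \"dashed\" or \"dotted\"", call. = FALSE)
    }
  }
  p <- c(list(kind = kind), payload,
         list(color = color, opacity = opacity, dash = dash))
  p <- p[!vapply(p, is.null, logical(1))]
  structure(p, class = "mvs_primitive_spec")
}

as_point3 <- function(x, what) {
  x <- as.double(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop(what, " must be a finite 3-vector", call. = FALSE)
  }
  x
}

# measurement endpoints may be literal points or selectors (resolved to the
# selection centroid at interpretation time)
as_endpoint <- function(x, what) {
  if (inherits(x, "mvs_selector")) {
    return(list(selector = selector_to_param(x)))
  }
  as_point3(x, what)
}

#' Triangle-mesh primitive
#'
#' @param vertices Numeric vector of length 3n (flat xyz triplets).
#' @param indices Integer vector of length 3m, 0-based vertex indices.
#' @param color,opacity Optional style.
#' @return An `mvs_primitive_spec` for [mvs_primitive()].
#' @export
primitive_mesh <- function(vertices, indices, color = NULL, opacity = NULL) {
  vertices <- as.double(vertices)
  indices <- as.double(indices)
  if (length(vertices) == 0L || length(vertices) %% 3L != 0L) {
    stop("vertices must be a non-empty flat xyz array (length divisible by 3)",
         call. = FALSE)
  }
  if (length(indices) == 0L || length(indices) %% 3L != 0L) {
    stop("indices must come in triangles (length divisible by 3)",
         call. = FALSE)
  }
  nvert <- length(vertices) / 3L
  if (any(indices != floor(indices)) || any(indices < 0) ||
      any(indices >= nvert)) {
    stop("triangle index out of range [0, ", nvert - 1, "]", call. = FALSE)
  }
  new_primitive("mesh", list(vertices = vertices, indices = indices),
                color = color, opacity = opacity)
}

#' Line-segment primitive (pairs of points)
#'
#' @param points Numeric vector of length 6k: flat xyz pairs, one pair per
#'   segment.
#' @param color,opacity,dash Optional style; `dash` is `"dashed"` or
#'   `"dotted"`.
#' @return An `mvs_primitive_spec`.
#' @export
primitive_lines <- function(points, color = NULL, opacity = NULL,
                            dash = NULL) {
  points <- as.double(points)
  if (length(points) == 0L || length(points) %% 6L != 0L) {
    stop("points must be flat xyz pairs (length divisible by 6)",
         call. = FALSE)
  }
  new_primitive("lines", list(points = points), color = color,
                opacity = opacity, dash = dash)
}

#' Sphere primitive
#' @param center Length-3 center (Angstrom).
#' @param radius Positive radius (Angstrom).
#' @param color,opacity Optional style.
#' @return An `mvs_primitive_spec`.
#' @export
primitive_sphere <- function(center, radius, color = NULL, opacity = NULL) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("sphere radius must be a positive number", call. = FALSE)
  }
  new_primitive("sphere",
                list(center = as_point3(center, "center"),
                     radius = as.double(radius)),
                color = color, opacity = opacity)
}

#' Distance-measurement primitive
#'
#' Endpoints are literal 3-vectors or [mvs_selector()]s (resolved to the
#' selection centroid at interpretation time). The label template may
#' contain one `{{distance}}` placeholder; crosslink-style dotted rendering
#' comes from `dash = "dotted"`.
#'
#' @param start,end Endpoints: length-3 numeric or `mvs_selector`.
#' @param label_template Template string (default `"{{distance}} A"`).
#' @param color,opacity,dash Optional style.
#' @return An `mvs_primitive_spec`.
#' @export
#' @examples
#' primitive_distance(c(0, 0, 0), c(3, 4, 0), dash = "dotted")
primitive_distance <- function(start, end, label_template = "{{distance}} A",
                               color = NULL, opacity = NULL, dash = NULL) {
  render_label_template(label_template, 0)  # reject unknown placeholders now
  new_primitive("distance_measurement",
                list(start = as_endpoint(start, "start"),
                     end = as_endpoint(end, "end"),
                     label_template = label_template),
                color = color, opacity = opacity, dash = dash)
}

#' Angle-measurement primitive
#'
#' @param a,b,c Points (or selectors); `b` is the vertex.
#' @param label_template Template with one optional `{{angle}}`
#'   placeholder.
#' @param color,opacity Optional style.
#' @return An `mvs_primitive_spec`.
#' @export
primitive_angle <- function(a, b, c, label_template = "{{angle}} deg",
                            color = NULL, opacity = NULL) {
  render_label_template(label_template, 0)
  new_primitive("angle_measurement",
                list(a = as_endpoint(a, "a"), b = as_endpoint(b, "b"),
                     c = as_endpoint(c, "c"),
                     label_template = label_template),
                color = color, opacity = opacity)
}

#' Free-standing 3D text label primitive
#' @param position Length-3 anchor point.
#' @param text Non-empty label text.
#' @param color,opacity Optional style.
#' @return An `mvs_primitive_spec`.
#' @export
primitive_label <- function(position, text, color = NULL, opacity = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("label text must be a non-empty string", call. = FALSE)
  }
  new_primitive("label",
                list(position = as_point3(position, "position"), text = text),
                color = color, opacity = opacity)
}
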