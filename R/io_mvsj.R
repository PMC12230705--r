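# MVSJ (JSON) document I/O and the URL-fragment codec.
#
# Serialization is canonical: sorted keys, 2-space indent, shortest
# round-trip numbers, color names normalized to hex. Equal trees therefore
# produce identical bytes, and write -> read -> write is a byte fixed
# point. Readers must not rely on canonical input; read_mvsj accepts any
# strict-JSON MVSJ document.

# kind-specific color-bearing parameters normalized at serialization only
normalize_tree_colors <- function(node) {
  for (key in c("color", "background_color")) {
    if (is.character(node$params[[key]]) && is_valid_color(node$params[[key]])) {
      node$params[[key]] <- normalize_color(node$params[[key]])
    }
  }
  node$children <- lapply(node$children, normalize_tree_colors)
  node
}

node_to_json <- function(node) {
  out <- list(kind = node$kind)
  if (length(node$params)) out$params <- node$params
  if (length(node$children)) out$children <- lapply(node$children,
                                                    node_to_json)
  if (!is.null(node$ref)) out$ref <- node$ref
  if (!is.null(node$custom) && length(node$custom)) out$custom <- node$custom
  out
}

json_to_node <- function(j) {
  if (!is.list(j)) {
    # retained for validation rather than dropped
    return(mvs_node("<malformed>"))
  }
  kind <- j$kind
  if (!is.character(kind) || length(kind) != 1L) kind <- "<missing-kind>"
  params <- j$params
  if (!is.list(params)) params <- list()
  children <- j$children
  if (!is.list(children)) children <- list()
  mvs_node(kind,
           params = params,
           children = lapply(children, json_to_node),
           ref = if (is.character(j$ref) && length(j$ref) == 1L) j$ref else NULL,
           custom = if (is.list(j$custom)) j$custom else NULL)
}

#' Serialize a state or snapshot list to canonical MVSJ text
#'
#' The document is validated first ([assert_valid()]); serialization of an
#' invalid state is refused. Output is canonical (sorted keys, 2-space
#' indent, shortest round-trip numbers, colors normalized to lowercase
#' hex), so equal trees serialize to identical bytes.
#'
#' @param x An `mvs_state` or `mvs_snapshot_list`.
#' @return A single UTF-8 string of JSON text.
#' @export
#' @examples
#' s <- mvs_builder() |> mvs_state()
#' cat(write_mvsj(s))
write_mvsj <- function(x) {
  assert_valid(x)
  if (inherits(x, "mvs_state")) {
    doc <- list(kind = "single",
                metadata = x$metadata,
                root = node_to_json(normalize_tree_colors(x$root)))
  } else if (inherits(x, "mvs_snapshot_list")) {
    snaps <- lapply(x$snapshots, function(s) {
      entry <- list(
        metadata = s$state$metadata,
        root = node_to_json(normalize_tree_colors(s$state$root)),
        linger_duration_ms = as.double(s$linger_duration_ms),
        transition_duration_ms = as.double(s$transition_duration_ms))
      if (!is.null(s$key)) entry$key <- s$key
      entry
    })
    doc <- list(kind = "multiple", metadata = x$metadata, snapshots = snaps)
  } else {
    stop("x must be an mvs_state or mvs_snapshot_list", call. = FALSE)
  }
  json_emit(doc)
}

read_error <- function(code, msg) {
  stop(structure(class = c("mvs_read_error", "error", "condition"),
                 list(message = paste0(code, ": ", msg), call = NULL,
                      code = code)))
}

#' Parse MVSJ text into a state or snapshot list
#'
#' Faithful inverse of [write_mvsj()]: `tree_equal(read_mvsj(write_mvsj(s))$root,
#' s$root)` holds for any valid state. Malformed *nodes* are retained (so
#' that [validate_state()] can report them precisely); malformed
#' *documents* (not JSON, missing `kind`/`metadata`, unsupported major
#' version) raise an `mvs_read_error`.
#'
#' @param text MVSJ JSON text (single string).
#' @return An `mvs_state` or `mvs_snapshot_list`.
#' @export
read_mvsj <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) read_error("mvsj.bad_json",
                                                 conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$kind)) {
    read_error("mvsj.missing_kind",
               "document has no top-level \"kind\" (single or multiple)")
  }
  if (!is.list(doc$metadata)) {
    read_error("mvsj.missing_metadata", "document has no metadata object")
  }
  v <- doc$metadata$version
  if (is.character(v) && length(v) == 1L) {
    got <- parse_version(v)
    sup <- parse_version(MVS_VERSION)
    if (!is.null(got) && got[1] > sup[1]) {
      read_error("mvsj.unsupported_version",
                 paste0("document major version ", v,
                        " exceeds supported ", MVS_VERSION))
    }
  }
  if (identical(doc$kind, "single")) {
    if (is.null(doc$root)) read_error("mvsj.missing_root",
                                      "single-state document has no root")
    return(new_mvs_state(json_to_node(doc$root),
                         metadata = normalize_metadata(doc$metadata)))
  }
  if (identical(doc$kind, "multiple")) {
    snaps <- doc$snapshots
    if (!is.list(snaps)) read_error("mvsj.missing_snapshots",
                                    "multiple-state document has no snapshots")
    snapshots <- lapply(snaps, function(s) {
      list(state = new_mvs_state(json_to_node(s$root),
                                 metadata = normalize_metadata(
                                   if (is.list(s$metadata)) s$metadata
                                   else doc$metadata)),
           key = if (is.character(s$key) && length(s$key) == 1L) s$key else NULL,
           linger_duration_ms = as.double(s$linger_duration_ms %||% 0),
           transition_duration_ms = as.double(s$transition_duration_ms %||% 0))
    })
    return(structure(list(snapshots = snapshots,
                          metadata = normalize_metadata(doc$metadata)),
                     class = "mvs_snapshot_list"))
  }
  read_error("mvsj.unknown_kind",
             paste0("unknown top-level kind '", doc$kind, "'"))
}

normalize_metadata <- function(m) {
  m <- m[!vapply(m, is.null, logical(1))]
  lapply(m, function(v) {
    if (is.numeric(v)) as.double(v) else v
  })
}

#' Encode a state for URL embedding
#'
#' The fragment is `"mvs:"` followed by unpadded base64url of the
#' gzip-compressed canonical MVSJ bytes. The encoding is this
#' implementation's choice; the standard states the capability (embedding
#' a state in a browser URL), not the codec.
#'
#' @param x An `mvs_state` or `mvs_snapshot_list`.
#' @return A single fragment string.
#' @export
#' @examples
#' s <- mvs_builder() |> mvs_state()
#' substr(encode_url_fragment(s), 1, 4)
encode_url_fragment <- function(x) {
  bytes <- charToRaw(write_mvsj(x))
  b64 <- jsonlite::base64url_enc(memCompress(bytes, type = "gzip"))
  paste0("mvs:", gsub("[\r\n]", "", b64))  # the encoder wraps long lines
}

#' Decode a URL fragment back into a state
#'
#' Inverse of [encode_url_fragment()]; `decode_url_fragment(encode_url_fragment(s))`
#' reproduces a tree equal to `s`.
#'
#' @param fragment Fragment string starting with `"mvs:"`.
#' @return An `mvs_state` or `mvs_snapshot_list`.
#' @export
decode_url_fragment <- function(fragment) {
  if (!is.character(fragment) || length(fragment) != 1L ||
      !nzchar(fragment)) {
    read_error("mvsurl.empty", "empty URL fragment")
  }
  if (!startsWith(fragment, "mvs:")) {
    read_error("mvsurl.bad_prefix", "URL fragment must start with \"mvs:\"")
  }
  payload <- substring(fragment, 5L)
  if (!nzchar(payload)) read_error("mvsurl.empty", "empty payload")
  bytes <- tryCatch(
    memDecompress(jsonlite::base64url_dec(payload), type = "gzip"),
    error = function(e) read_error("mvsurl.corrupt",
                                   paste0("cannot decode fragment: ",
                                          conditionMessage(e))))
  read_mvsj(rawToChar(bytes))
}
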