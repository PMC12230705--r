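# MVSX archives: a ZIP container with "index.mvsj" at the root plus the
# asset files (mmCIF etc.) that the state references by relative URL.

# relative URLs are the ones an archive must satisfy; absolute URLs and
# data: URIs pass through untouched (the library never dereferences them)
is_relative_url <- function(url) {
  !grepl("^[A-Za-z][A-Za-z0-9+.-]*://", url) && !startsWith(url, "/") &&
    !startsWith(url, "data:")
}

# "./model.cif" and "model.cif" address the same archive member
normalize_rel_url <- function(url) sub("^\\./", "", url)

state_download_urls <- function(x) {
  roots <- if (inherits(x, "mvs_state")) {
    list(x$root)
  } else {
    lapply(x$snapshots, function(s) s$state$root)
  }
  urls <- character(0)
  for (r in roots) {
    for (n in find_nodes(r, "download")) {
      if (is.character(n$params$url)) urls <- c(urls, n$params$url)
    }
  }
  unique(urls)
}

#' Pack a state and its assets into an MVSX archive
#'
#' The archive is a ZIP whose first member is `index.mvsj` (the canonical
#' MVSJ serialization of `x`), followed by the assets in sorted path
#' order. Member timestamps are fixed, so identical inputs produce
#' identical archive bytes on every run and platform.
#'
#' Every relative URL referenced by a `download` node must have a matching
#' asset; absolute URLs (e.g. `https://...`) are left untouched.
#'
#' @param x An `mvs_state` or `mvs_snapshot_list`.
#' @param assets Named list mapping relative paths (as referenced in the
#'   state, with or without a leading `"./"`) to raw vectors or character
#'   content.
#' @return Raw vector of archive bytes.
#' @export
#' @examples
#' s <- mvs_builder() |> mvs_download("./m.cif") |> mvs_parse("mmcif") |>
#'   mvs_structure() |> mvs_component("all") |>
#'   mvs_representation("cartoon") |> mvs_state()
#' arc <- pack_mvsx(s, assets = list("./m.cif" = "data_x\n"))
pack_mvsx <- function(x, assets = list()) {
  index <- write_mvsj(x)  # validates
  if (length(assets)) {
    if (is.null(names(assets)) || any(!nzchar(names(assets)))) {
      stop("assets must be a named list of relative paths", call. = FALSE)
    }
    names(assets) <- vapply(names(assets), normalize_rel_url, character(1))
    for (nm in names(assets)) check_member_path(nm)
  }
  rel <- Filter(is_relative_url, state_download_urls(x))
  need <- vapply(rel, normalize_rel_url, character(1))
  missing <- rel[!need %in% names(assets)]
  if (length(missing)) {
    stop("missing asset(s) for relative URL(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("index.mvsj" %in% names(assets)) {
    stop("asset path 'index.mvsj' collides with the archive index",
         call. = FALSE)
  }
  ordered <- assets[order(names(assets), method = "radix")]
  files <- c(list(index.mvsj = charToRaw(index)), ordered)
  zip_build(files)
}

#' Unpack an MVSX archive
#'
#' @param bytes Raw vector of archive bytes (or a file path to read).
#' @return List with elements `state` (`mvs_state` or
#'   `mvs_snapshot_list`), `assets` (named list of raw vectors, keyed by
#'   member path), and `audit` (data frame of the state's relative URL
#'   references and whether each resolves to a member).
#' @export
unpack_mvsx <- function(bytes) {
  if (is.character(bytes) && length(bytes) == 1L) {
    bytes <- readBin(bytes, "raw", n = file.size(bytes))
  }
  members <- zip_extract(bytes)
  if (!"index.mvsj" %in% names(members)) {
    read_error("mvsx.no_index", "archive has no index.mvsj member")
  }
  state <- read_mvsj(rawToChar(members[["index.mvsj"]]))
  assets <- members[setdiff(names(members), "index.mvsj")]
  rel <- Filter(is_relative_url, state_download_urls(state))
  audit <- data.frame(
    url = rel,
    member = vapply(rel, normalize_rel_url, character(1)),
    resolved = vapply(rel, function(u) {
      normalize_rel_url(u) %in% names(assets)
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(state = state, assets = assets, audit = audit)
}
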