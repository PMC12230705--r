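# Selector resolution against an atom table, plus the opt-in semantic
# audit of a state against loaded structures.

#' Resolve a selector to atom indices
#'
#' Static components select by entity type (`ligand` means non-polymer
#' entities excluding water and single-atom ions). Expression lists are
#' resolved as the union over expressions, each expression the conjunction
#' of its set fields; `beg_*`/`end_*` ranges are inclusive. `label_*` and
#' `auth_*` fields match only the scheme that was set — there is no
#' fallback aliasing between the two mmCIF numbering schemes.
#'
#' @param atoms An `mvs_atoms` table from [read_mmcif_atoms()].
#' @param sel An [mvs_selector()] (or a static name string).
#' @return Ascending, duplicate-free integer vector of 0-based
#'   `atom_index` values. Empty selections are legal and return
#'   `integer(0)`.
#' @export
resolve_selector <- function(atoms, sel) {
  stopifnot(inherits(atoms, "data.frame"))
  if (is.character(sel)) sel <- mvs_selector(static = sel)
  if (!inherits(sel, "mvs_selector")) {
    stop("sel must be an mvs_selector", call. = FALSE)
  }
  if (!is.null(sel$static)) {
    mask <- switch(sel$static,
      all = rep(TRUE, nrow(atoms)),
      protein = atoms$entity_type == "polymer_protein",
      nucleic = atoms$entity_type == "polymer_nucleic",
      branched = atoms$entity_type == "polymer_branched",
      ligand = atoms$entity_type == "non_polymer",
      ion = atoms$entity_type == "ion",
      water = atoms$entity_type == "water")
    return(sort(atoms$atom_index[mask]))
  }
  mask <- rep(FALSE, nrow(atoms))
  for (e in sel$expressions) {
    mask <- mask | expression_mask(atoms, e)
  }
  sort(unique(atoms$atom_index[mask]))
}

expression_mask <- function(atoms, e) {
  m <- rep(TRUE, nrow(atoms))
  eq_chr <- function(colv, val) !is.na(colv) & colv == val
  eq_num <- function(colv, val) !is.na(colv) & colv == val
  for (f in names(e)) {
    v <- e[[f]]
    m <- m & switch(f,
      label_entity_id = eq_chr(atoms$label_entity_id, as.character(v)),
      label_asym_id = eq_chr(atoms$label_asym_id, v),
      auth_asym_id = eq_chr(atoms$auth_asym_id, v),
      label_seq_id = eq_num(atoms$label_seq_id, v),
      auth_seq_id = eq_num(atoms$auth_seq_id, v),
      pdbx_PDB_ins_code = eq_chr(atoms$pdbx_PDB_ins_code, v),
      beg_label_seq_id = !is.na(atoms$label_seq_id) & atoms$label_seq_id >= v,
      end_label_seq_id = !is.na(atoms$label_seq_id) & atoms$label_seq_id <= v,
      beg_auth_seq_id = !is.na(atoms$auth_seq_id) & atoms$auth_seq_id >= v,
      end_auth_seq_id = !is.na(atoms$auth_seq_id) & atoms$auth_seq_id <= v,
      label_atom_id = eq_chr(atoms$label_atom_id, v),
      auth_atom_id = eq_chr(atoms$auth_atom_id, v),
      type_symbol = eq_chr(atoms$type_symbol, v),
      atom_id = eq_num(atoms$atom_id, v),
      atom_index = eq_num(atoms$atom_index, v),
      stop("unknown selector field '", f, "'", call. = FALSE))
  }
  m
}

#' Bounding sphere of a selection
#'
#' @param atoms An `mvs_atoms` table.
#' @param indices Non-empty 0-based `atom_index` vector (as returned by
#'   [resolve_selector()]).
#' @return An `mvs_sphere` (see [bounding_sphere()]).
#' @export
component_sphere <- function(atoms, indices) {
  if (length(indices) == 0L) {
    stop("cannot focus an empty selection", call. = FALSE)
  }
  rows <- match(indices, atoms$atom_index)
  if (anyNA(rows)) stop("atom index not present in table", call. = FALSE)
  bounding_sphere(cbind(atoms$x[rows], atoms$y[rows], atoms$z[rows]))
}

selection_centroid <- function(atoms, indices) {
  rows <- match(indices, atoms$atom_index)
  c(mean(atoms$x[rows]), mean(atoms$y[rows]), mean(atoms$z[rows]))
}

#' Audit a state against loaded structures
#'
#' The semantic lint that plain validation deliberately does not do:
#' resolves every component's selector against the referenced structure,
#' reports per-component atom counts, warns on empty selections, and
#' computes distances for selector-based distance primitives (using the
#' centroid of each endpoint selection). Only asymmetric-unit coordinates
#' are audited; assembly and symmetry expansion parameters are carried by
#' the state but not expanded here.
#'
#' @param state An `mvs_state` (snapshot lists: audit each snapshot's
#'   state separately).
#' @param structures Named list mapping download URLs to `mvs_atoms`
#'   tables. Every structure-format download URL must be present; map
#'   (volume) and unsupported-format references are reported in
#'   `references` instead of resolved.
#' @return List of class `mvs_audit` with data frames `components`
#'   (url, breadcrumb, selector, atom_count), `references` (url, format,
#'   status), `distances` (breadcrumb, distance, label), and `warnings`
#'   (code, message).
#' @export
audit_state_against_structures <- function(state, structures = list()) {
  stopifnot(inherits(state, "mvs_state"))
  comp_rows <- list()
  ref_rows <- list()
  warn_rows <- list()
  dist_rows <- list()
  first_atoms <- NULL
  first_url <- NULL
  warn <- function(code, message) {
    warn_rows[[length(warn_rows) + 1L]] <<- list(code = code,
                                                 message = message)
  }
  entries <- mvs_traverse(state$root)
  for (e in entries) {
    if (e$node$kind != "download") next
    url <- e$node$params$url
    for (pnode in e$node$children) {
      if (!identical(pnode$kind, "parse")) next
      fmt <- pnode$params$format
      if (identical(fmt, "map")) {
        ref_rows[[length(ref_rows) + 1L]] <- list(
          url = url, format = "map",
          status = if (is_relative_url(url)) "unresolved" else
            "external_by_design")
        next
      }
      if (!identical(fmt, "mmcif")) {
        ref_rows[[length(ref_rows) + 1L]] <- list(
          url = url, format = fmt %||% "<missing>",
          status = "unsupported_format")
        warn("unsupported_format",
             paste0("resolver reads mmCIF only; cannot audit '", url,
                    "' (", fmt, ")"))
        next
      }
      if (!url %in% names(structures)) {
        stop("no structure supplied for URL '", url, "'", call. = FALSE)
      }
      atoms <- structures[[url]]
      ref_rows[[length(ref_rows) + 1L]] <- list(url = url, format = "mmcif",
                                                status = "resolved")
      for (snode in pnode$children) {
        if (!identical(snode$kind, "structure")) next
        for (cnode in snode$children) {
          if (identical(cnode$kind, "component")) {
            sel <- tryCatch(param_to_selector(cnode$params$selector),
                            error = function(err) NULL)
            if (is.null(sel)) {
              warn("bad_selector", paste0("malformed selector under ", url))
              next
            }
            idx <- resolve_selector(atoms, sel)
            desc <- if (!is.null(sel$static)) sel$static else
              paste0(length(sel$expressions), " expression(s)")
            comp_rows[[length(comp_rows) + 1L]] <- list(
              url = url, selector = desc, atom_count = length(idx))
            if (length(idx) == 0L) {
              warn("empty_selection",
                   paste0("component selector '", desc, "' matches no atoms",
                          " in '", url, "'"))
            }
          }
        }
      }
      if (is.null(first_atoms)) {
        first_atoms <- atoms
        first_url <- url
      }
    }
  }
  # distance primitives: literal endpoints always resolve; selector
  # endpoints resolve to centroids against the first loaded structure
  for (prim in find_nodes(state$root, "primitive")) {
    if (!identical(prim$params$kind, "distance_measurement")) next
    ends <- lapply(list(prim$params$start, prim$params$end), function(p) {
      if (is.numeric(p) && length(p) == 3L) return(p)
      if (is.list(p) && !is.null(p$selector) && !is.null(first_atoms)) {
        sel <- param_to_selector(p$selector)
        idx <- resolve_selector(first_atoms, sel)
        if (length(idx) == 0L) return(NULL)
        return(selection_centroid(first_atoms, idx))
      }
      NULL
    })
    if (any(vapply(ends, is.null, logical(1)))) {
      if (!is.null(first_atoms)) {
        warn("empty_selection",
             "distance primitive endpoint selector matches no atoms")
      }
      next
    }
    d <- measure_distance(ends[[1]], ends[[2]])
    lbl <- if (is.character(prim$params$label_template)) {
      render_label_template(prim$params$label_template, d)
    } else {
      NA_character_
    }
    dist_rows[[length(dist_rows) + 1L]] <- list(
      url = first_url %||% NA_character_, distance = d, label = lbl)
  }
  to_df <- function(rows, cols) {
    if (!length(rows)) {
      return(stats::setNames(
        as.data.frame(rep(list(character(0)), length(cols))), cols))
    }
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    components = to_df(comp_rows, c("url", "selector", "atom_count")),
    references = to_df(ref_rows, c("url", "format", "status")),
    distances = to_df(dist_rows, c("url", "distance", "label")),
    warnings = to_df(warn_rows, c("code", "message"))
  ), class = "mvs_audit")
}

#' @export
print.mvs_audit <- function(x, ...) {
  cat("<mvs_audit>\n")
  cat(" references:\n")
  if (nrow(x$references)) print.data.frame(x$references) else cat("  none\n")
  cat(" components:\n")
  if (nrow(x$components)) print.data.frame(x$components) else cat("  none\n")
  if (nrow(x$distances)) {
    cat(" distances:\n")
    print.data.frame(x$distances)
  }
  if (nrow(x$warnings)) {
    cat(" warnings:\n")
    print.data.frame(x$warnings)
  }
  invisible(x)
}
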