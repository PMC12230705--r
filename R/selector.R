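# Atom selectors: either a predefined (static) component name or a list of
# mmCIF-field match expressions. Expression semantics: fields within one
# expression are ANDed, expressions in the list are ORed (union).

.STATIC_COMPONENTS <- c("all", "protein", "nucleic", "branched", "ligand",
                        "ion", "water")

.SELECTOR_CHAR_FIELDS <- c("label_entity_id", "label_asym_id", "auth_asym_id",
                           "pdbx_PDB_ins_code", "label_atom_id",
                           "auth_atom_id", "type_symbol")
.SELECTOR_NUM_FIELDS <- c("label_seq_id", "auth_seq_id",
                          "beg_label_seq_id", "end_label_seq_id",
                          "beg_auth_seq_id", "end_auth_seq_id",
                          "atom_id", "atom_index")
.SELECTOR_FIELDS <- c(.SELECTOR_CHAR_FIELDS, .SELECTOR_NUM_FIELDS)

#' Construct an atom selector
#'
#' Either a static component name (`"protein"`, `"ligand"`, ...) or a list
#' of match expressions over mmCIF `_atom_site` item names. Within one
#' expression all set fields must match (conjunction); across expressions
#' results are unioned. `beg_*`/`end_*` ranges are inclusive on both ends.
#' `label_*` and `auth_*` fields match only the scheme the user set; there
#' is no silent fallback from one numbering scheme to the other.
#'
#' @param static One of `all, protein, nucleic, branched, ligand, ion,
#'   water`.
#' @param expressions List of named lists, e.g.
#'   `list(list(label_asym_id = "A", beg_label_seq_id = 1,
#'   end_label_seq_id = 10))`.
#' @return An object of class `mvs_selector`.
#' @export
#' @examples
#' mvs_selector("protein")
#' mvs_selector(expressions = list(list(label_asym_id = "A")))
mvs_selector <- function(static = NULL, expressions = NULL) {
  if (is.null(static) == is.null(expressions)) {
    stop("give exactly one of `static` or `expressions`", call. = FALSE)
  }
  if (!is.null(static)) {
    if (!is.character(static) || length(static) != 1L ||
        !static %in% .STATIC_COMPONENTS) {
      stop("unknown static component '", paste(static, collapse = ","),
           "'; expected one of: ", paste(.STATIC_COMPONENTS, collapse = ", "),
           call. = FALSE)
    }
    return(structure(list(static = static), class = "mvs_selector"))
  }
  if (!is.list(expressions) || length(expressions) == 0L) {
    stop("selector selects nothing by construction: empty expression list",
         call. = FALSE)
  }
  expressions <- lapply(expressions, check_selector_expression)
  structure(list(expressions = expressions), class = "mvs_selector")
}

check_selector_expression <- function(e) {
  if (!is.list(e) || length(e) == 0L || is.null(names(e)) ||
      !all(nzchar(names(e)))) {
    stop("selector expression must be a non-empty named list", call. = FALSE)
  }
  bad <- setdiff(names(e), .SELECTOR_FIELDS)
  if (length(bad)) {
    stop("unknown selector field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (f in names(e)) {
    v <- e[[f]]
    if (length(v) != 1L || is.na(v)) {
      stop("selector field '", f, "' must be a single non-missing value",
           call. = FALSE)
    }
    if (f %in% .SELECTOR_NUM_FIELDS && !is.numeric(v)) {
      stop("selector field '", f, "' must be numeric", call. = FALSE)
    }
    if (f %in% .SELECTOR_CHAR_FIELDS && !is.character(v)) {
      stop("selector field '", f, "' must be a string", call. = FALSE)
    }
  }
  for (pair in list(c("beg_label_seq_id", "end_label_seq_id"),
                    c("beg_auth_seq_id", "end_auth_seq_id"))) {
    if (all(pair %in% names(e)) && e[[pair[1]]] > e[[pair[2]]]) {
      stop("selector range ", pair[1], " > ", pair[2], call. = FALSE)
    }
  }
  e
}

# parameter-map encoding of a selector: a bare string for static names,
# an array of expression objects otherwise
selector_to_param <- function(sel) {
  stopifnot(inherits(sel, "mvs_selector"))
  if (!is.null(sel$static)) sel$static else normalize_value(sel$expressions)
}

# inverse of selector_to_param, for trees parsed from MVSJ
param_to_selector <- function(p) {
  if (is.character(p) && length(p) == 1L) return(mvs_selector(static = p))
  if (is.list(p)) return(mvs_selector(expressions = p))
  stop("malformed selector parameter", call. = FALSE)
}

#' @export
print.mvs_selector <- function(x, ...) {
  if (!is.null(x$static)) {
    cat("<mvs_selector> static:", x$static, "\n")
  } else {
    cat("<mvs_selector>", length(x$expressions), "expression(s)\n")
    for (e in x$expressions) {
      cat("  ", paste(sprintf("%s=%s", names(e), unlist(e)), collapse = " & "),
          "\n")
    }
  }
  invisible(x)
}
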