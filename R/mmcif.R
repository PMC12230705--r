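# Focused PDBx/mmCIF reader: _atom_site + _entity + _entity_poly. Enough
# of the dialect to load deposited coordinate files and the package's own
# fixtures (loops, key-value items, quoting, comments, semicolon text
# fields); no write support, no BinaryCIF.

tokenize_cif_line <- function(line) {
  tokens <- character(0)
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        # closing quote must be followed by whitespace or EOL
        if (substr(line, j, j) == ch &&
            (j == n || substr(line, j + 1L, j + 1L) %in% c(" ", "\t"))) break
        j <- j + 1L
      }
      tokens <- c(tokens, substr(line, i + 1L, j - 1L))
      i <- j + 1L
      next
    }
    j <- i
    while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
    tokens <- c(tokens, substr(line, i, j - 1L))
    i <- j
  }
  tokens
}

# parse CIF text into list(category -> list(item -> character vector))
parse_cif_categories <- function(text, wanted = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  cats <- list()
  i <- 1L
  nl <- length(lines)
  read_value_tokens <- function(start) {
    # returns list(tokens, next_line); handles semicolon text fields
    toks <- character(0)
    i <- start
    while (i <= nl) {
      ln <- lines[i]
      if (startsWith(ln, ";")) {
        j <- i + 1L
        buf <- substring(ln, 2L)
        while (j <= nl && !startsWith(lines[j], ";")) {
          buf <- paste(buf, lines[j], sep = "\n")
          j <- j + 1L
        }
        toks <- c(toks, buf)
        i <- j + 1L
        next
      }
      if (grepl("^\\s*(_|loop_|data_|stop_|#)", ln) || i > start) break
      toks <- c(toks, tokenize_cif_line(ln))
      i <- i + 1L
    }
    list(tokens = toks, next_line = i)
  }
  while (i <= nl) {
    ln <- lines[i]
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln)) ||
        grepl("^\\s*data_", ln)) {
      i <- i + 1L
      next
    }
    if (grepl("^\\s*loop_\\s*$", ln)) {
      i <- i + 1L
      items <- character(0)
      while (i <= nl && grepl("^\\s*_", lines[i])) {
        items <- c(items, trimws(lines[i]))
        i <- i + 1L
      }
      if (!length(items)) next
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", items[1])
      item_names <- sub("^_[^.]+\\.", "", items)
      values <- character(0)
      while (i <= nl) {
        ln2 <- lines[i]
        if (grepl("^\\s*(_|loop_|data_|stop_)", ln2)) break
        if (startsWith(ln2, ";")) {
          res <- read_value_tokens(i)
          values <- c(values, res$tokens)
          i <- res$next_line
          next
        }
        if (grepl("^\\s*#", ln2)) { i <- i + 1L; next }
        values <- c(values, tokenize_cif_line(ln2))
        i <- i + 1L
      }
      if (is.null(wanted) || cat_name %in% wanted) {
        ncol_ <- length(item_names)
        if (length(values) %% ncol_ != 0L) {
          stop("malformed mmCIF loop for category _", cat_name,
               ": value count not a multiple of the column count",
               call. = FALSE)
        }
        m <- matrix(values, ncol = ncol_, byrow = TRUE)
        cols <- stats::setNames(lapply(seq_len(ncol_),
                                       function(k) m[, k]), item_names)
        cats[[cat_name]] <- merge_category(cats[[cat_name]], cols)
      }
      next
    }
    if (grepl("^\\s*_", ln)) {
      toks <- tokenize_cif_line(ln)
      tag <- toks[1]
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", tag)
      item <- sub("^_[^.]+\\.", "", tag)
      if (length(toks) >= 2L) {
        val <- toks[2]
        i <- i + 1L
      } else {
        res <- read_value_tokens(i + 1L)
        val <- if (length(res$tokens)) res$tokens[1] else NA_character_
        i <- res$next_line
      }
      if (is.null(wanted) || cat_name %in% wanted) {
        cur <- cats[[cat_name]] %||% list()
        cur[[item]] <- c(cur[[item]], val)
        cats[[cat_name]] <- cur
      }
      next
    }
    i <- i + 1L
  }
  cats
}

merge_category <- function(old, new) {
  if (is.null(old)) return(new)
  for (k in names(new)) old[[k]] <- c(old[[k]], new[[k]])
  old
}

cif_null_to_na <- function(x) {
  x[x %in% c(".", "?")] <- NA_character_
  x
}

classify_entities <- function(cats) {
  # entity id -> entity_type enum
  types <- character(0)
  ent <- cats$entity
  if (!is.null(ent) && !is.null(ent$id) && !is.null(ent$type)) {
    types <- stats::setNames(tolower(ent$type), ent$id)
  }
  poly <- cats$entity_poly
  poly_types <- character(0)
  if (!is.null(poly) && !is.null(poly$entity_id) && !is.null(poly$type)) {
    poly_types <- stats::setNames(tolower(poly$type), poly$entity_id)
  }
  list(entity = types, poly = poly_types)
}

entity_type_of <- function(id, cls, single_atom_nonpoly) {
  base <- cls$entity[[id]] %||% NA_character_
  if (is.na(base)) return("non_polymer")
  if (base == "water") return("water")
  if (base == "branched") return("polymer_branched")
  if (base == "polymer") {
    pt <- cls$poly[[id]] %||% ""
    if (grepl("polypeptide", pt)) return("polymer_protein")
    if (grepl("ribonucleotide", pt)) return("polymer_nucleic")
    if (grepl("saccharide", pt)) return("polymer_branched")
    return("polymer_protein")
  }
  # non-polymer: single-atom-residue entities are classified as ions
  if (isTRUE(single_atom_nonpoly[[id]])) return("ion")
  "non_polymer"
}

#' Read the atoms of an mmCIF file into a flat atom table
#'
#' Parses the `_atom_site` loop (plus `_entity` / `_entity_poly` for
#' entity typing) into one row per atom. mmCIF nulls (`.` and `?`) map to
#' `NA`. Only the first model of a multi-model file is kept unless `model`
#' is given, matching the structure node's `model_index` default.
#'
#' Entity types: polymers are classified from `_entity_poly.type`
#' (`polypeptide*` is protein, `*ribonucleotide` is nucleic,
#' saccharides/`branched` are branched); `water` from `_entity.type`;
#' remaining non-polymer entities whose residues all consist of a single
#' atom are classified as ions.
#'
#' @param text mmCIF file content as a single string (or a character
#'   vector of lines).
#' @param model Optional model number (as printed in
#'   `pdbx_PDB_model_num`) to select instead of the first.
#' @return A data frame of class `mvs_atoms` with columns `atom_index`
#'   (dense, 0-based), `atom_id`, `label_atom_id`, `auth_atom_id`,
#'   `type_symbol`, `label_asym_id`, `auth_asym_id`, `label_entity_id`,
#'   `label_seq_id`, `auth_seq_id`, `pdbx_PDB_ins_code`, `x`, `y`, `z`,
#'   `model_num`, `entity_type`.
#' @export
read_mmcif_atoms <- function(text, model = NULL) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  cats <- parse_cif_categories(text,
                               wanted = c("atom_site", "entity",
                                          "entity_poly"))
  as_ <- cats$atom_site
  if (is.null(as_)) {
    stop("mmCIF text has no _atom_site loop", call. = FALSE)
  }
  n <- length(as_[[1]])
  col <- function(name, default = NA_character_) {
    v <- as_[[name]]
    if (is.null(v)) rep(default, n) else cif_null_to_na(v)
  }
  x <- suppressWarnings(as.numeric(col("Cartn_x")))
  y <- suppressWarnings(as.numeric(col("Cartn_y")))
  z <- suppressWarnings(as.numeric(col("Cartn_z")))
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      any(!is.finite(c(x, y, z)))) {
    stop("unparseable or missing atom coordinates in _atom_site",
         call. = FALSE)
  }
  model_num <- suppressWarnings(as.integer(col("pdbx_PDB_model_num", "1")))
  model_num[is.na(model_num)] <- 1L
  keep <- if (is.null(model)) model_num == model_num[1] else
    model_num == as.integer(model)
  label_atom <- col("label_atom_id")
  auth_atom <- col("auth_atom_id")
  auth_atom[is.na(auth_atom)] <- label_atom[is.na(auth_atom)]
  label_asym <- col("label_asym_id")
  auth_asym <- col("auth_asym_id")
  auth_asym[is.na(auth_asym)] <- label_asym[is.na(auth_asym)]
  entity_id <- col("label_entity_id")
  label_seq <- suppressWarnings(as.integer(col("label_seq_id")))
  auth_seq <- suppressWarnings(as.integer(col("auth_seq_id")))
  df <- data.frame(
    atom_id = suppressWarnings(as.integer(col("id", as.character(seq_len(n))))),
    label_atom_id = label_atom,
    auth_atom_id = auth_atom,
    type_symbol = col("type_symbol"),
    label_asym_id = label_asym,
    auth_asym_id = auth_asym,
    label_entity_id = entity_id,
    label_seq_id = label_seq,
    auth_seq_id = auth_seq,
    pdbx_PDB_ins_code = col("pdbx_PDB_ins_code"),
    x = x, y = y, z = z,
    model_num = model_num,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no atoms in the selected model", call. = FALSE)
  }
  cls <- classify_entities(cats)
  # ion predicate: non-polymer entity whose residues each hold one atom
  single_atom <- list()
  nonpoly_ids <- names(cls$entity)[cls$entity == "non-polymer"]
  for (id in unique(df$label_entity_id)) {
    if (!id %in% nonpoly_ids) next
    sub <- df[df$label_entity_id == id, , drop = FALSE]
    res_key <- paste(sub$label_asym_id, sub$auth_seq_id)
    single_atom[[id]] <- max(table(res_key)) == 1L
  }
  df$entity_type <- vapply(df$label_entity_id, entity_type_of,
                           character(1), cls = cls,
                           single_atom_nonpoly = single_atom)
  df$atom_index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  df <- df[, c("atom_index", "atom_id", "label_atom_id", "auth_atom_id",
               "type_symbol", "label_asym_id", "auth_asym_id",
               "label_entity_id", "label_seq_id", "auth_seq_id",
               "pdbx_PDB_ins_code", "x", "y", "z", "model_num",
               "entity_type")]
  class(df) <- c("mvs_atoms", "data.frame")
  df
}

#' @export
print.mvs_atoms <- function(x, ...) {
  cat("<mvs_atoms>", nrow(x), "atoms,",
      length(unique(x$label_asym_id)), "chain(s),",
      length(unique(x$label_entity_id)), "entity(ies)\n")
  NextMethod()
}
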