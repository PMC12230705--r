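# Deterministic synthetic mmCIF generator. Regeneration from an equal
# spec is byte-identical (its only randomness is a private LCG seeded from
# the spec), so fixtures never need to be stored on disk. The declared
# counts are embedded as a comment header so tests can use them as an
# independent oracle.

#' Describe a synthetic structure fixture
#'
#' The generated "protein" is a poly-glycine-like chain of backbone atoms
#' on a jittered 3.8-Angstrom grid — valid, parseable mmCIF with known
#' composition, not realistic stereochemistry. Chains are copies of one
#' polymer entity translated by multiples of `chain_offset`, so
#' inter-chain centroid distances are known by construction.
#'
#' @param n_chains Number of polymer chains (>= 1), labelled `A`, `B`, ...
#' @param residues_per_chain Residues per chain (>= 1).
#' @param atoms_per_residue Atoms per residue (1..8: backbone then
#'   side-chain names `N, CA, C, O, CB, CG, CD, CE`).
#' @param chain_offset Length-3 translation (Angstrom) between
#'   consecutive chains.
#' @param include_water Add one water molecule (entity `water`).
#' @param include_ligand Add one 3-atom non-polymer ligand.
#' @param seed Integer seed of the private jitter generator.
#' @return List of class `mvs_fixture_spec`.
#' @export
fixture_spec <- function(n_chains = 2L, residues_per_chain = 3L,
                         atoms_per_residue = 4L,
                         chain_offset = c(20, 0, 0),
                         include_water = FALSE, include_ligand = FALSE,
                         seed = 0L) {
  stopifnot(n_chains >= 1, residues_per_chain >= 1,
            atoms_per_residue >= 1, atoms_per_residue <= 8,
            length(chain_offset) == 3L)
  structure(list(n_chains = as.integer(n_chains),
                 residues_per_chain = as.integer(residues_per_chain),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 chain_offset = as.double(chain_offset),
                 include_water = isTRUE(include_water),
                 include_ligand = isTRUE(include_ligand),
                 seed = as.integer(seed)),
            class = "mvs_fixture_spec")
}

# private LCG (never touches R's global RNG); exact in double arithmetic
lcg_new <- function(seed) {
  state <- (as.double(seed) %% 2^32)
  function() {
    state <<- (69069 * state + 1) %% 2^32
    state / 2^32
  }
}

.FIXTURE_ATOM_NAMES <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")

fixture_counts <- function(spec) {
  poly <- spec$n_chains * spec$residues_per_chain * spec$atoms_per_residue
  list(polymer = poly,
       water = if (spec$include_water) 1L else 0L,
       ligand = if (spec$include_ligand) 3L else 0L,
       total = poly + (if (spec$include_water) 1L else 0L) +
         (if (spec$include_ligand) 3L else 0L))
}

#' Generate deterministic synthetic mmCIF text
#'
#' @param spec A [fixture_spec()].
#' @return mmCIF text (single string) parseable by [read_mmcif_atoms()];
#'   equal specs always produce byte-identical text. The header comment
#'   carries the declared atom counts.
#' @export
#' @examples
#' atoms <- read_mmcif_atoms(make_mmcif(fixture_spec()))
#' nrow(atoms)  # 2 chains x 3 residues x 4 atoms
make_mmcif <- function(spec) {
  stopifnot(inherits(spec, "mvs_fixture_spec"))
  cnt <- fixture_counts(spec)
  header <- c(
    "data_synthetic_fixture",
    sprintf(paste0("# synthetic fixture: n_chains=%d residues_per_chain=%d",
                   " atoms_per_residue=%d n_polymer_atoms=%d n_water=%d",
                   " n_ligand_atoms=%d total_atoms=%d seed=%d"),
            spec$n_chains, spec$residues_per_chain, spec$atoms_per_residue,
            cnt$polymer, cnt$water, cnt$ligand, cnt$total, spec$seed),
    "#"
  )
  ent_rows <- c("1 polymer 'synthetic poly-glycine chain'")
  if (spec$include_water) ent_rows <- c(ent_rows, "2 water 'water'")
  if (spec$include_ligand) ent_rows <- c(ent_rows, "3 non-polymer 'ligand'")
  entity <- c("loop_", "_entity.id", "_entity.type",
              "_entity.pdbx_description", ent_rows, "#")
  entity_poly <- c("loop_", "_entity_poly.entity_id", "_entity_poly.type",
                   "1 'polypeptide(L)'", "#")
  atom_header <- c(
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- character(0)
  serial <- 0L
  atom_names <- .FIXTURE_ATOM_NAMES[seq_len(spec$atoms_per_residue)]
  elem_of <- function(nm) substr(nm, 1, 1)
  emit <- function(group, type_symbol, atom, comp, asym, entity, seq_id,
                   xyz, auth_seq) {
    serial <<- serial + 1L
    sprintf("%s %d %s %s %s %s %s %s . %.3f %.3f %.3f %s %s %s 1",
            group, serial, type_symbol, atom, comp, asym, entity,
            seq_id, xyz[1], xyz[2], xyz[3], auth_seq, asym, atom)
  }
  for (ch in seq_len(spec$n_chains)) {
    asym <- LETTERS[ch]
    base <- (ch - 1L) * spec$chain_offset
    # same jitter stream per chain: chains are exact translated copies,
    # so inter-chain centroid offsets equal chain_offset by construction
    rng <- lcg_new(spec$seed)
    for (res in seq_len(spec$residues_per_chain)) {
      for (k in seq_len(spec$atoms_per_residue)) {
        jitter <- c(rng(), rng(), rng()) * 0.6 - 0.3
        xyz <- base + c((res - 1L) * 3.8, (k - 1L) * 1.4, 0) + jitter
        rows <- c(rows, emit("ATOM", elem_of(atom_names[k]),
                             atom_names[k], "GLY", asym, "1",
                             as.character(res), xyz, as.character(res)))
      }
    }
  }
  if (spec$include_water) {
    far <- spec$n_chains * spec$chain_offset + c(0, 10, 10)
    rows <- c(rows, emit("HETATM", "O", "O", "HOH", "W", "2", ".",
                         far, "101"))
  }
  if (spec$include_ligand) {
    base <- spec$n_chains * spec$chain_offset + c(5, -8, 0)
    lig_atoms <- c("C1", "C2", "O1")
    for (k in 1:3) {
      jitter <- c(rng(), rng(), rng()) * 0.6 - 0.3
      rows <- c(rows, emit("HETATM", elem_of(lig_atoms[k]), lig_atoms[k],
                           "LIG", "L", "3", ".",
                           base + c(k * 1.5, 0, 0) + jitter, "201"))
    }
  }
  paste(c(header, entity, entity_poly, atom_header, rows, "#", ""),
        collapse = "\n")
}

#' Parse the declared-count header of a generated fixture
#'
#' The independent count oracle for tests: reads the comment header that
#' [make_mmcif()] embeds, without going through the mmCIF parser.
#'
#' @param text Fixture mmCIF text.
#' @return Named list of declared counts.
#' @export
fixture_declared_counts <- function(text) {
  line <- grep("^# synthetic fixture:", strsplit(text, "\n")[[1]],
               value = TRUE)
  if (length(line) != 1L) stop("no fixture header found", call. = FALSE)
  kv <- regmatches(line, gregexpr("[a-z_]+=[0-9-]+", line))[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) as.integer(p[2])),
                  vapply(parts, `[[`, character(1), 1))
}
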