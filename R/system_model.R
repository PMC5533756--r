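#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select left_join group_by summarise arrange
#'   bind_rows n across all_of count ungroup rename
NULL

# Residue-name based group assignment. Protein protomers are told apart by
# chain/segment: the first protein chain encountered is protein_A, the second
# protein_B (additional chains are an error).
LIPID_RESNAMES <- c("DOPC", "DOPE", "DOPS")
WATER_RESNAMES <- c("TIP3", "TIP", "HOH", "WAT", "SPC")
ION_RESNAMES <- c("POT", "CLA", "SOD", "K", "CL", "NA", "MG", "CAL")

# 3-character on-disk aliases for the 4-character lipid residue names
# (standard PDB columns hold 3 characters; aliases are mapped back on load)
LIPID_PDB_ALIASES <- c(DPC = "DOPC", DPE = "DOPE", DPS = "DOPS")

AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL"
)

ATOM_GROUPS <- c("protein_A", "protein_B", "DOPC", "DOPE", "DOPS", "water", "ion")

#' Construct a system model from an atom table
#'
#' A system model is the static description of a molecular system: one row per
#' atom carrying identity (name, element, residue, segment), nonbonded
#' parameters (mass, partial charge, Lennard-Jones epsilon and rmin/2) and a
#' disjoint group label (`protein_A`, `protein_B`, `DOPC`, `DOPE`, `DOPS`,
#' `water`, `ion`).
#'
#' @param atoms Data frame with columns `atom_id`, `name`, `element`,
#'   `residue_name`, `residue_id`, `segment`, `mass` (amu), `charge` (e),
#'   `lj_epsilon` (kcal/mol, >= 0), `lj_rmin_half` (Angstrom, >= 0), `group`.
#' @return A `system_model`: a tibble of atoms with class attributes, plus an
#'   `is_heavy` column derived from the element.
#' @export
system_model <- function(atoms) {
  req <- c(
    "atom_id", "name", "element", "residue_name", "residue_id", "segment",
    "mass", "charge", "lj_epsilon", "lj_rmin_half", "group"
  )
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  if (anyDuplicated(atoms$atom_id) > 0) abort("atom_id values must be unique")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) abort("all masses must be > 0")
  if (any(atoms$lj_epsilon < 0)) abort("lj_epsilon must be >= 0")
  if (any(atoms$lj_rmin_half < 0)) abort("lj_rmin_half must be >= 0")
  bad_group <- setdiff(unique(atoms$group), ATOM_GROUPS)
  if (length(bad_group) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad_group, collapse = ", ")))
  }
  atoms$is_heavy <- atoms$element != "H"
  class(atoms) <- c("system_model", class(atoms))
  atoms
}

#' @export
print.system_model <- function(x, ...) {
  cat("<system_model> ", nrow(x), " atoms\n", sep = "")
  tab <- table(x$group)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Read a nonbonded parameter table
#'
#' The table is a TSV mapping `(residue_name, atom_name)` to mass, charge and
#' Lennard-Jones parameters; it stands in for full force-field topology files,
#' of which only these four per-atom quantities are consumed.
#'
#' @param path Path to a TSV with columns `residue_name`, `atom_name`, `mass`,
#'   `charge`, `epsilon`, `rmin_half`.
#' @return Tibble of parameters.
#' @export
read_param_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("residue_name", "atom_name", "mass", "charge", "epsilon", "rmin_half")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("parameter table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' Write a nonbonded parameter table
#'
#' @param params Tibble as returned by [read_param_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  readr::write_tsv(params, path, progress = FALSE)
  invisible(path)
}

# Element from a PDB/CHARMM atom name when no element column is present:
# strip leading digits, take the first letter; two-letter ions handled first.
infer_element <- function(name) {
  nm <- toupper(gsub("^[0-9']+", "", name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "NA", "MG", "FE", "ZN", "BR"), two, substr(nm, 1, 1))
  # CHARMM potassium is POT; single-letter fallback is fine for K/P/N/C/O/S/H
  el
}

assign_group <- function(residue_name, segment, chain) {
  n <- length(residue_name)
  group <- rep(NA_character_, n)
  group[residue_name %in% LIPID_RESNAMES] <- residue_name[residue_name %in% LIPID_RESNAMES]
  group[residue_name %in% WATER_RESNAMES] <- "water"
  group[residue_name %in% ION_RESNAMES] <- "ion"
  is_prot <- residue_name %in% AMINO_ACIDS
  if (any(is_prot)) {
    key <- ifelse(is.na(segment) | segment == "", chain, segment)
    prot_keys <- unique(key[is_prot])
    if (length(prot_keys) > 2) {
      abort(paste0(
        "more than two protein chains/segments found: ",
        paste(prot_keys, collapse = ", ")
      ))
    }
    group[is_prot & key == prot_keys[1]] <- "protein_A"
    if (length(prot_keys) == 2) group[is_prot & key == prot_keys[2]] <- "protein_B"
  }
  group
}

#' Load a molecular system from a PDB file plus a parameter table
#'
#' Atom records are read from the PDB (via bio3d); masses, charges and LJ
#' parameters are resolved from the sidecar parameter table by
#' `(residue_name, atom_name)`. Group labels are assigned from residue names
#' (lipids, water, ions) and chain/segment (protein protomers A and B).
#'
#' @param structure_path Path to a PDB file.
#' @param parameter_table_path Path to the parameter TSV
#'   (see [read_param_table()]).
#' @return A [system_model()].
#' @export
load_system <- function(structure_path, parameter_table_path) {
  if (!file.exists(structure_path)) abort(paste0("no such structure file: ", structure_path))
  pdb <- tryCatch(
    bio3d::read.pdb(structure_path, verbose = FALSE),
    error = function(e) abort(paste0("malformed PDB '", structure_path, "': ", conditionMessage(e)))
  )
  params <- read_param_table(parameter_table_path)
  at <- pdb$atom
  resname <- at$resid
  aliased <- resname %in% names(LIPID_PDB_ALIASES)
  resname[aliased] <- LIPID_PDB_ALIASES[resname[aliased]]
  atoms <- tibble(
    atom_id = seq_len(nrow(at)),
    name = at$elety,
    residue_name = resname,
    residue_id = at$resno,
    segment = ifelse(is.na(at$segid) | at$segid == "", at$chain, at$segid),
    chain = at$chain,
    x = at$x, y = at$y, z = at$z
  )
  atoms <- left_join(
    atoms,
    rename(params, name = "atom_name"),
    by = c("residue_name", "name")
  )
  unresolved <- filter(atoms, is.na(.data$mass))
  if (nrow(unresolved) > 0) {
    pairs <- unique(paste0(unresolved$residue_name, ":", unresolved$name))
    abort(paste0(
      "atoms missing from parameter table: ",
      paste(utils::head(pairs, 20), collapse = ", "),
      if (length(pairs) > 20) sprintf(" (and %d more)", length(pairs) - 20) else ""
    ))
  }
  atoms$element <- infer_element(atoms$name)
  atoms$group <- assign_group(atoms$residue_name, atoms$segment, atoms$chain)
  if (anyNA(atoms$group)) {
    bad <- unique(atoms$residue_name[is.na(atoms$group)])
    abort(paste0("cannot assign group for residue(s): ", paste(bad, collapse = ", ")))
  }
  sys <- system_model(
    select(
      atoms, "atom_id", "name", "element", "residue_name", "residue_id",
      "segment", "mass", "charge",
      lj_epsilon = "epsilon", lj_rmin_half = "rmin_half", "group"
    )
  )
  attr(sys, "coordinates") <- unname(as.matrix(atoms[, c("x", "y", "z")]))
  sys
}

#' Write a system model (with coordinates) to a PDB file
#'
#' @param system A [system_model()].
#' @param coordinates N x 3 matrix of coordinates in Angstrom (defaults to the
#'   coordinates carried by the system, if any).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_system_pdb <- function(system, path, coordinates = NULL) {
  coordinates <- coordinates %||% attr(system, "coordinates")
  if (is.null(coordinates)) abort("no coordinates supplied or stored on the system")
  stopifnot(nrow(coordinates) == nrow(system))
  chain <- ifelse(system$group == "protein_B", "B", "A")
  resid_out <- system$residue_name
  rev_alias <- stats::setNames(names(LIPID_PDB_ALIASES), LIPID_PDB_ALIASES)
  mapped <- resid_out %in% names(rev_alias)
  resid_out[mapped] <- rev_alias[resid_out[mapped]]
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coordinates)),
    type = rep("ATOM", nrow(system)),
    eleno = system$atom_id,
    elety = system$name,
    resid = resid_out,
    resno = system$residue_id,
    chain = chain,
    segid = substr(system$segment, 1, 4)
  )
  invisible(path)
}

#' Count atoms and lipids per group
#'
#' @param system A [system_model()].
#' @return Tibble with `group`, `n_atoms`, `n_residues`.
#' @export
group_census <- function(system) {
  as_tibble(system) |>
    group_by(.data$group) |>
    summarise(
      n_atoms = n(),
      n_residues = length(unique(paste(.data$segment, .data$residue_id))),
      .groups = "drop"
    ) |>
    rename(group = "group")
}

#' Derive a parameter table from a system model
#'
#' One row per distinct `(residue_name, atom_name)` with the nonbonded
#' parameters carried by the system; lets generated systems round-trip
#' through [write_system_pdb()] and [load_system()].
#'
#' @param system A [system_model()].
#' @return Parameter tibble as consumed by [load_system()].
#' @export
system_param_table <- function(system) {
  as_tibble(system) |>
    select(
      "residue_name", atom_name = "name", "mass", "charge",
      epsilon = "lj_epsilon", rmin_half = "lj_rmin_half"
    ) |>
    dplyr::distinct()
}

#' Net formal charge from a residue composition
#'
#' Sums formal charges over a residue-composition table using standard
#' protonation at neutral pH: Lys and Arg +1, Asp and Glu -1, His 0 unless
#' listed as protonated (HSP). Used to check the printed composition of a
#' basic protein domain (e.g. 52 Lys + 20 Arg - 18 Asp - 46 Glu = +8 e for an
#' I-BAR dimer).
#'
#' @param composition Data frame with columns `residue_name` and `count`.
#' @return Net formal charge in units of e.
#' @export
net_formal_charge <- function(composition) {
  charges <- c(
    LYS = 1, ARG = 1, ASP = -1, GLU = -1, HIS = 0, HSD = 0, HSE = 0, HSP = 1
  )
  q <- charges[toupper(composition$residue_name)]
  q[is.na(q)] <- 0
  sum(q * composition$count)
}
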