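#' Select atoms of a system model
#'
#' Builds a deterministic atom selection from simple predicates over the atom
#' table. All predicates are combined with AND; `NULL` means "no constraint".
#' Empty selections are valid and returned as `integer(0)`.
#'
#' @param system A [system_model()].
#' @param group Character vector of group labels to keep.
#' @param residue_id Integer vector (or range) of residue ids to keep.
#' @param name Character vector of atom names to keep.
#' @param element Character vector of elements to keep.
#' @param heavy_only If `TRUE`, drop hydrogens.
#' @return Integer vector of row indices into the atom table.
#' @export
select_atoms <- function(system, group = NULL, residue_id = NULL, name = NULL,
                         element = NULL, heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(system))
  if (!is.null(group)) keep <- keep & system$group %in% group
  if (!is.null(residue_id)) keep <- keep & system$residue_id %in% residue_id
  if (!is.null(name)) keep <- keep & system$name %in% name
  if (!is.null(element)) keep <- keep & system$element %in% element
  if (heavy_only) keep <- keep & system$is_heavy
  which(keep)
}

#' Protein heavy-atom selection
#'
#' @param system A [system_model()].
#' @param protomer `"both"` (default), `"A"` or `"B"`.
#' @return Integer atom indices.
#' @export
select_protein <- function(system, protomer = "both") {
  groups <- switch(protomer,
    both = c("protein_A", "protein_B"),
    A = "protein_A",
    B = "protein_B",
    abort("protomer must be 'both', 'A' or 'B'")
  )
  select_atoms(system, group = groups, heavy_only = TRUE)
}

#' Lipid heavy-atom selection
#'
#' @param system A [system_model()].
#' @param types Lipid types to keep (default all three).
#' @return Integer atom indices.
#' @export
select_lipids <- function(system, types = c("DOPC", "DOPE", "DOPS")) {
  select_atoms(system, group = types, heavy_only = TRUE)
}

# Default headgroup atom names per lipid type: phosphate plus the
# choline/ethanolamine/serine moiety. Configurable wherever consumed; the
# headgroup COM defines lipid position in all membrane profiles.
DEFAULT_HEADGROUP_ATOMS <- list(
  DOPC = c("N", "C12", "C13", "C14", "C15", "C11", "P", "O11", "O12", "O13", "O14"),
  DOPE = c("N", "C12", "C11", "P", "O11", "O12", "O13", "O14"),
  DOPS = c("N", "C12", "C13", "O13A", "O13B", "C11", "P", "O11", "O12", "O13", "O14")
)

#' Lipid headgroup atom selection
#'
#' @param system A [system_model()].
#' @param types Lipid types to keep.
#' @param headgroup_atoms Named list of headgroup atom names per lipid type.
#' @return Integer atom indices.
#' @export
select_headgroups <- function(system, types = c("DOPC", "DOPE", "DOPS"),
                              headgroup_atoms = DEFAULT_HEADGROUP_ATOMS) {
  idx <- integer(0)
  for (tp in types) {
    idx <- c(idx, select_atoms(system, group = tp, name = headgroup_atoms[[tp]]))
  }
  sort(idx)
}
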