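#' Mass-weighted center of mass
#'
#' @param frm A [frame()].
#' @param system A [system_model()] supplying masses.
#' @param selection Integer atom indices (see [select_atoms()]).
#' @return Length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(frm, system, selection) {
  if (length(selection) == 0) abort("empty selection in center_of_mass")
  m <- system$mass[selection]
  r <- frm$coordinates[selection, , drop = FALSE]
  colSums(r * m) / sum(m)
}

# Inertia tensor about the COM, amu * A^2
inertia_tensor <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  r2 <- rowSums(r * r)
  I <- diag(c(sum(masses * r2), sum(masses * r2), sum(masses * r2)))
  for (a in 1:3) {
    for (b in 1:3) {
      I[a, b] <- I[a, b] - sum(masses * r[, a] * r[, b])
    }
  }
  I
}

#' Principal axes of inertia
#'
#' Diagonalizes the inertia tensor of the selected atoms about their center of
#' mass. Axes are returned in ascending order of inertia eigenvalue
#' (first axis = smallest moment, i.e. the long axis of an elongated body).
#' Sign is fixed so each axis has a non-negative Z component; if the Z
#' component is (numerically) zero, non-negative X and then Y break the tie,
#' making the orientation angle deterministic for symmetric bodies.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param selection Integer atom indices; needs at least 3 non-collinear atoms.
#' @return List with `axes` (3 x 3 matrix, axes in columns) and `moments`
#'   (ascending eigenvalues, amu A^2).
#' @export
principal_axes <- function(frm, system, selection) {
  if (length(selection) < 3) abort("principal_axes needs at least 3 atoms")
  coords <- frm$coordinates[selection, , drop = FALSE]
  masses <- system$mass[selection]
  I <- inertia_tensor(coords, masses)
  eig <- eigen(I, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # collinear point set: inertia about the line is ~0 twice degenerate with
  # zero perpendicular extent -> smallest eigenvalue ~ 0 AND gyration rank < 2
  gyr <- svd(sweep(coords, 2, colMeans(coords)))$d
  if (gyr[2] < 1e-8 * max(gyr[1], 1)) abort("degenerate (collinear) point set")
  tol <- 1e-12
  for (j in 1:3) {
    v <- vecs[, j]
    s <- if (abs(v[3]) > tol) sign(v[3]) else if (abs(v[1]) > tol) sign(v[1]) else sign(v[2])
    if (s < 0) vecs[, j] <- -v
  }
  list(axes = vecs, moments = vals)
}

#' Orientation angle theta of a membrane-binding domain
#'
#' The angle between the second principal axis of inertia of the protein and
#' the membrane normal (Z), folded into `[0, 90]` degrees. Zero means the
#' binding face points straight at the membrane.
#'
#' @inheritParams principal_axes
#' @return Angle in degrees.
#' @export
theta_angle <- function(frm, system, selection) {
  ax <- principal_axes(frm, system, selection)
  a2 <- ax$axes[, 2]
  acos(pmin(1, abs(a2[3]))) * 180 / pi
}

# Minimum over heavy-atom pairs of the 3D minimum-image distance.
# Chunked over the first selection to bound memory.
min_pair_distance <- function(coordsA, coordsB, box, chunk = 2000L) {
  best <- Inf
  nA <- nrow(coordsA)
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(nA, s + chunk - 1L)
    d2 <- min_image_dist2(coordsA[s:e, , drop = FALSE], coordsB, box)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Z-projected gap between two atom sets: the distance between their Z
# intervals (0 if they interpenetrate).
gap_z_value <- function(zA, zB) {
  lo <- max(min(zA), min(zB))
  hi <- min(max(zA), max(zB))
  if (hi >= lo) return(0)
  lo2 <- max(min(zA) - max(zB), min(zB) - max(zA))
  max(0, lo2)
}

#' Binding-geometry observables for one frame
#'
#' Computes the center-of-mass separation along Z (`d_z`), its offset from a
#' reference (`delta_d_z`), the Z-projected interfacial gap, the minimum 3D
#' heavy-atom pair distance, and the orientation angle theta.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param protein_sel,membrane_sel Heavy-atom index selections.
#' @param reference_d_z Reference separation defining `delta_d_z = d_z -
#'   reference_d_z`; conventionally the separation at the bound-state free
#'   energy minimum.
#' @return One-row tibble: `time`, `theta`, `d_z`, `delta_d_z`, `gap_z`,
#'   `min_pair_distance`.
#' @export
binding_coordinates <- function(frm, system, protein_sel, membrane_sel,
                                reference_d_z = 0) {
  if (length(protein_sel) == 0 || length(membrane_sel) == 0) {
    abort("empty selection in binding_coordinates")
  }
  com_p <- center_of_mass(frm, system, protein_sel)
  com_m <- center_of_mass(frm, system, membrane_sel)
  d_z <- abs(com_p[3] - com_m[3])
  cp <- frm$coordinates[protein_sel, , drop = FALSE]
  cm <- frm$coordinates[membrane_sel, , drop = FALSE]
  tibble(
    time = frm$time,
    theta = if (length(protein_sel) >= 3) {
      theta_angle(frm, system, protein_sel)
    } else NA_real_,
    d_z = d_z,
    delta_d_z = d_z - reference_d_z,
    gap_z = gap_z_value(cp[, 3], cm[, 3]),
    min_pair_distance = min_pair_distance(cp, cm, frm$box)
  )
}

#' Binding-geometry time series over a trajectory
#'
#' @param traj A [trajectory()].
#' @inheritParams binding_coordinates
#' @return Tibble with one row per frame (columns as
#'   [binding_coordinates()]).
#' @export
orientation_series <- function(traj, system, protein_sel, membrane_sel,
                               reference_d_z = 0) {
  purrr::map_dfr(
    traj, binding_coordinates,
    system = system, protein_sel = protein_sel,
    membrane_sel = membrane_sel, reference_d_z = reference_d_z
  )
}

#' First protein-membrane contact along a trajectory
#'
#' Scans frames in time order for the first whose minimum heavy-atom pair
#' distance between protein and lipids is at or below the contact cutoff, and
#' reports which protein residue(s) achieve it.
#'
#' @param traj A [trajectory()].
#' @param system A [system_model()].
#' @param protein_sel,lipid_sel Heavy-atom index selections.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @return One-row tibble `time`, `residue_id`, `residue_name`, `distance`,
#'   or a zero-row tibble if contact never occurs. Multiple residues tied at
#'   the minimum give multiple rows.
#' @export
first_contact_time <- function(traj, system, protein_sel, lipid_sel, cutoff = 5) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (length(traj) == 0) abort("empty trajectory")
  empty <- tibble(
    time = numeric(0), residue_id = integer(0),
    residue_name = character(0), distance = numeric(0)
  )
  for (f in traj) {
    cp <- f$coordinates[protein_sel, , drop = FALSE]
    cl <- f$coordinates[lipid_sel, , drop = FALSE]
    d2 <- min_image_dist2(cp, cl, f$box)
    dmin <- sqrt(min(d2))
    if (dmin <= cutoff) {
      rows <- which(apply(d2, 1, min) <= max(dmin^2 + 1e-12, dmin^2))
      rows <- rows[sqrt(apply(d2[rows, , drop = FALSE], 1, min)) <= dmin + 1e-9]
      res <- unique(tibble(
        residue_id = system$residue_id[protein_sel[rows]],
        residue_name = system$residue_name[protein_sel[rows]]
      ))
      return(tibble(
        time = f$time, residue_id = res$residue_id,
        residue_name = res$residue_name, distance = dmin
      ))
    }
  }
  empty
}
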