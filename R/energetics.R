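# CHARMM-style energy switching function, applied between r_on and r_off.
# C1-continuous: 1 at r <= r_on, 0 at r >= r_off.
switch_factor <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  s[r >= r_off] <- 0
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2
    on2 <- r_on^2
    off2 <- r_off^2
    s[mid] <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  }
  s
}

#' Nonbonded pair energy
#'
#' Coulomb plus Lennard-Jones energy of one atom pair, CHARMM conventions:
#' `E = 332.0636 q_i q_j / r + eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)`
#' with Lorentz-Berthelot-style combination `eps_ij = sqrt(eps_i eps_j)`,
#' `rmin_ij = rmin_half_i + rmin_half_j`.
#'
#' @param q_i,q_j Partial charges, e.
#' @param eps_i,eps_j LJ well depths, kcal/mol.
#' @param rmin_half_i,rmin_half_j LJ rmin/2, Angstrom.
#' @param r Distance, Angstrom (> 0).
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(q_i, q_j, eps_i, eps_j, rmin_half_i, rmin_half_j, r) {
  if (any(r <= 0)) abort("pair distance must be > 0")
  eps_ij <- sqrt(eps_i * eps_j)
  rmin_ij <- rmin_half_i + rmin_half_j
  sr6 <- (rmin_ij / r)^6
  COULOMB_KCAL * q_i * q_j / r + eps_ij * (sr6^2 - 2 * sr6)
}

# energy of all pairs between index sets A and B (disjoint), with optional
# switched cutoff; minimum image
group_energy_matrix <- function(frm, system, selA, selB, cutoff, r_on) {
  d2 <- min_image_dist2(
    frm$coordinates[selA, , drop = FALSE],
    frm$coordinates[selB, , drop = FALSE], frm$box
  )
  r <- sqrt(d2)
  qq <- outer(system$charge[selA], system$charge[selB])
  eps <- outer(system$lj_epsilon[selA], system$lj_epsilon[selB], function(a, b) sqrt(a * b))
  rmin <- outer(system$lj_rmin_half[selA], system$lj_rmin_half[selB], "+")
  sr6 <- (rmin / r)^6
  e <- COULOMB_KCAL * qq / r + eps * (sr6^2 - 2 * sr6)
  if (is.finite(cutoff)) {
    e <- e * switch_factor(r, r_on, cutoff)
  }
  e
}

#' Nonbonded interaction energy between two atom groups
#'
#' Sum of pair energies over all inter-group pairs, with a CHARMM-style
#' energy-switched cutoff (default: switch from 10 Angstrom, cut at 12;
#' `cutoff = Inf` disables truncation). Minimum-image distances throughout.
#' This is an analysis-level decomposition proxy, not an Ewald production
#' energy.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param sel_a,sel_b Disjoint atom index selections.
#' @param cutoff Cutoff radius, Angstrom (default 12; `Inf` supported).
#' @param r_on Switching onset radius, Angstrom (default 10).
#' @return Energy in kcal/mol.
#' @export
group_energy <- function(frm, system, sel_a, sel_b, cutoff = 12, r_on = 10) {
  if (length(intersect(sel_a, sel_b)) > 0) abort("selections must be disjoint")
  if (length(sel_a) == 0 || length(sel_b) == 0) return(0)
  chunk <- max(1L, floor(2e6 / length(sel_b)))
  total <- 0
  for (s in seq(1L, length(sel_a), by = chunk)) {
    e <- min(length(sel_a), s + chunk - 1L)
    total <- total + sum(group_energy_matrix(frm, system, sel_a[s:e], sel_b, cutoff, r_on))
  }
  total
}

#' Protein-lipid interaction-energy map on the membrane plane
#'
#' For each lipid, its whole-lipid interaction energy with the protein is
#' accumulated at the XY bin of its headgroup center of mass, then
#' time-averaged over frames. A Y-integrated profile along X (row sums of the
#' grid) is attached.
#'
#' @param traj A [trajectory()].
#' @param system A [system_model()].
#' @param protein_sel Protein atom selection (all atoms, not just heavy).
#' @param lipid_types Lipid types to include.
#' @param headgroup_sel Headgroup selection used to place each lipid.
#' @param grid_size Number of bins per axis, `c(nx, ny)` (each >= 2).
#' @param cutoff,r_on Passed to [group_energy()].
#' @return An `energy_map`: tibble `x_bin`, `y_bin`, `x`, `y`, `energy`
#'   (kcal/mol, time-averaged); attribute `profile` is the Y-integrated
#'   tibble `x`, `energy`.
#' @export
interaction_map <- function(traj, system, protein_sel,
                            lipid_types = c("DOPC", "DOPE", "DOPS"),
                            headgroup_sel = select_headgroups(system, lipid_types),
                            grid_size = c(32, 8), cutoff = 12, r_on = 10) {
  if (any(grid_size < 2)) abort("grid must be at least 2 x 2")
  box <- traj[[1]]$box
  nx <- grid_size[1]
  ny <- grid_size[2]
  acc <- matrix(0, nx, ny)
  lipid_rows <- which(system$group %in% lipid_types)
  lipid_keys <- unique(paste(system$group[lipid_rows], system$residue_id[lipid_rows], sep = ":"))
  for (f in traj) {
    hg <- headgroup_positions(f, system, headgroup_sel)
    for (lk in lipid_keys) {
      parts <- strsplit(lk, ":")[[1]]
      lsel <- which(system$group == parts[1] & system$residue_id == as.integer(parts[2]))
      e <- group_energy(f, system, protein_sel, lsel, cutoff, r_on)
      row <- hg[hg$lipid_key == lk, ]
      bx <- x_bin_index(row$x, box[1], nx)
      by <- x_bin_index(row$y, box[2], ny)
      acc[bx, by] <- acc[bx, by] + e
    }
  }
  acc <- acc / length(traj)
  xc <- x_bin_centers(box[1], nx)
  yc <- x_bin_centers(box[2], ny)
  out <- tidyr::expand_grid(x_bin = seq_len(nx), y_bin = seq_len(ny)) |>
    mutate(
      x = xc[.data$x_bin], y = yc[.data$y_bin],
      energy = acc[cbind(.data$x_bin, .data$y_bin)]
    )
  attr(out, "profile") <- tibble(x = xc, energy = rowSums(acc))
  class(out) <- c("energy_map", class(out))
  out
}

#' Interaction-energy change on binding, decomposed by partner
#'
#' Component-wise difference of mean protein-partner interaction energies
#' between a bound and an unbound frame window, for water, ion and lipid
#' partners, plus the total.
#'
#' @param bound_traj,unbound_traj Trajectories (or lists of frames) sampling
#'   the two states of the same system.
#' @param system A [system_model()].
#' @param protein_sel Protein atom selection.
#' @param cutoff,r_on Passed to [group_energy()].
#' @return Tibble: `partner` (water/ion/lipid/total), `e_bound`, `e_unbound`,
#'   `delta_e` (kcal/mol).
#' @export
delta_e_int <- function(bound_traj, unbound_traj, system, protein_sel,
                        cutoff = 12, r_on = 10) {
  if (length(bound_traj) == 0 || length(unbound_traj) == 0) {
    abort("both frame windows must be non-empty")
  }
  partners <- list(
    water = select_atoms(system, group = "water"),
    ion = select_atoms(system, group = "ion"),
    lipid = select_atoms(system, group = c("DOPC", "DOPE", "DOPS"))
  )
  mean_energy <- function(frames, sel) {
    if (length(sel) == 0) return(0)
    mean(vapply(
      frames, group_energy, numeric(1),
      system = system, sel_a = protein_sel, sel_b = sel,
      cutoff = cutoff, r_on = r_on
    ))
  }
  rows <- purrr::imap_dfr(partners, function(sel, nm) {
    eb <- mean_energy(bound_traj, sel)
    eu <- mean_energy(unbound_traj, sel)
    tibble(partner = nm, e_bound = eb, e_unbound = eu, delta_e = eb - eu)
  })
  bind_rows(
    rows,
    tibble(
      partner = "total",
      e_bound = sum(rows$e_bound), e_unbound = sum(rows$e_unbound),
      delta_e = sum(rows$delta_e)
    )
  )
}
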