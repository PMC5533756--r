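#' Default basic/acidic group definitions for salt bridges
#'
#' Basic nitrogens: Lys NZ; Arg NE/NH1/NH2; protonated His (HSP) ND1/NE2; the
#' lipid amine/choline N of all three lipid types (the quaternary choline N of
#' PC counts as basic against protein acidic oxygens). Acidic oxygens: Asp
#' OD1/OD2; Glu OE1/OE2; C-terminal O/OXT; lipid phosphate oxygens; the PS
#' serine carboxylate. N-/C-termini are detected per protein segment.
#'
#' @return List with `basic` and `acidic` tibbles (`residue_name`,
#'   `atom_name`).
#' @export
default_salt_bridge_groups <- function() {
  list(
    basic = tibble(
      residue_name = c(
        "LYS", "ARG", "ARG", "ARG", "HSP", "HSP",
        "DOPC", "DOPE", "DOPS"
      ),
      atom_name = c("NZ", "NE", "NH1", "NH2", "ND1", "NE2", "N", "N", "N")
    ),
    acidic = tibble(
      residue_name = c(
        "ASP", "ASP", "GLU", "GLU",
        rep("DOPC", 4), rep("DOPE", 4), rep("DOPS", 6),
        rep("DOPC", 4), rep("DOPE", 4), rep("DOPS", 4)
      ),
      atom_name = c(
        "OD1", "OD2", "OE1", "OE2",
        rep(c("O11", "O12", "O13", "O14"), 3), "O13A", "O13B",
        rep(c("O1P", "O2P", "O3P", "O4P"), 3)
      )
    )
  )
}

# residue instance key
res_key <- function(system, idx) {
  paste(system$segment[idx], system$residue_id[idx], sep = ":")
}

# pairs (i in selA, j in selB) with min-image distance <= cutoff
pairs_within <- function(frm, selA, selB, cutoff) {
  if (length(selA) == 0 || length(selB) == 0) {
    return(tibble(i = integer(0), j = integer(0), distance = numeric(0)))
  }
  d2 <- min_image_dist2(
    frm$coordinates[selA, , drop = FALSE],
    frm$coordinates[selB, , drop = FALSE],
    frm$box
  )
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  tibble(
    i = selA[hit[, 1]],
    j = selB[hit[, 2]],
    distance = sqrt(d2[hit])
  )
}

#' Residue-lipid contacts in one frame
#'
#' An amino acid contacts a lipid when any heavy-atom pair between them is
#' within the cutoff (default 5 Angstrom), using minimum-image distances.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param protein_sel,lipid_sel Heavy-atom index selections.
#' @param cutoff Contact cutoff, Angstrom.
#' @return Tibble with one row per (residue, lipid) contact: `residue_id`,
#'   `residue_name`, `segment`, `lipid_id`, `lipid_type`, `min_distance`,
#'   `time`.
#' @export
find_contacts <- function(frm, system, protein_sel, lipid_sel, cutoff = 5) {
  pw <- pairs_within(frm, protein_sel, lipid_sel, cutoff)
  if (nrow(pw) == 0) {
    return(tibble(
      residue_id = integer(0), residue_name = character(0),
      segment = character(0), lipid_id = integer(0),
      lipid_type = character(0), min_distance = numeric(0), time = numeric(0)
    ))
  }
  tibble(
    residue_id = system$residue_id[pw$i],
    residue_name = system$residue_name[pw$i],
    segment = system$segment[pw$i],
    lipid_id = system$residue_id[pw$j],
    lipid_type = system$group[pw$j],
    distance = pw$distance
  ) |>
    group_by(
      .data$residue_id, .data$residue_name, .data$segment,
      .data$lipid_id, .data$lipid_type
    ) |>
    summarise(min_distance = min(.data$distance), .groups = "drop") |>
    mutate(time = frm$time)
}

# classify atoms of the system as basic N / acidic O per the definitions,
# including protein termini
classify_charged_atoms <- function(system, definitions) {
  basic <- rep(FALSE, nrow(system))
  acidic <- rep(FALSE, nrow(system))
  for (r in seq_len(nrow(definitions$basic))) {
    basic <- basic |
      (system$residue_name == definitions$basic$residue_name[r] &
        system$name == definitions$basic$atom_name[r])
  }
  for (r in seq_len(nrow(definitions$acidic))) {
    acidic <- acidic |
      (system$residue_name == definitions$acidic$residue_name[r] &
        system$name == definitions$acidic$atom_name[r])
  }
  is_prot <- system$group %in% c("protein_A", "protein_B")
  for (seg in unique(system$segment[is_prot])) {
    in_seg <- is_prot & system$segment == seg
    basic <- basic | (in_seg & system$residue_id == min(system$residue_id[in_seg]) &
      system$name == "N")
    acidic <- acidic | (in_seg & system$residue_id == max(system$residue_id[in_seg]) &
      system$name %in% c("O", "OXT"))
  }
  list(basic = which(basic), acidic = which(acidic))
}

#' Salt bridges in one frame
#'
#' A salt bridge exists between a basic group and an acidic group when any
#' basic nitrogen is within the cutoff (default 3.2 Angstrom) of any acidic
#' oxygen. Records are deduplicated at the group (residue/headgroup) pair
#' level, so a bidentate arginine-phosphate interaction counts once.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param definitions Basic/acidic atom definitions
#'   (see [default_salt_bridge_groups()]).
#' @param cutoff N-O distance cutoff, Angstrom.
#' @return Tibble: `basic_key`, `basic_residue`, `acidic_key`,
#'   `acidic_residue`, `min_distance`, `intra_protein`, `protein_lipid`,
#'   `time`.
#' @export
find_salt_bridges <- function(frm, system, definitions = default_salt_bridge_groups(),
                              cutoff = 3.2) {
  cls <- classify_charged_atoms(system, definitions)
  pw <- pairs_within(frm, cls$basic, cls$acidic, cutoff)
  if (nrow(pw) == 0) {
    return(tibble(
      basic_key = character(0), basic_residue = character(0),
      acidic_key = character(0), acidic_residue = character(0),
      min_distance = numeric(0), intra_protein = logical(0),
      protein_lipid = logical(0), time = numeric(0)
    ))
  }
  prot <- c("protein_A", "protein_B")
  tibble(
    basic_key = res_key(system, pw$i),
    basic_residue = system$residue_name[pw$i],
    basic_is_prot = system$group[pw$i] %in% prot,
    acidic_key = res_key(system, pw$j),
    acidic_residue = system$residue_name[pw$j],
    acidic_is_prot = system$group[pw$j] %in% prot,
    distance = pw$distance
  ) |>
    filter(.data$basic_key != .data$acidic_key) |>
    group_by(
      .data$basic_key, .data$basic_residue, .data$basic_is_prot,
      .data$acidic_key, .data$acidic_residue, .data$acidic_is_prot
    ) |>
    summarise(min_distance = min(.data$distance), .groups = "drop") |>
    mutate(
      intra_protein = .data$basic_is_prot & .data$acidic_is_prot,
      protein_lipid = xor(.data$basic_is_prot, .data$acidic_is_prot),
      time = frm$time
    ) |>
    select(-"basic_is_prot", -"acidic_is_prot")
}

#' Hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor distance at most `d_cut` and
#' donor-hydrogen-acceptor angle at least `angle_cut`. Donor hydrogens are
#' located as hydrogens within 1.25 Angstrom of the donor heavy atom; donors
#' without an attached hydrogen are skipped with a warning.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param donors Integer indices of donor heavy atoms.
#' @param acceptors Integer indices of acceptor heavy atoms.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut D-H...A angle cutoff, degrees (default 130).
#' @return Tibble: `donor`, `hydrogen`, `acceptor`, `distance`, `angle`,
#'   `time`.
#' @export
find_hydrogen_bonds <- function(frm, system, donors, acceptors,
                                d_cut = 3.5, angle_cut = 130) {
  hydrogens <- which(!system$is_heavy)
  out <- list()
  kept_donors <- logical(length(donors))
  dh_pairs <- pairs_within(frm, donors, hydrogens, 1.25)
  missing_h <- setdiff(donors, unique(dh_pairs$i))
  if (length(missing_h) > 0) {
    warn(sprintf("%d donor(s) lack an attached hydrogen and were skipped", length(missing_h)))
  }
  da_pairs <- pairs_within(frm, unique(dh_pairs$i), acceptors, d_cut)
  if (nrow(da_pairs) == 0 || nrow(dh_pairs) == 0) {
    return(tibble(
      donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
      distance = numeric(0), angle = numeric(0), time = numeric(0)
    ))
  }
  cand <- left_join(da_pairs, dh_pairs, by = "i", suffix = c("_da", "_dh"),
                    relationship = "many-to-many")
  # angle D-H...A at H
  vh_d <- minimum_image_displacement(
    frm$coordinates[cand$i, , drop = FALSE],
    frm$coordinates[cand$j_dh, , drop = FALSE], frm$box
  )
  vh_a <- minimum_image_displacement(
    frm$coordinates[cand$j_da, , drop = FALSE],
    frm$coordinates[cand$j_dh, , drop = FALSE], frm$box
  )
  cosang <- rowSums(vh_d * vh_a) /
    (sqrt(rowSums(vh_d^2)) * sqrt(rowSums(vh_a^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- ang >= angle_cut & cand$i != cand$j_da
  tibble(
    donor = cand$i[keep],
    hydrogen = cand$j_dh[keep],
    acceptor = cand$j_da[keep],
    distance = cand$distance_da[keep],
    angle = ang[keep],
    time = frm$time
  )
}

#' Interface composition over a trajectory window
#'
#' Runs the contact and salt-bridge censuses on every frame in a time window
#' and aggregates per-frame counts to mean and sample standard deviation, by
#' amino-acid type (number of residue-lipid contact pairs and of
#' protein-lipid bridges whose basic/acidic partner is that residue type) and
#' by lipid type (number of distinct amino-acid residues contacting, and
#' bridging to, lipids of that type), plus protein-lipid totals.
#'
#' @param traj A [trajectory()].
#' @param system A [system_model()].
#' @param protein_sel,lipid_sel Heavy-atom selections.
#' @param window Length-2 numeric `c(t0, t1)` in ns; frames with `t0 <= time
#'   <= t1` are used (default: all frames). At least 2 frames required.
#' @param contact_cutoff,bridge_cutoff Cutoffs in Angstrom.
#' @param definitions Salt-bridge group definitions.
#' @return Tibble: `kind` (contact/salt_bridge), `class` (residue_type /
#'   lipid_type / total), `level`, `mean`, `sd`.
#' @export
tally_interface <- function(traj, system, protein_sel, lipid_sel,
                            window = NULL, contact_cutoff = 5,
                            bridge_cutoff = 3.2,
                            definitions = default_salt_bridge_groups()) {
  times <- frame_times(traj)
  keep <- if (is.null(window)) seq_along(traj) else {
    which(times >= window[1] & times <= window[2])
  }
  if (length(keep) < 2) abort("tally window must contain at least 2 frames")
  frames <- traj[keep]

  per_frame <- purrr::map(frames, function(f) {
    ct <- find_contacts(f, system, protein_sel, lipid_sel, contact_cutoff)
    sb <- find_salt_bridges(f, system, definitions, bridge_cutoff) |>
      filter(.data$protein_lipid)
    list(contacts = ct, bridges = sb)
  })

  count_levels <- function(values, levels) {
    tab <- table(factor(values, levels = levels))
    as.numeric(tab)
  }
  aa_levels <- sort(unique(system$residue_name[
    system$group %in% c("protein_A", "protein_B")
  ]))
  lipid_levels <- intersect(c("DOPC", "DOPE", "DOPS"), unique(system$group))

  rows <- list()
  add_stat <- function(kind, class, level, values) {
    tibble(
      kind = kind, class = class, level = level,
      mean = mean(values), sd = stats::sd(values)
    )
  }
  # per amino-acid type
  for (aa in aa_levels) {
    c_counts <- vapply(per_frame, function(p) sum(p$contacts$residue_name == aa), numeric(1))
    b_counts <- vapply(per_frame, function(p) {
      sum(p$bridges$basic_residue == aa | p$bridges$acidic_residue == aa)
    }, numeric(1))
    rows[[length(rows) + 1]] <- add_stat("contact", "residue_type", aa, c_counts)
    rows[[length(rows) + 1]] <- add_stat("salt_bridge", "residue_type", aa, b_counts)
  }
  # per lipid type: distinct protein residues involved
  for (lt in lipid_levels) {
    c_counts <- vapply(per_frame, function(p) {
      ct <- filter(p$contacts, .data$lipid_type == lt)
      length(unique(paste(ct$segment, ct$residue_id)))
    }, numeric(1))
    b_counts <- vapply(per_frame, function(p) {
      br <- p$bridges
      lip_basic <- br$basic_residue == lt
      lip_acidic <- br$acidic_residue == lt
      length(unique(c(br$acidic_key[lip_basic], br$basic_key[lip_acidic])))
    }, numeric(1))
    rows[[length(rows) + 1]] <- add_stat("contact", "lipid_type", lt, c_counts)
    rows[[length(rows) + 1]] <- add_stat("salt_bridge", "lipid_type", lt, b_counts)
  }
  # totals
  c_tot <- vapply(per_frame, function(p) nrow(p$contacts), numeric(1))
  b_tot <- vapply(per_frame, function(p) nrow(p$bridges), numeric(1))
  rows[[length(rows) + 1]] <- add_stat("contact", "total", "protein_lipid", c_tot)
  rows[[length(rows) + 1]] <- add_stat("salt_bridge", "total", "protein_lipid", b_tot)
  bind_rows(rows)
}
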