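# Fixture builders and independent brute-force oracles. All fixtures are
# constructed in code; oracles deliberately use naive formulations distinct
# from the package's vectorized implementations.

toy_atoms <- function(n, group = "protein_A", residue_name = "GLY",
                      name = "CA", element = "C", mass = 12,
                      segment = "PROA", residue_id = NULL) {
  tibble::tibble(
    atom_id = seq_len(n),
    name = name, element = element,
    residue_name = residue_name,
    residue_id = residue_id %||% seq_len(n),
    segment = segment,
    mass = mass, charge = 0, lj_epsilon = 0.1, lj_rmin_half = 2,
    group = group
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_frame <- function(n, box = c(50, 50, 50), seed = 1) {
  set.seed(seed)
  frame(matrix(runif(3 * n, 0, max(box)), n, 3) %*% diag(box / max(box)),
    box = box, time = 0
  )
}

# minimum-image displacement by explicit search over periodic images
# (wide enough for points several box lengths apart)
bf_min_image <- function(p, q, box) {
  best <- NULL
  best_d <- Inf
  for (i in -4:4) for (j in -4:4) for (k in -4:4) {
    d <- p - (q + c(i, j, k) * box)
    if (sum(d^2) < best_d) {
      best_d <- sum(d^2)
      best <- d
    }
  }
  best
}

bf_min_image_dist <- function(p, q, box) sqrt(sum(bf_min_image(p, q, box)^2))

# O(N^2) minimum pair distance with the 27-image search
bf_min_pair_distance <- function(A, B, box) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      best <- min(best, bf_min_image_dist(A[i, ], B[j, ], box))
    }
  }
  best
}

bf_center_of_mass <- function(coords, masses) {
  out <- c(0, 0, 0)
  for (i in seq_len(nrow(coords))) out <- out + masses[i] * coords[i, ]
  out / sum(masses)
}

bf_inertia <- function(coords, masses) {
  com <- bf_center_of_mass(coords, masses)
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, ] - com
    I <- I + masses[i] * (sum(r^2) * diag(3) - outer(r, r))
  }
  I
}

bf_pair_energy <- function(qi, qj, ei, ej, ri, rj, r) {
  332.0636 * qi * qj / r +
    sqrt(ei * ej) * (((ri + rj) / r)^12 - 2 * ((ri + rj) / r)^6)
}

# naive group-group energy, no cutoff
bf_group_energy <- function(frm, sys, selA, selB) {
  total <- 0
  for (i in selA) {
    for (j in selB) {
      r <- bf_min_image_dist(frm$coordinates[i, ], frm$coordinates[j, ], frm$box)
      total <- total + bf_pair_energy(
        sys$charge[i], sys$charge[j], sys$lj_epsilon[i], sys$lj_epsilon[j],
        sys$lj_rmin_half[i], sys$lj_rmin_half[j], r
      )
    }
  }
  total
}

# small mixed protein/lipid system with random coordinates, for census and
# energy oracles
random_interface_system <- function(n_protein = 50, n_lipid = 50,
                                    box = c(40, 40, 40), seed = 1) {
  set.seed(seed)
  # residue types are drawn per residue, atom names consistently with the
  # type (so e.g. NZ only appears inside LYS residues)
  prot_res <- rep(seq_len(ceiling(n_protein / 3)), each = 3)[seq_len(n_protein)]
  res_types <- sample(c("LYS", "GLU", "GLY"), max(prot_res), replace = TRUE)
  atom_name_for <- function(type, slot) {
    switch(type,
      LYS = c("NZ", "CA", "CB"),
      GLU = c("OE1", "CA", "CB"),
      GLY = c("CA", "CB", "C")
    )[slot]
  }
  slot <- stats::ave(prot_res, prot_res, FUN = seq_along)
  prot <- tibble::tibble(
    atom_id = seq_len(n_protein),
    name = mapply(atom_name_for, res_types[prot_res], slot),
    residue_name = res_types[prot_res],
    residue_id = prot_res,
    segment = "PROA",
    mass = 12, charge = runif(n_protein, -0.5, 0.5),
    lj_epsilon = runif(n_protein, 0, 0.2), lj_rmin_half = runif(n_protein, 1, 2.2),
    group = "protein_A"
  )
  prot$element <- substr(prot$name, 1, 1)
  lip_res <- 1000 + rep(seq_len(ceiling(n_lipid / 4)), each = 4)[seq_len(n_lipid)]
  lip_slot <- stats::ave(lip_res, lip_res, FUN = seq_along)
  lip <- tibble::tibble(
    atom_id = n_protein + seq_len(n_lipid),
    name = c("P", "O11", "N", "C2")[lip_slot],
    residue_id = lip_res,
    segment = "MEMB",
    mass = 15, charge = runif(n_lipid, -0.8, 0.8),
    lj_epsilon = runif(n_lipid, 0, 0.3), lj_rmin_half = runif(n_lipid, 1, 2.2)
  )
  lip$group <- c("DOPC", "DOPE", "DOPS")[(lip$residue_id %% 3) + 1]
  lip$element <- substr(lip$name, 1, 1)
  lip$residue_name <- lip$group
  atoms <- dplyr::bind_rows(prot, lip)
  sys <- system_model(atoms)
  frm <- frame(matrix(runif(3 * nrow(atoms), 0, box[1]), ncol = 3), box, 0)
  list(system = sys, frame = frm,
       protein_sel = seq_len(n_protein), lipid_sel = n_protein + seq_len(n_lipid))
}

# double-well analytic potential used across free-energy tests
double_well <- function(x) {
  -8.6 * exp(-x^2 / (2 * 1.5^2)) - 6 * exp(-(x - 3.5)^2 / (2 * 1^2))
}

double_well_barrier <- function() {
  xs <- seq(0, 3.5, 0.001)
  max(double_well(xs)) - min(double_well(seq(-5, 31, 0.001)))
}
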