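# two-residue fixture: one Lys NZ against one Glu OE1 at distance d
lys_glu_system <- function(d) {
  atoms <- tibble::tibble(
    atom_id = 1:2,
    name = c("NZ", "OE1"),
    element = c("N", "O"),
    residue_name = c("LYS", "GLU"),
    residue_id = c(10L, 20L),
    segment = "PROA",
    mass = c(14.007, 15.999), charge = c(-0.3, -0.76),
    lj_epsilon = 0.15, lj_rmin_half = 1.8,
    group = "protein_A"
  )
  list(
    system = system_model(atoms),
    frame = frame(rbind(c(0, 0, 0), c(d, 0, 0)), c(50, 50, 50), 0)
  )
}

test_that("contact detection honors the 5 A heavy-atom criterion exactly", {
  fx <- gen_planted_interface(0, 1, seed = 2)
  ps <- select_protein(fx$system)
  ls <- select_lipids(fx$system)
  ct <- find_contacts(fx$frame, fx$system, ps, ls)
  expect_equal(nrow(ct), 1)

  # boundary: 4.9 in, 5.1 out
  sys <- lys_glu_system(4.9)$system
  mk <- function(d) {
    atoms <- tibble::as_tibble(sys)
    atoms$group <- c("protein_A", "DOPS")
    atoms$residue_name <- c("LYS", "DOPS")
    s <- system_model(atoms)
    list(s = s, f = frame(rbind(c(0, 0, 0), c(d, 0, 0)), c(50, 50, 50), 0))
  }
  near <- mk(4.9)
  expect_equal(nrow(find_contacts(near$f, near$s, 1L, 2L)), 1)
  far <- mk(5.1)
  expect_equal(nrow(find_contacts(far$f, far$s, 1L, 2L)), 0)
})

test_that("salt bridges use the 3.2 A N-O criterion with group deduplication", {
  near <- lys_glu_system(3.1)
  sb <- find_salt_bridges(near$frame, near$system)
  expect_equal(nrow(sb), 1)
  expect_true(sb$intra_protein)
  expect_false(sb$protein_lipid)

  far <- lys_glu_system(3.3)
  expect_equal(nrow(find_salt_bridges(far$frame, far$system)), 0)

  # planted interfaces return exactly the planted number
  for (k in c(0, 3, 7)) {
    fx <- gen_planted_interface(k, 2, seed = k + 1)
    sb <- find_salt_bridges(fx$frame, fx$system)
    expect_equal(nrow(sb), k)
    if (k > 0) expect_true(all(sb$protein_lipid))
  }
})

test_that("census matches brute force on a random interface and is cutoff-monotone", {
  fx <- random_interface_system(50, 50, seed = 21)
  ct <- find_contacts(fx$frame, fx$system, fx$protein_sel, fx$lipid_sel, cutoff = 5)
  # brute-force re-derivation of residue-lipid contact pairs
  pairs <- character(0)
  for (i in fx$protein_sel) {
    for (j in fx$lipid_sel) {
      d <- bf_min_image_dist(
        fx$frame$coordinates[i, ], fx$frame$coordinates[j, ], fx$frame$box
      )
      if (d <= 5) {
        pairs <- c(pairs, paste(fx$system$residue_id[i], fx$system$residue_id[j]))
      }
    }
  }
  expect_equal(nrow(ct), length(unique(pairs)))
  expect_setequal(paste(ct$residue_id, ct$lipid_id), unique(pairs))

  # every default-cutoff salt bridge is also a contact, and counts are
  # monotone in the cutoff
  sb32 <- find_salt_bridges(fx$frame, fx$system, cutoff = 3.2)
  sb50 <- find_salt_bridges(fx$frame, fx$system, cutoff = 5)
  expect_gte(nrow(sb50), nrow(sb32))
  expect_true(all(sb32$min_distance <= 5))
})

test_that("census is invariant under global rotation and atom reordering", {
  fx <- gen_planted_interface(4, 3, seed = 5)
  n0 <- nrow(find_salt_bridges(fx$frame, fx$system))
  phi <- 0.53
  Rz <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
  big_box <- c(1000, 1000, 1000) # rotation breaks wrapping, so use a huge box
  rot <- frame(fx$frame$coordinates %*% t(Rz), big_box, 0)
  expect_equal(nrow(find_salt_bridges(rot, fx$system)), n0)

  # planted pairs survive coordinate wrapping
  co <- fx$frame$coordinates
  co[, 1] <- (co[, 1] + 123.4) %% fx$frame$box[1]
  wrapped <- frame(co, fx$frame$box, 0)
  expect_equal(nrow(find_salt_bridges(wrapped, fx$system)), n0)
  expect_equal(
    nrow(find_contacts(wrapped, fx$system, select_protein(fx$system), select_lipids(fx$system))),
    4 + 3
  )
})

test_that("hydrogen bonds require both distance and angle criteria", {
  atoms <- tibble::tibble(
    atom_id = 1:3,
    name = c("N", "HN", "O"),
    element = c("N", "H", "O"),
    residue_name = c("GLY", "GLY", "GLU"),
    residue_id = c(1L, 1L, 2L),
    segment = "PROA",
    mass = c(14, 1, 16), charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.5,
    group = "protein_A"
  )
  sys <- system_model(atoms)
  # ideal linear D-H...A at d(D-A) = 2.9
  lin <- frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)), c(50, 50, 50), 0)
  hb <- find_hydrogen_bonds(lin, sys, donors = 1L, acceptors = 3L)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$angle, 180)

  # 90-degree geometry rejected
  bent <- frame(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.5, 0)), c(50, 50, 50), 0)
  expect_equal(nrow(find_hydrogen_bonds(bent, sys, donors = 1L, acceptors = 3L)), 0)

  # donor without an attached hydrogen is skipped with a warning
  lone <- frame(rbind(c(0, 0, 0), c(10, 10, 10), c(2.9, 0, 0)), c(50, 50, 50), 0)
  expect_warning(
    out <- find_hydrogen_bonds(lone, sys, donors = 1L, acceptors = 3L),
    "hydrogen"
  )
  expect_equal(nrow(out), 0)
})

test_that("interface tallies aggregate per-frame counts to mean and sd", {
  fx <- gen_planted_interface(5, 4, seed = 8)
  frames <- lapply(0:9, function(t) frame(fx$frame$coordinates, fx$frame$box, t))
  traj <- trajectory(frames, fx$system)
  tl <- tally_interface(
    traj, fx$system, select_protein(fx$system), select_lipids(fx$system)
  )
  tot_sb <- dplyr::filter(tl, kind == "salt_bridge", class == "total")
  expect_equal(tot_sb$mean, 5)
  expect_equal(tot_sb$sd, 0)
  tot_ct <- dplyr::filter(tl, kind == "contact", class == "total")
  expect_equal(tot_ct$mean, 9)
  lys_sb <- dplyr::filter(tl, kind == "salt_bridge", class == "residue_type", level == "LYS")
  expect_equal(lys_sb$mean, 5)

  expect_error(
    tally_interface(traj, fx$system, select_protein(fx$system),
      select_lipids(fx$system),
      window = c(100, 200)
    ),
    "at least 2 frames"
  )

  # no contacts anywhere gives all-zero tallies
  far <- gen_planted_interface(0, 0, seed = 1)
  co <- far$frame$coordinates
  frames2 <- lapply(0:2, function(t) frame(co, far$frame$box, t))
  tl2 <- tally_interface(
    trajectory(frames2, far$system), far$system,
    select_protein(far$system), select_lipids(far$system)
  )
  expect_true(all(tl2$mean == 0))
})
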