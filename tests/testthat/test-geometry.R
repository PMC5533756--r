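test_that("center of mass matches hand and brute-force results", {
  sys <- system_model(toy_atoms(2))
  frm <- frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(10, 10, 10), 0)
  expect_equal(center_of_mass(frm, sys, 1:2), c(1, 0, 0))

  atoms <- toy_atoms(2)
  atoms$mass <- c(1, 3)
  sys2 <- system_model(atoms)
  frm2 <- frame(rbind(c(0, 0, 0), c(0, 0, 4)), c(10, 10, 10), 0)
  expect_equal(center_of_mass(frm2, sys2, 1:2)[3], 3)

  set.seed(3)
  atoms <- toy_atoms(20)
  atoms$mass <- runif(20, 1, 30)
  sys3 <- system_model(atoms)
  frm3 <- random_frame(20, seed = 3)
  expect_equal(
    center_of_mass(frm3, sys3, 1:20),
    bf_center_of_mass(frm3$coordinates, atoms$mass),
    tolerance = 1e-12
  )
  expect_error(center_of_mass(frm3, sys3, integer(0)), "empty")
})

test_that("principal axes diagonalize the inertia tensor with fixed ordering and sign", {
  sys <- system_model(toy_atoms(5))
  # near-rod along Z (tiny lateral spread keeps the geometry non-singular)
  rod <- frame(cbind(c(0.01, -0.01, 0, 0.01, -0.01), c(0, 0.01, -0.01, 0, 0.01),
    seq(-2, 2)
  ), c(10, 10, 10), 0)
  ax <- principal_axes(rod, sys, 1:5)
  expect_equal(abs(ax$axes[3, 1]), 1, tolerance = 1e-4) # long axis = Z
  expect_gte(ax$axes[3, 1], 0) # sign convention

  sq <- frame(rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(0, 0, 0)),
    c(10, 10, 10), 0
  )
  ax2 <- principal_axes(sq, sys, 1:5)
  expect_equal(abs(ax2$axes[3, 3]), 1, tolerance = 1e-12) # largest inertia = Z

  set.seed(9)
  atoms <- toy_atoms(30)
  atoms$mass <- runif(30, 1, 20)
  sys3 <- system_model(atoms)
  frm <- random_frame(30, seed = 9)
  ax3 <- principal_axes(frm, sys3, 1:30)
  I <- bf_inertia(frm$coordinates, atoms$mass)
  D <- t(ax3$axes) %*% I %*% ax3$axes
  expect_equal(diag(D), ax3$moments, tolerance = 1e-8)
  expect_lt(max(abs(D - diag(diag(D)))), 1e-6)
  expect_true(all(diff(ax3$moments) >= 0))

  collinear <- frame(cbind(seq(0, 4), 0, 0), c(10, 10, 10), 0)
  expect_error(principal_axes(collinear, sys, 1:5), "collinear")
})

test_that("theta measures the second-axis tilt and respects symmetries", {
  # a slab whose second principal axis is Z at rest
  gp <- as.matrix(expand.grid(x = seq(-8, 8, 2), y = c(-1, 0, 1), z = seq(-4, 4, 2)))
  sys <- system_model(toy_atoms(nrow(gp)))
  frm0 <- frame(gp, c(100, 100, 100), 0)
  expect_equal(theta_angle(frm0, sys, seq_len(nrow(gp))), 0, tolerance = 1e-8)

  # rotating by 30 degrees about the first (X) axis tilts theta to 30
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  frm30 <- frame(gp %*% t(R), c(100, 100, 100), 0)
  expect_equal(theta_angle(frm30, sys, seq_len(nrow(gp))), 30, tolerance = 1e-6)

  # second axis in the XY plane reads 90
  Ry <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0)) # 90 deg about Y
  Rx90 <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  frm90 <- frame(gp %*% t(Rx90), c(100, 100, 100), 0)
  expect_equal(theta_angle(frm90, sys, seq_len(nrow(gp))), 90, tolerance = 1e-6)

  # invariance under rotation about Z and translation
  phi <- 0.7
  Rz <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
  moved <- sweep(gp %*% t(R) %*% t(Rz), 2, c(5, -3, 11), "+")
  expect_equal(
    theta_angle(frame(moved, c(100, 100, 100), 0), sys, seq_len(nrow(gp))),
    30,
    tolerance = 1e-6
  )
})

test_that("binding coordinates combine COM separation, gap and minimum distance", {
  atoms <- toy_atoms(4)
  atoms$element <- "C"
  sys <- system_model(atoms)
  # protein atoms around z = 50, membrane around z = 20
  frm <- frame(rbind(
    c(10, 10, 49), c(12, 10, 51), # protein, COM z = 50
    c(10, 10, 19), c(12, 10, 21) # membrane, COM z = 20
  ), c(100, 100, 100), 0)
  bc <- binding_coordinates(frm, sys, 1:2, 3:4, reference_d_z = 25)
  expect_equal(bc$d_z, 30)
  expect_equal(bc$delta_d_z, 5)
  expect_equal(bc$gap_z, 49 - 21)

  # closest heavy atoms at z = 13 and 10 give gap 3
  frm2 <- frame(rbind(
    c(0, 0, 13), c(0, 0, 15),
    c(0, 0, 10), c(0, 0, 8)
  ), c(100, 100, 100), 0)
  bc2 <- binding_coordinates(frm2, sys, 1:2, 3:4, 0)
  expect_equal(bc2$gap_z, 3)
  expect_equal(bc2$min_pair_distance, 3)

  set.seed(12)
  sysr <- system_model(toy_atoms(24))
  frm3 <- random_frame(24, box = c(15, 15, 15), seed = 12)
  bc3 <- binding_coordinates(frm3, sysr, 1:12, 13:24, 0)
  expect_equal(
    bc3$min_pair_distance,
    bf_min_pair_distance(
      frm3$coordinates[1:12, ], frm3$coordinates[13:24, ], frm3$box
    ),
    tolerance = 1e-10
  )
  expect_lte(bc3$gap_z, bc3$min_pair_distance)
})

test_that("first contact reports the earliest frame within cutoff and its residue", {
  atoms <- dplyr::bind_rows(
    toy_atoms(1, residue_name = "LYS", name = "NZ", element = "N", residue_id = 152),
    dplyr::mutate(toy_atoms(1, group = "DOPS", residue_name = "DOPS", name = "P",
      element = "P", segment = "MEMB"
    ), atom_id = 2L, residue_id = 900L)
  )
  sys <- system_model(atoms)
  # descending protein atom crosses the 5 A cutoff at frame 12 (time 12)
  frames <- lapply(0:20, function(t) {
    frame(rbind(c(0, 0, 30 - t * 2.1), c(0, 0, 0)), c(100, 100, 100), t)
  })
  traj <- trajectory(frames, sys)
  fc <- first_contact_time(traj, sys, 1L, 2L, cutoff = 5)
  crossing <- which(30 - (0:20) * 2.1 <= 5)[1] - 1
  expect_equal(fc$time, crossing)
  expect_equal(fc$residue_id, 152)
  expect_equal(fc$residue_name, "LYS")

  # contact already in frame 0
  traj0 <- trajectory(list(frame(rbind(c(0, 0, 3), c(0, 0, 0)), c(100, 100, 100), 0)), sys)
  expect_equal(first_contact_time(traj0, sys, 1L, 2L)$time, 0)

  # never within cutoff
  traj_far <- trajectory(list(frame(rbind(c(0, 0, 40), c(0, 0, 0)), c(100, 100, 100), 0)), sys)
  expect_equal(nrow(first_contact_time(traj_far, sys, 1L, 2L)), 0)
})
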