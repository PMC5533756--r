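test_that("leaflet assignment splits lipids at the midplane with a documented tie rule", {
  m <- gen_membrane_surface("flat", n_lipids = c(DOPC = 32, DOPE = 32, DOPS = 8), seed = 1)
  hs <- select_headgroups(m$system)
  lf <- assign_leaflets(m$trajectory[[1]], m$system, hs)
  expect_equal(sum(lf$leaflet == "upper"), 36)
  expect_equal(sum(lf$leaflet == "lower"), 36)

  # the standard-sized bilayer splits 720/720
  m2 <- gen_membrane_surface("flat", seed = 2)
  lf2 <- assign_leaflets(m2$trajectory[[1]], m2$system, select_headgroups(m2$system))
  expect_equal(as.numeric(table(lf2$leaflet)), c(720, 720))

  # all at the same height: everything upper by the z >= midplane rule
  flat_rows <- tibble::as_tibble(m$system)
  co <- attr(m$system, "coordinates")
  co[, 3] <- rep(c(30.5, 29.726), nrow(co) / 2) # headgroup COMs all equal
  frm <- frame(co, m$trajectory[[1]]$box, 0)
  lf3 <- assign_leaflets(frm, m$system, hs)
  expect_true(all(lf3$leaflet == "upper"))
})

test_that("surface profile recovers flat and sinusoidal height fields", {
  m <- gen_membrane_surface("flat", z_upper = 30, z_lower = 5, nx = 32, seed = 3)
  hs <- select_headgroups(m$system)
  sp <- surface_profile(m$trajectory, m$system, hs, n_bins = 32)
  expect_equal(sp$h, rep(30, 32), tolerance = 1e-9)
  expect_false(any(sp$interpolated))

  m2 <- gen_membrane_surface("sinusoid", amplitude = 5, nx = 64, seed = 4)
  sp2 <- surface_profile(m2$trajectory, m2$system, select_headgroups(m2$system), n_bins = 64)
  expect_equal(sp2$h - 95, m2$height_fn(sp2$x), tolerance = 0.02)
})

test_that("curvature profile matches analytic curvature and is offset-invariant", {
  m <- gen_membrane_surface("flat", nx = 64, seed = 5)
  hs <- select_headgroups(m$system)
  sp <- surface_profile(m$trajectory, m$system, hs, n_bins = 64)
  cp <- curvature_profile(sp, smoothing_window = 1)
  expect_equal(cp$curvature, rep(0, 64), tolerance = 1e-10)
  expect_equal(attr(cp, "c_ave"), 0, tolerance = 1e-10)

  # gaussian bump apex within 2 percent at 64 bins, noise 0
  mb <- gen_membrane_surface("gaussian_bump", amplitude = 6, width = 60, nx = 64, seed = 6)
  spb <- surface_profile(mb$trajectory, mb$system, select_headgroups(mb$system), n_bins = 64)
  cpb <- curvature_profile(spb, smoothing_window = 1)
  truth <- max(mb$curvature_fn(spb$x))
  expect_lt(abs(max(cpb$curvature) - truth) / truth, 0.02)

  # circular-arc height field sampled directly: apex curvature ~ 1/R
  R <- 300
  box <- c(470, 90, 150)
  arc <- tibble::tibble(
    x = (seq_len(64) - 0.5) * box[1] / 64,
    h = sqrt(R^2 - ((seq_len(64) - 0.5) * box[1] / 64 - 235)^2) - R + 90,
    n_samples = 10, interpolated = FALSE
  )
  attr(arc, "box") <- box
  cpa <- curvature_profile(arc, smoothing_window = 1, footprint = c(200, 270))
  expect_lt(abs(attr(cpa, "c_max") - 10 / R) / (10 / R), 0.02)

  # adding a constant Z offset leaves curvature unchanged
  sp_off <- dplyr::mutate(spb, h = h + 17.3)
  attr(sp_off, "box") <- attr(spb, "box")
  cp_off <- curvature_profile(sp_off, smoothing_window = 1)
  expect_equal(cp_off$curvature, cpb$curvature, tolerance = 1e-12)
})

test_that("curvature estimates converge with resolution on noise-free surfaces", {
  errs <- sapply(c(16, 32, 64), function(nb) {
    m <- gen_membrane_surface("sinusoid", amplitude = 4, nx = nb, seed = 7)
    sp <- surface_profile(m$trajectory, m$system, select_headgroups(m$system), n_bins = nb)
    cp <- curvature_profile(sp, smoothing_window = 1)
    max(abs(cp$curvature - m$curvature_fn(sp$x)))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("curvature-to-diameter conversion is d = 2/C", {
  expect_equal(curvature_to_diameter(0.05), 40)
  expect_error(curvature_to_diameter(0), "undefined")
})

test_that("local density counts are conserved and localized", {
  m <- gen_membrane_surface("flat", nx = 32, seed = 8)
  hs <- select_headgroups(m$system)
  dens <- local_density(m$trajectory, m$system, hs, n_bins = 32, y_half_width = 1000)
  expect_equal(sum(dens$n_lipid), 720) # all upper-leaflet lipids counted
  # lattice occupancy is uniform across bins up to the partial last row
  expect_lte(max(dens$n_lipid) - min(dens$n_lipid), 2)

  # brute-force histogram agreement on random placements
  b <- gen_brownian_lipids(D = 0, n_steps = 0, n_lipids = 137, seed = 9)
  d2 <- local_density(b$trajectory, b$system, select_atoms(b$system, name = "P"),
    n_bins = 16, y_half_width = 1000
  )
  xs <- attr(b$system, "coordinates")[, 1]
  expect_equal(d2$n_lipid, as.numeric(tabulate(pmin(16, floor(xs / (470 / 16)) + 1), 16)))
})

test_that("lateral MSD is zero for immobile or Z-only motion and 4Dt for Brownian lipids", {
  b0 <- gen_brownian_lipids(D = 0, dt = 0.1, n_steps = 20, n_lipids = 10, seed = 10)
  msd0 <- lateral_msd(b0$trajectory, b0$system, select_atoms(b0$system, name = "P"),
    lags = c(0.5, 1), origin_spacing = 2
  )
  expect_equal(msd0$msd, c(0, 0))

  # pure Z motion leaves the lateral MSD at zero
  frames <- lapply(0:10, function(t) {
    co <- attr(b0$system, "coordinates")
    co[, 3] <- co[, 3] + t * 2
    frame(co, c(470, 90, 150), t * 0.1)
  })
  msdz <- lateral_msd(trajectory(frames), b0$system,
    select_atoms(b0$system, name = "P"),
    lags = 0.5, origin_spacing = 2
  )
  expect_equal(msdz$msd, 0)

  # 2D Brownian motion: <dr^2(t)> = 4 D t within 3 standard errors,
  # including across periodic wrapping
  b <- gen_brownian_lipids(D = 1.5, dt = 0.05, n_steps = 1500, n_lipids = 150,
    seed = 11, wrap = TRUE
  )
  msd <- lateral_msd(b$trajectory, b$system, select_atoms(b$system, name = "P"),
    lags = c(2, 5), origin_spacing = 25
  )
  for (i in seq_len(nrow(msd))) {
    expect_lt(abs(msd$msd[i] - 4 * 1.5 * msd$lag[i]), 3 * msd$se[i])
  }

  expect_error(
    lateral_msd(b0$trajectory, b0$system, select_atoms(b0$system, name = "P"), lags = 100),
    "exceeds"
  )
})
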