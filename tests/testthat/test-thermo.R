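test_that("superposition removes planted rigid-body motion exactly", {
  set.seed(51)
  n <- 12
  atoms <- toy_atoms(n)
  atoms$mass <- runif(n, 1, 20)
  sys <- system_model(atoms)
  ref <- matrix(rnorm(3 * n, sd = 6), n, 3)
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  moved <- sweep(ref %*% t(R), 2, c(4, -2, 7), "+")
  traj <- trajectory(list(
    frame(ref, c(100, 100, 100), 0),
    frame(moved, c(100, 100, 100), 1)
  ), sys)
  sup <- superpose(traj, sys, selection = seq_len(n))
  expect_lt(sup$rmsd$rmsd[2], 1e-10)
  expect_equal(sup$trajectory[[2]]$coordinates, ref, tolerance = 1e-8)
  # identity on already-aligned frames
  expect_lt(sup$rmsd$rmsd[1], 1e-12)

  # independent oracle: bio3d least-squares fit gives the same aligned RMSD
  xyz_fixed <- as.numeric(t(ref))
  xyz_mobile <- as.numeric(t(moved))
  fitted <- suppressWarnings(bio3d::fit.xyz(xyz_fixed, xyz_mobile))
  expect_lt(sqrt(mean((fitted - xyz_fixed)^2)), 1e-8)
})

test_that("quasi-harmonic spectra match direct covariance diagonalization", {
  lam <- c(4, 2.5, 1.2, 0.6, 0.3)
  g <- gen_gaussian_ensemble(lam, masses = rep(10, 5), n_frames = 3000, seed = 52)
  al <- superpose(g$trajectory, g$system, selection = 1:5)$trajectory
  spec <- covariance_pca(al, g$system, selection = 1:5)
  # recovery of the planted spectrum within 3 relative standard errors
  se_rel <- 3 * sqrt(2 / 3000)
  expect_equal(spec$lambda[1:5], g$truth$lambda, tolerance = 4 * se_rel)

  # brute-force oracle: eigenvalues of the mass-weighted covariance matrix
  X <- vapply(al, function(f) as.numeric(t(f$coordinates)) * sqrt(rep(10, 15)),
    numeric(15)
  )
  ev <- sort(eigen(stats::cov(t(X)), symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
  expect_equal(spec$lambda, ev[seq_len(nrow(spec))], tolerance = 1e-6)

  # rigid ensemble: spectrum empty after thresholding
  rigid <- trajectory(lapply(0:5, function(t) {
    frame(matrix(1:15, 5, 3), c(50, 50, 50), t)
  }), g$system)
  spec0 <- suppressWarnings(covariance_pca(rigid, g$system, selection = 1:5))
  expect_equal(nrow(spec0), 0)
  expect_warning(
    covariance_pca(trajectory(g$trajectory[1:4], g$system), g$system, selection = 1:5),
    "rank"
  )
})

test_that("quantum harmonic-oscillator entropy matches closed forms and limits", {
  expect_equal(internal_entropy(tibble::tibble(omega_rad_ps = numeric(0)), 300), 0)

  # one mode at beta hbar omega = 1: S/kB = 1/(e-1) - log(1 - 1/e)
  omega_x1 <- 1.380649e-23 * 300 / 1.054571817e-34 * 1e-12
  s <- internal_entropy(tibble::tibble(omega_rad_ps = omega_x1), 300)
  expect_equal(s / 0.0019872041, 1 / (exp(1) - 1) - log(1 - exp(-1)), tolerance = 1e-9)

  # classical limit: S -> kB (1 - log x) as x -> 0
  omega_small <- omega_x1 * 1e-4
  s_q <- internal_entropy(tibble::tibble(omega_rad_ps = omega_small), 300)
  s_cl <- internal_entropy(tibble::tibble(omega_rad_ps = omega_small), 300, classical = TRUE)
  expect_equal(s_q, s_cl, tolerance = 1e-4)
  expect_equal(s_cl / 0.0019872041, 1 - log(1e-4), tolerance = 1e-9)

  # monotone: softer modes carry more entropy
  s_soft <- internal_entropy(tibble::tibble(omega_rad_ps = omega_x1 * 0.5), 300)
  expect_gt(s_soft, s)
  expect_error(internal_entropy(tibble::tibble(omega_rad_ps = 1), -1), "temperature")
})

test_that("translational and rotational entropies match textbook evaluations", {
  # argon at 298.15 K and 1 atm: Sackur-Tetrode gives ~36.98 cal/mol/K
  v_ideal <- 1.380649e-23 * 298.15 / 101325 * 1e30
  tr <- trans_rot_entropy(39.948, c(1, 1, 1), 298.15, volume = v_ideal)
  expect_equal(tr$s_trans * 1000, 36.98, tolerance = 0.01)

  # doubling the mass raises S_trans by (3/2) kB log 2
  tr2 <- trans_rot_entropy(2 * 39.948, c(1, 1, 1), 298.15, volume = v_ideal)
  expect_equal(tr2$s_trans - tr$s_trans, 1.5 * 0.0019872041 * log(2), tolerance = 1e-10)

  # spherical rotor against an independently coded closed form
  I0 <- 5000 # amu A^2
  T0 <- 300
  I_si <- I0 * 1.66053906660e-27 * 1e-20
  theta <- (1.054571817e-34)^2 / (2 * I_si * 1.380649e-23)
  s_rot_ref <- (1.5 + log(sqrt(pi) * (T0 / theta)^1.5)) * 0.0019872041
  tr3 <- trans_rot_entropy(100, c(I0, I0, I0), T0)
  expect_equal(tr3$s_rot, s_rot_ref, tolerance = 1e-9)
  expect_error(trans_rot_entropy(-1, c(1, 1, 1), 300), "> 0")
})

test_that("ensemble entropy is recovered and invariant under rigid-body motion", {
  lam <- exp(seq(log(6), log(0.05), length.out = 18))
  g <- gen_gaussian_ensemble(lam, masses = rep(12, 8), n_frames = 4000, seed = 53)
  rep1 <- entropy_report(g$trajectory, g$system, selection = 1:8, fit_selection = 1:8)
  expect_equal(rep1$s_internal, g$truth$s_internal_300K, tolerance = 0.02)
  expect_equal(rep1$s_total, rep1$s_trans + rep1$s_rot + rep1$s_internal)

  # rigidly moving every frame leaves the internal entropy unchanged
  th <- 1.2
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- trajectory(lapply(g$trajectory, function(f) {
    frame(sweep(f$coordinates %*% t(R), 2, c(10, 20, 30), "+"), f$box, f$time)
  }), g$system)
  rep2 <- entropy_report(moved, g$system, selection = 1:8, fit_selection = 1:8)
  expect_equal(rep2$s_internal, rep1$s_internal, tolerance = 1e-6)
})

test_that("the thermodynamic cycle assembles components into the binding free energy", {
  comp <- tibble::tibble(de_protein = 226.0, minus_tds = 81.7, ddmu = -316.3)
  cyc <- assemble_cycle(comp)
  expect_equal(cyc$dg_b, -8.6, tolerance = 1e-12)

  zeros <- assemble_cycle(tibble::tibble(de_protein = 0, minus_tds = 0, ddmu = 0))
  expect_equal(zeros$dg_b, 0)

  # raising -T dS with the other terms fixed raises dG_B
  up <- assemble_cycle(tibble::tibble(de_protein = 226.0, minus_tds = 90, ddmu = -316.3))
  expect_gt(up$dg_b, cyc$dg_b)

  # correlation diagnostic between the solvation term and interaction energies
  series <- tibble::tibble(
    delta_d_z = c(0, 5, 10, 20, 30),
    de_protein = c(226, 150, 80, 20, 0),
    minus_tds = c(81.7, 60, 30, 10, 0),
    ddmu = c(-316.3, -230, -120, -32, 0)
  )
  cyc2 <- assemble_cycle(series, de_int = series$ddmu * 1.05 + 3)
  expect_equal(attr(cyc2, "cor_ddmu_de_int"), 1, tolerance = 1e-9)
  expect_equal(cyc2$dg_b, series$de_protein + series$minus_tds + series$ddmu)
  expect_error(assemble_cycle(series[, -2]), "lack")
  expect_error(assemble_cycle(series, de_int = 1:2), "grid")
})

test_that("tidiers and plots expose fitted objects in broom/ggplot style", {
  ws <- gen_umbrella_samples(
    double_well,
    tibble::tibble(center = seq(-2, 5, by = 1), k = 8, temperature = 300),
    n_per_window = 500, seed = 54
  )
  prof <- pmf(ws)
  td <- tidy(prof)
  expect_true(all(c("bin_center", "dg", "se") %in% names(td)))
  gl <- glance(prof)
  expect_equal(gl$n_windows, 8)
  expect_s3_class(autoplot(prof), "ggplot")

  m <- gen_membrane_surface("gaussian_bump", nx = 32, seed = 55)
  sp <- surface_profile(m$trajectory, m$system, select_headgroups(m$system), n_bins = 32)
  cp <- curvature_profile(sp, smoothing_window = 1)
  expect_s3_class(autoplot(cp), "ggplot")

  g <- gen_gaussian_ensemble(c(2, 1), masses = rep(10, 4), n_frames = 200, seed = 56)
  spec <- covariance_pca(
    superpose(g$trajectory, g$system, selection = 1:4)$trajectory,
    g$system, selection = 1:4
  )
  expect_true(all(c("n_modes", "s_internal") %in% names(glance(spec))))
})
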