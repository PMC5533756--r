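# Minimal atom templates used by the generators. Headgroup positions are
# what the membrane analyses consume, so lipids are represented by their
# headgroup atoms (N and P placed so the headgroup COM sits exactly on the
# generated surface); proteins by single-atom residues. Charges/LJ are
# nominal CHARMM-like values.
MASS_N <- 14.007
MASS_P <- 30.974
MASS_C <- 12.011
MASS_O <- 15.999

lipid_atom_rows <- function(lipid_type, residue_id, x, y, z_surface) {
  # N above, P below, offsets chosen so the mass-weighted COM z equals
  # z_surface exactly
  o_n <- 0.5
  o_p <- -o_n * MASS_N / MASS_P
  tibble(
    name = c("N", "P"),
    element = c("N", "P"),
    residue_name = lipid_type,
    residue_id = residue_id,
    segment = "MEMB",
    mass = c(MASS_N, MASS_P),
    charge = c(if (lipid_type == "DOPC") 0.35 else 0.25, 1.5),
    lj_epsilon = c(0.2, 0.585),
    lj_rmin_half = c(1.85, 2.15),
    group = lipid_type,
    x = x, y = y, z = z_surface + c(o_n, o_p)
  )
}

finalize_system <- function(rows) {
  rows$atom_id <- seq_len(nrow(rows))
  sys <- system_model(rows[, c(
    "atom_id", "name", "element", "residue_name", "residue_id", "segment",
    "mass", "charge", "lj_epsilon", "lj_rmin_half", "group"
  )])
  attr(sys, "coordinates") <- unname(as.matrix(rows[, c("x", "y", "z")]))
  sys
}

check_surface_shape <- function(shape) {
  if (!shape %in% c("flat", "sinusoid", "gaussian_bump")) {
    abort("shape must be flat, sinusoid or gaussian_bump")
  }
  shape
}

surface_height_fn <- function(shape, amplitude, wavelength, width, box) {
  switch(shape,
    flat = function(x) rep(0, length(x)),
    sinusoid = function(x) amplitude * sin(2 * pi * x / wavelength),
    gaussian_bump = function(x) amplitude * exp(-(x - box[1] / 2)^2 / (2 * width^2)),
    abort("shape must be flat, sinusoid or gaussian_bump")
  )
}

surface_curvature_fn <- function(shape, amplitude, wavelength, width, box,
                                 protein_above = TRUE) {
  h1 <- switch(shape,
    flat = function(x) rep(0, length(x)),
    sinusoid = function(x) amplitude * 2 * pi / wavelength * cos(2 * pi * x / wavelength),
    gaussian_bump = function(x) {
      u <- x - box[1] / 2
      -amplitude * u / width^2 * exp(-u^2 / (2 * width^2))
    }
  )
  h2 <- switch(shape,
    flat = function(x) rep(0, length(x)),
    sinusoid = function(x) -amplitude * (2 * pi / wavelength)^2 * sin(2 * pi * x / wavelength),
    gaussian_bump = function(x) {
      u <- x - box[1] / 2
      amplitude * (u^2 / width^2 - 1) / width^2 * exp(-u^2 / (2 * width^2))
    }
  )
  s <- if (protein_above) -1 else 1
  function(x) s * h2(x) / (1 + h1(x)^2)^1.5 * 10 # nm^-1
}

#' Generate a bilayer leaflet point cloud on an analytic surface
#'
#' Places lipid headgroups on a lattice over the box XY plane, on two
#' leaflets whose upper surface follows an analytic height field along X
#' (flat, sinusoid, or Gaussian bump), with optional Gaussian Z noise. Lipid
#' types are assigned at the 4:4:1 DOPC:DOPE:DOPS ratio by seeded shuffle.
#' The analytic curvature of the upper surface (sign positive toward a
#' protein above) is returned as the ground truth.
#'
#' @param shape `"flat"`, `"sinusoid"` or `"gaussian_bump"`.
#' @param n_lipids Named total lipid counts (default `c(DOPC = 640, DOPE =
#'   640, DOPS = 160)`, split evenly between leaflets).
#' @param box Box lengths, Angstrom (default `c(470, 90, 150)`).
#' @param amplitude Surface amplitude, Angstrom.
#' @param wavelength Sinusoid wavelength, Angstrom (default box X).
#' @param width Gaussian bump standard deviation, Angstrom.
#' @param noise_sd Z noise standard deviation, Angstrom.
#' @param z_upper,z_lower Base leaflet heights, Angstrom.
#' @param n_frames Number of frames (noise redrawn each frame).
#' @param dt Frame spacing, ns.
#' @param nx Lattice columns along X; set equal to the analysis bin count to
#'   sample the surface exactly at bin centers (default: chosen from the box
#'   aspect ratio).
#' @param seed RNG seed.
#' @return List: `system`, `trajectory`, `height_fn`, `curvature_fn`
#'   (nm^-1), `params`.
#' @export
gen_membrane_surface <- function(shape = "flat",
                                 n_lipids = c(DOPC = 640, DOPE = 640, DOPS = 160),
                                 box = c(470, 90, 150),
                                 amplitude = 6, wavelength = NULL, width = 60,
                                 noise_sd = 0, z_upper = 95, z_lower = 55,
                                 n_frames = 1, dt = 1, nx = NULL, seed = 1) {
  shape <- check_surface_shape(shape)
  wavelength <- wavelength %||% box[1]
  if (shape != "flat") {
    max_slope <- switch(shape,
      sinusoid = amplitude * 2 * pi / wavelength,
      gaussian_bump = amplitude / width * exp(-0.5)
    )
    if (max_slope > 1) abort("surface slope too steep for a height-field representation")
  }
  set.seed(seed)
  n_total <- sum(n_lipids)
  if (n_total %% 2 != 0) abort("total lipid count must be even (two leaflets)")
  n_leaf <- n_total / 2
  # lattice close to the box aspect ratio unless pinned to the bin grid
  nx <- nx %||% max(2, round(sqrt(n_leaf * box[1] / box[2])))
  ny <- ceiling(n_leaf / nx)
  gx <- (rep(seq_len(nx), times = ny) - 0.5) * box[1] / nx
  gy <- (rep(seq_len(ny), each = nx) - 0.5) * box[2] / ny
  gx <- gx[seq_len(n_leaf)]
  gy <- gy[seq_len(n_leaf)]
  h_fn <- surface_height_fn(shape, amplitude, wavelength, width, box)
  types <- sample(rep(names(n_lipids), times = n_lipids))
  rows <- list()
  for (leaf in c("upper", "lower")) {
    base_z <- if (leaf == "upper") z_upper else z_lower
    hz <- if (leaf == "upper") h_fn(gx) else rep(0, n_leaf)
    offset <- if (leaf == "upper") 0 else n_leaf
    for (i in seq_len(n_leaf)) {
      rows[[length(rows) + 1]] <- lipid_atom_rows(
        types[offset + i], offset + i, gx[i], gy[i], base_z + hz[i]
      )
    }
  }
  rows <- bind_rows(rows)
  sys <- finalize_system(rows)
  base_coords <- attr(sys, "coordinates")
  frames <- lapply(seq_len(n_frames), function(fi) {
    co <- base_coords
    if (noise_sd > 0) {
      # one Z offset per lipid so the headgroup COM is what fluctuates
      dz <- stats::rnorm(n_total, 0, noise_sd)
      co[, 3] <- co[, 3] + rep(dz, each = 2)
    }
    frame(co, box, (fi - 1) * dt)
  })
  list(
    system = sys,
    trajectory = trajectory(frames, system = sys),
    height_fn = h_fn,
    curvature_fn = surface_curvature_fn(shape, amplitude, wavelength, width, box),
    params = list(
      shape = shape, amplitude = amplitude, wavelength = wavelength,
      width = width, noise_sd = noise_sd, box = box, seed = seed
    )
  )
}

#' Generate an interface with planted salt bridges and contacts
#'
#' Builds a minimal protein-lipid interface with exactly `n_bridges`
#' lysine-NZ-to-phosphate-oxygen pairs at 2.8-3.1 Angstrom and `n_contacts`
#' additional glycine-CA-to-lipid pairs at 4.4-4.9 Angstrom; planted units
#' are spaced far apart so no unintended pairs fall within the detection
#' cutoffs.
#'
#' @param n_bridges,n_contacts Planted counts.
#' @param box Box lengths, Angstrom.
#' @param seed RNG seed.
#' @return List: `system`, `frame`, `truth` (planted distances).
#' @export
gen_planted_interface <- function(n_bridges, n_contacts, box = c(200, 200, 100),
                                  seed = 1) {
  set.seed(seed)
  n_units <- n_bridges + n_contacts
  if (n_units == 0) {
    sys <- finalize_system(tibble(
      name = character(0), element = character(0),
      residue_name = character(0), residue_id = integer(0),
      segment = character(0), mass = numeric(0), charge = numeric(0),
      lj_epsilon = numeric(0), lj_rmin_half = numeric(0),
      group = character(0), x = numeric(0), y = numeric(0), z = numeric(0)
    ))
    return(list(
      system = sys, frame = frame(matrix(numeric(0), 0, 3), box, 0),
      truth = list(
        n_bridges = 0, n_contacts = 0,
        bridge_distances = numeric(0), contact_distances = numeric(0)
      )
    ))
  }
  spacing <- 15
  per_row <- max(1, floor(box[1] / spacing))
  if (n_units > per_row * floor(box[2] / spacing)) {
    abort("too many planted units for the box")
  }
  rows <- list()
  res_id <- 0
  bridge_d <- stats::runif(max(n_bridges, 1), 2.8, 3.1)
  contact_d <- stats::runif(max(n_contacts, 1), 4.4, 4.9)
  for (u in seq_len(n_units)) {
    cx <- ((u - 1) %% per_row + 0.5) * spacing
    cy <- (floor((u - 1) / per_row) + 0.5) * spacing
    res_id <- res_id + 1
    lipid_id <- res_id
    # lipid: P at (cx, cy, 50), O11 1.6 A above it
    rows[[length(rows) + 1]] <- tibble(
      name = c("P", "O11"), element = c("P", "O"),
      residue_name = "DOPS", residue_id = lipid_id, segment = "MEMB",
      mass = c(MASS_P, MASS_O), charge = c(1.5, -0.78),
      lj_epsilon = c(0.585, 0.12), lj_rmin_half = c(2.15, 1.7),
      group = "DOPS",
      x = cx, y = cy, z = c(50, 51.6)
    )
    res_id <- res_id + 1
    if (u <= n_bridges) {
      d <- bridge_d[u]
      rows[[length(rows) + 1]] <- tibble(
        name = "NZ", element = "N", residue_name = "LYS",
        residue_id = res_id, segment = "PROA",
        mass = MASS_N, charge = -0.3, lj_epsilon = 0.2, lj_rmin_half = 1.85,
        group = "protein_A", x = cx, y = cy, z = 51.6 + d
      )
    } else {
      d <- contact_d[u - n_bridges]
      # contact below the lipid P, away from O11
      rows[[length(rows) + 1]] <- tibble(
        name = "CA", element = "C", residue_name = "GLY",
        residue_id = res_id, segment = "PROA",
        mass = MASS_C, charge = 0.07, lj_epsilon = 0.11, lj_rmin_half = 2.0,
        group = "protein_A", x = cx, y = cy, z = 50 - d
      )
    }
  }
  rows <- bind_rows(rows)
  sys <- finalize_system(rows)
  list(
    system = sys,
    frame = frame(attr(sys, "coordinates"), box, 0),
    truth = list(
      n_bridges = n_bridges, n_contacts = n_contacts,
      bridge_distances = if (n_bridges > 0) bridge_d[seq_len(n_bridges)] else numeric(0),
      contact_distances = if (n_contacts > 0) contact_d[seq_len(n_contacts)] else numeric(0)
    )
  )
}

#' Generate 2D Brownian lipid motion
#'
#' Independent Gaussian XY increments of variance `2 D dt` per axis per step;
#' Z fixed. Single-atom headgroups of type DOPC.
#'
#' @param D Diffusion coefficient, A^2/ns (>= 0).
#' @param dt Time step, ns.
#' @param n_steps Number of steps (frames = steps + 1).
#' @param n_lipids Number of lipids.
#' @param box Box lengths, Angstrom.
#' @param seed RNG seed.
#' @param wrap Wrap coordinates into the box (tests unwrapping).
#' @return List: `system`, `trajectory`, `params`.
#' @export
gen_brownian_lipids <- function(D, dt = 0.01, n_steps = 1000, n_lipids = 100,
                                box = c(470, 90, 150), seed = 1, wrap = FALSE) {
  if (D < 0) abort("D must be >= 0")
  set.seed(seed)
  rows <- tibble(
    name = "P", element = "P", residue_name = "DOPC",
    residue_id = seq_len(n_lipids), segment = "MEMB",
    mass = MASS_P, charge = 1.5, lj_epsilon = 0.585, lj_rmin_half = 2.15,
    group = "DOPC",
    x = stats::runif(n_lipids, 0, box[1]),
    y = stats::runif(n_lipids, 0, box[2]),
    z = 95
  )
  sys <- finalize_system(rows)
  co <- attr(sys, "coordinates")
  sd_step <- sqrt(2 * D * dt)
  frames <- vector("list", n_steps + 1)
  wrap_xy <- function(m) {
    if (!wrap) return(m)
    m[, 1] <- m[, 1] %% box[1]
    m[, 2] <- m[, 2] %% box[2]
    m
  }
  frames[[1]] <- frame(wrap_xy(co), box, 0)
  for (s in seq_len(n_steps)) {
    if (sd_step > 0) {
      co[, 1] <- co[, 1] + stats::rnorm(n_lipids, 0, sd_step)
      co[, 2] <- co[, 2] + stats::rnorm(n_lipids, 0, sd_step)
    }
    frames[[s + 1]] <- frame(wrap_xy(co), box, s * dt)
  }
  list(
    system = sys,
    trajectory = trajectory(frames, system = sys),
    params = list(D = D, dt = dt, n_steps = n_steps, n_lipids = n_lipids, seed = seed)
  )
}

# mass-weighted rigid-body basis (3 translations + 3 rotations) at reference
rigid_body_basis <- function(coords, masses) {
  n <- nrow(coords)
  sqm <- sqrt(masses)
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- sqm
  # rotations: dr = e_a x r
  cross <- list(
    function(v) cbind(0, -v[, 3], v[, 2]),
    function(v) cbind(v[, 3], 0, -v[, 1]),
    function(v) cbind(-v[, 2], v[, 1], 0)
  )
  for (a in 1:3) {
    d <- cross[[a]](r) * sqm
    B[, 3 + a] <- as.numeric(t(d))
  }
  qr.Q(qr(B))
}

#' Generate a Gaussian conformational ensemble with known mode spectrum
#'
#' Samples frames from a multivariate Gaussian in mass-weighted coordinates
#' whose covariance has the requested eigenvalues along random directions
#' orthogonal to the rigid-body subspace of a seeded reference structure, so
#' quasi-harmonic analysis has an exact ground truth.
#'
#' @param lambda Covariance eigenvalues, A^2 amu (positive, at most 3N - 6).
#' @param masses Atomic masses, amu (length N >= 3).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param spread Spatial extent of the seeded reference structure, Angstrom.
#' @return List: `system`, `trajectory`, `truth` (`lambda`, closed-form
#'   entropies at 300 K).
#' @export
gen_gaussian_ensemble <- function(lambda, masses, n_frames, seed = 1, spread = 10) {
  if (any(lambda <= 0)) abort("all eigenvalues must be positive")
  n <- length(masses)
  if (length(lambda) > 3 * n - 6) abort("at most 3N - 6 modes are available")
  set.seed(seed)
  ref <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
  rows <- tibble(
    name = "CA", element = "C", residue_name = "GLY",
    residue_id = seq_len(n), segment = "PROA",
    mass = masses, charge = 0, lj_epsilon = 0.11, lj_rmin_half = 2.0,
    group = "protein_A",
    x = ref[, 1], y = ref[, 2], z = ref[, 3]
  )
  sys <- finalize_system(rows)
  rigid <- rigid_body_basis(ref, masses)
  G <- matrix(stats::rnorm(3 * n * length(lambda)), 3 * n, length(lambda))
  G <- G - rigid %*% (t(rigid) %*% G)
  Q <- qr.Q(qr(G))
  sqm <- sqrt(rep(masses, each = 3))
  x0_mw <- as.numeric(t(ref)) * sqm
  Z <- matrix(stats::rnorm(n_frames * length(lambda)), length(lambda), n_frames)
  X_mw <- x0_mw + Q %*% (sqrt(lambda) * Z)
  frames <- lapply(seq_len(n_frames), function(i) {
    frame(matrix(X_mw[, i] / sqm, n, 3, byrow = TRUE), c(200, 200, 200), (i - 1) * 0.001)
  })
  spec_truth <- tibble(
    mode = seq_along(lambda),
    lambda = sort(lambda, decreasing = TRUE),
    omega_rad_ps = sqrt(KB_SI * 300 / (sort(lambda, decreasing = TRUE) * AMU_KG * 1e-20)) * 1e-12
  )
  list(
    system = sys,
    trajectory = trajectory(frames, system = sys),
    truth = list(
      lambda = sort(lambda, decreasing = TRUE),
      s_internal_300K = internal_entropy(spec_truth, 300)
    )
  )
}

#' Generate umbrella-window samples from an analytic potential
#'
#' Per-window Metropolis sampling of `exp(-beta (U(x) + bias))` with
#' burn-in, automatic step-size tuning to 30-60 percent acceptance, and
#' per-sample timestamps. All windows are advanced in lockstep (vectorized
#' chains).
#'
#' @param u_fn Analytic potential, kcal/mol, vectorized over x.
#' @param schedule Tibble `center`, `k`, `temperature` (default the
#'   standard binding schedule, [umbrella_schedule()]).
#' @param n_per_window Retained samples per window.
#' @param seed RNG seed.
#' @param burn_in Discarded initial steps (during which steps are tuned).
#' @param thin Keep every `thin`-th post-burn-in step (default 20, which
#'   leaves random-walk Metropolis chains effectively uncorrelated at these
#'   acceptance rates), the usual decorrelation practice.
#' @param total_time_ns Time span assigned to the retained samples
#'   (default 10).
#' @return List of [umbrella_window()]s.
#' @export
gen_umbrella_samples <- function(u_fn, schedule = umbrella_schedule(),
                                 n_per_window = 1000, seed = 1,
                                 burn_in = 500, thin = 20, total_time_ns = 10) {
  set.seed(seed)
  K <- nrow(schedule)
  beta <- 1 / kbt(schedule$temperature[1])
  x <- schedule$center
  step <- sqrt(1 / (beta * schedule$k)) * 2.5
  energy <- function(xv) beta * (u_fn(xv) + 0.5 * schedule$k * (xv - schedule$center)^2)
  e_cur <- energy(x)
  acc_win <- numeric(K)
  n_win <- 0
  samples <- matrix(0, n_per_window, K)
  n_steps <- burn_in + n_per_window * thin
  for (it in seq_len(n_steps)) {
    prop <- x + stats::rnorm(K, 0, step)
    e_prop <- energy(prop)
    accept <- log(stats::runif(K)) < (e_cur - e_prop)
    x[accept] <- prop[accept]
    e_cur[accept] <- e_prop[accept]
    acc_win <- acc_win + accept
    n_win <- n_win + 1
    if (it <= burn_in && n_win == 50) {
      rate <- acc_win / n_win
      step[rate < 0.35] <- step[rate < 0.35] * 0.8
      step[rate > 0.55] <- step[rate > 0.55] * 1.25
      acc_win[] <- 0
      n_win <- 0
    }
    if (it == burn_in) {
      acc_win[] <- 0
      n_win <- 0
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      samples[(it - burn_in) %/% thin, ] <- x
    }
  }
  rate <- acc_win / n_win
  if (any(rate < 0.3 | rate > 0.6)) {
    abort(sprintf(
      "Metropolis acceptance outside 30-60%% after tuning in %d window(s)",
      sum(rate < 0.3 | rate > 0.6)
    ))
  }
  times <- seq(0, total_time_ns, length.out = n_per_window)
  lapply(seq_len(K), function(kk) {
    umbrella_window(
      center = schedule$center[kk], k = schedule$k[kk],
      x = samples[, kk], temperature = schedule$temperature[kk], time = times
    )
  })
}

# rotation matrix about the X axis
rot_x <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(
    1, 0, 0,
    0, cos(th), -sin(th),
    0, sin(th), cos(th)
  ), 3, 3, byrow = TRUE)
}

#' Generate a scripted binding trajectory with ground truth
#'
#' Composite scene mirroring a spontaneous membrane-binding event: a rigid
#' slab-shaped two-protomer protein descends along Z while its orientation
#' angle relaxes linearly to zero, and the membrane's upper leaflet develops
#' a Gaussian bump under the protein in the final third of the trajectory.
#' The scripted first-contact time, orientation series and final apex
#' curvature are recorded as ground truth.
#'
#' @param n_frames Number of frames at 1-ns spacing.
#' @param theta0 Initial orientation angle, degrees.
#' @param z_start,z_end Initial and final protein-COM heights above the
#'   upper leaflet, Angstrom.
#' @param bump_amplitude Final bump amplitude, Angstrom.
#' @param bump_width Bump standard deviation, Angstrom.
#' @param n_lipids Total lipid counts by type.
#' @param box Box lengths.
#' @param seed RNG seed.
#' @return List: `system`, `trajectory`, `truth`.
#' @export
gen_binding_trajectory <- function(n_frames = 40, theta0 = 30,
                                   z_start = 45, z_end = 6,
                                   bump_amplitude = 5, bump_width = 40,
                                   n_lipids = c(DOPC = 160, DOPE = 160, DOPS = 40),
                                   box = c(240, 90, 200), seed = 1) {
  set.seed(seed)
  mem <- gen_membrane_surface(
    shape = "flat", n_lipids = n_lipids, box = box,
    z_upper = 95, z_lower = 55, n_frames = 1, seed = seed
  )
  mem_rows <- as_tibble(mem$system)
  mem_coords <- attr(mem$system, "coordinates")
  # rigid slab protein: lattice 9 x 3 x 5 scaled to 64 x 8 x 16 A so the
  # inertia order makes the second principal axis the slab normal (Z when
  # theta = 0)
  gp <- as.matrix(expand.grid(
    x = seq(-32, 32, length.out = 9),
    y = seq(-4, 4, length.out = 3),
    z = seq(-8, 8, length.out = 5)
  ))
  n_prot <- nrow(gp)
  half <- n_prot %/% 2
  prot_rows <- tibble(
    name = "CA", element = "C", residue_name = "LYS",
    residue_id = seq_len(n_prot), segment = ifelse(seq_len(n_prot) <= half, "PROA", "PROB"),
    mass = MASS_C, charge = 0.1, lj_epsilon = 0.11, lj_rmin_half = 2.0,
    group = ifelse(seq_len(n_prot) <= half, "protein_A", "protein_B"),
    x = 0, y = 0, z = 0
  )
  all_rows <- bind_rows(
    mutate(mem_rows, x = mem_coords[, 1], y = mem_coords[, 2], z = mem_coords[, 3]),
    prot_rows
  )
  all_rows$residue_id <- c(mem_rows$residue_id, prot_rows$residue_id + max(mem_rows$residue_id))
  sys <- finalize_system(all_rows)
  n_mem <- nrow(mem_rows)

  theta_t <- seq(theta0, 0, length.out = n_frames)
  z_offset_t <- seq(z_start, z_end, length.out = n_frames)
  bump_t <- pmax(0, (seq_len(n_frames) - ceiling(2 * n_frames / 3)) /
    (n_frames - ceiling(2 * n_frames / 3))) * bump_amplitude
  center_xy <- c(box[1] / 2, box[2] / 2)
  upper <- mem_rows$residue_id <= sum(n_lipids) / 2

  frames <- vector("list", n_frames)
  d_min <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    co_m <- mem_coords
    bump <- bump_t[i] * exp(-(co_m[, 1] - center_xy[1])^2 / (2 * bump_width^2))
    co_m[upper, 3] <- co_m[upper, 3] + bump[upper]
    co_p <- gp %*% t(rot_x(theta_t[i]))
    co_p <- sweep(co_p, 2, c(center_xy, 95 + z_offset_t[i]), "+")
    # scripted minimum protein-membrane distance (plain pairwise arithmetic)
    d2 <- outer(co_p[, 1], co_m[, 1], "-")^2 +
      outer(co_p[, 2], co_m[, 2], "-")^2 +
      outer(co_p[, 3], co_m[, 3], "-")^2
    d_min[i] <- sqrt(min(d2))
    frames[[i]] <- frame(rbind(co_m, co_p), box, i - 1)
  }
  traj <- trajectory(frames, system = sys)
  first_contact_frame <- which(d_min <= 5)[1]
  list(
    system = sys,
    trajectory = traj,
    truth = list(
      theta = tibble(time = frame_times(traj), theta = theta_t),
      first_contact_time = if (is.na(first_contact_frame)) NA_real_ else first_contact_frame - 1,
      final_bump_amplitude = bump_amplitude,
      final_c_max = bump_amplitude / bump_width^2 * 10, # nm^-1, apex of the bump
      bump_width = bump_width,
      min_distance = tibble(time = frame_times(traj), distance = d_min)
    )
  )
}
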