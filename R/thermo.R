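# Kabsch: optimal rotation R and translation aligning mobile onto ref
# (mass-weighted least squares). Returns list(R, t, rmsd).
kabsch <- function(mobile, ref, masses) {
  w <- masses / sum(masses)
  cm_m <- colSums(mobile * w)
  cm_r <- colSums(ref * w)
  A <- sweep(mobile, 2, cm_m)
  B <- sweep(ref, 2, cm_r)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  aligned <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - B)^2)))
  list(R = R, t = cm_r, rmsd = rmsd, aligned = sweep(aligned, 2, cm_r, "+"))
}

#' Rigid-body superposition of trajectory frames onto a reference
#'
#' Mass-weighted least-squares (Kabsch) superposition of each frame onto the
#' reference coordinates, using the given atom selection to define the fit;
#' all atoms are moved by the fitted transform.
#'
#' @param traj A [trajectory()].
#' @param system A [system_model()].
#' @param selection Atom indices defining the fit (default: C-alpha atoms of
#'   the protein; >= 3 non-collinear atoms required).
#' @param reference Reference coordinates (N x 3) for the selection frame of
#'   reference; defaults to the first frame.
#' @return List: `trajectory` (aligned), `rmsd` (tibble `time`, `rmsd`).
#' @export
superpose <- function(traj, system, selection = NULL, reference = NULL) {
  selection <- selection %||% select_atoms(
    system, group = c("protein_A", "protein_B"), name = "CA"
  )
  if (length(selection) < 3) abort("superposition needs at least 3 fit atoms")
  ref_all <- reference %||% traj[[1]]$coordinates
  ref <- ref_all[selection, , drop = FALSE]
  if (svd(sweep(ref, 2, colMeans(ref)))$d[2] < 1e-8) {
    abort("degenerate (collinear) reference geometry")
  }
  masses <- system$mass[selection]
  out <- vector("list", length(traj))
  rmsd <- numeric(length(traj))
  for (i in seq_along(traj)) {
    f <- traj[[i]]
    fit <- kabsch(f$coordinates[selection, , drop = FALSE], ref, masses)
    moved <- sweep(
      sweep(f$coordinates, 2, colSums(
        f$coordinates[selection, , drop = FALSE] * (masses / sum(masses))
      )) %*% t(fit$R),
      2, fit$t, "+"
    )
    out[[i]] <- frame(moved, f$box, f$time)
    rmsd[i] <- fit$rmsd
  }
  list(
    trajectory = trajectory(out, system = attr(traj, "system")),
    rmsd = tibble(time = frame_times(traj), rmsd = rmsd)
  )
}

#' Quasi-harmonic mode spectrum from a conformational ensemble
#'
#' Eigen-decomposition of the mass-weighted covariance matrix of atomic
#' displacements in an aligned ensemble. Each retained eigenvalue
#' `lambda_i` (A^2 amu) defines an effective frequency
#' `omega_i = sqrt(k_B T / lambda_i)`. The six smallest modes are dropped as
#' rigid-body remnants, as are modes with `lambda` below the rank threshold.
#'
#' @param traj An aligned [trajectory()] (see [superpose()]).
#' @param system A [system_model()].
#' @param selection Atom indices entering the covariance (default protein
#'   heavy atoms).
#' @param temperature Temperature in K for the effective frequencies.
#' @param lambda_min Rank-deficiency threshold, A^2 amu (default 1e-8).
#' @param drop_rigid Number of smallest modes dropped as rigid-body remnants
#'   (default 6).
#' @return A `mode_spectrum`: tibble `mode`, `lambda` (descending),
#'   `omega_rad_ps`; attributes `n_dropped`, `rank_deficient`, `temperature`.
#' @export
covariance_pca <- function(traj, system, selection = NULL, temperature = 300,
                           lambda_min = 1e-8, drop_rigid = 6) {
  if (length(traj) == 0) abort("no frames")
  selection <- selection %||% select_atoms(
    system, group = c("protein_A", "protein_B"), heavy_only = TRUE
  )
  n_atoms <- length(selection)
  n_frames <- length(traj)
  sqm <- sqrt(rep(system$mass[selection], each = 3))
  X <- vapply(
    traj,
    function(f) as.numeric(t(f$coordinates[selection, , drop = FALSE])) * sqm,
    numeric(3 * n_atoms)
  ) # (3N) x F
  mu <- rowMeans(X)
  Xc <- X - mu
  rank_deficient <- n_frames < 3 * n_atoms
  if (rank_deficient) {
    warn(sprintf(
      "only %d frames for %d coordinates; covariance is rank-deficient",
      n_frames, 3 * n_atoms
    ))
  }
  # eigenvalues of C = Xc Xc^T/(F-1) via the smaller Gram matrix
  if (n_frames < 3 * n_atoms) {
    ev <- eigen(crossprod(Xc) / (n_frames - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(tcrossprod(Xc) / (n_frames - 1), symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  n_modes <- max(0, min(length(ev), 3 * n_atoms) - drop_rigid)
  lambda <- ev[seq_len(n_modes)]
  below <- lambda < lambda_min
  n_dropped <- drop_rigid + sum(below)
  lambda <- lambda[!below]
  kT_si <- KB_SI * temperature
  omega_si <- sqrt(kT_si / (lambda * AMU_KG * 1e-20)) # 1/s
  out <- tibble(
    mode = seq_along(lambda),
    lambda = lambda,
    omega_rad_ps = omega_si * 1e-12
  )
  attr(out, "n_dropped") <- n_dropped
  attr(out, "rank_deficient") <- rank_deficient
  attr(out, "temperature") <- temperature
  class(out) <- c("mode_spectrum", class(out))
  out
}

#' Internal (quasi-harmonic) conformational entropy
#'
#' Quantum harmonic-oscillator entropy summed over the effective modes:
#' `S = k_B sum_i [ x_i/(exp(x_i)-1) - log(1-exp(-x_i)) ]` with
#' `x_i = hbar omega_i / k_B T`. The classical limit
#' `S -> k_B (1 - log x)` per mode is available as a flag.
#'
#' @param spectrum A [covariance_pca()] result (or tibble with
#'   `omega_rad_ps`).
#' @param temperature Temperature, K (> 0).
#' @param classical Use the classical HO entropy instead (default `FALSE`).
#' @return Entropy in kcal/mol/K.
#' @export
internal_entropy <- function(spectrum, temperature = 300, classical = FALSE) {
  if (temperature <= 0) abort("temperature must be > 0")
  if (nrow(spectrum) == 0) return(0)
  omega_si <- spectrum$omega_rad_ps * 1e12
  x <- HBAR_SI * omega_si / (KB_SI * temperature)
  s_per_mode <- if (classical) {
    1 - log(x)
  } else {
    x / (expm1(x)) - log1p(-exp(-x))
  }
  sum(s_per_mode) * KB_KCAL
}

#' Translational and rotational entropy of a rigid body
#'
#' Sackur-Tetrode translational entropy at a chosen standard-state volume and
#' the classical rigid-rotor rotational entropy (symmetry number 1).
#'
#' @param mass Total mass, amu.
#' @param inertia_moments Length-3 principal moments of inertia, amu A^2.
#' @param temperature Temperature, K.
#' @param volume Standard-state volume per molecule, A^3 (default the 1 M
#'   volume, 1660.5 A^3).
#' @return Tibble: `s_trans`, `s_rot` in kcal/mol/K.
#' @export
trans_rot_entropy <- function(mass, inertia_moments, temperature = 300,
                              volume = STD_VOLUME_1M) {
  if (mass <= 0 || any(inertia_moments <= 0) || volume <= 0 || temperature <= 0) {
    abort("mass, inertia moments, volume and temperature must all be > 0")
  }
  m_kg <- mass * AMU_KG
  lambda_th <- PLANCK_SI / sqrt(2 * pi * m_kg * KB_SI * temperature) # m
  v_m3 <- volume * 1e-30
  s_trans_kb <- log(v_m3 / lambda_th^3) + 2.5
  I_si <- inertia_moments * AMU_KG * 1e-20 # kg m^2
  theta_rot <- HBAR_SI^2 / (2 * I_si * KB_SI) # K
  s_rot_kb <- 1.5 + log(sqrt(pi) * sqrt(prod(temperature / theta_rot)))
  tibble(
    s_trans = s_trans_kb * KB_KCAL,
    s_rot = s_rot_kb * KB_KCAL
  )
}

#' Total protein entropy report
#'
#' Sum of translational, rotational and internal quasi-harmonic entropies of
#' a conformational ensemble.
#'
#' @param traj A [trajectory()] of the protein ensemble (will be superposed).
#' @param system A [system_model()].
#' @param selection Atoms entering the covariance (default protein heavy
#'   atoms); the rigid-body terms use all selected atoms' mass and inertia of
#'   the first frame.
#' @param fit_selection Atoms defining the superposition (default C-alpha).
#' @param temperature Temperature, K.
#' @param volume Standard-state volume per molecule, A^3.
#' @return Tibble: `s_trans`, `s_rot`, `s_internal`, `s_total` (kcal/mol/K),
#'   `temperature`, `volume`, `n_modes`.
#' @export
entropy_report <- function(traj, system, selection = NULL, fit_selection = NULL,
                           temperature = 300, volume = STD_VOLUME_1M) {
  selection <- selection %||% select_atoms(
    system, group = c("protein_A", "protein_B"), heavy_only = TRUE
  )
  aligned <- superpose(traj, system, selection = fit_selection)$trajectory
  spec <- covariance_pca(aligned, system, selection, temperature)
  s_int <- internal_entropy(spec, temperature)
  I <- inertia_tensor(
    aligned[[1]]$coordinates[selection, , drop = FALSE],
    system$mass[selection]
  )
  tr <- trans_rot_entropy(
    sum(system$mass[selection]),
    eigen(I, symmetric = TRUE, only.values = TRUE)$values,
    temperature, volume
  )
  tibble(
    s_trans = tr$s_trans, s_rot = tr$s_rot, s_internal = s_int,
    s_total = tr$s_trans + tr$s_rot + s_int,
    temperature = temperature, volume = volume, n_modes = nrow(spec)
  )
}

#' Assemble the thermodynamic cycle of membrane binding
#'
#' Combines the conformational energy change of the protein, the
#' conformational-entropy term and the solvation term into the binding free
#' energy `dG_B = dE_protein + (-T dS) + ddmu` on a shared reaction-coordinate
#' grid. When a total interaction-energy series is also supplied, its
#' correlation with the solvation term is reported (the proxy justification
#' for reading `ddmu` off interaction energies).
#'
#' @param components Data frame with columns `delta_d_z` (or a single row
#'   without it), `de_protein`, `minus_tds`, `ddmu`, all kcal/mol.
#' @param de_int Optional numeric vector (same grid) of total interaction
#'   energies for the correlation check.
#' @return A `cycle_components` tibble: inputs plus `dg_b`; attribute
#'   `cor_ddmu_de_int` when `de_int` given.
#' @export
assemble_cycle <- function(components, de_int = NULL) {
  req <- c("de_protein", "minus_tds", "ddmu")
  missing_cols <- setdiff(req, names(components))
  if (length(missing_cols) > 0) {
    abort(paste0("components lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(components) |>
    mutate(dg_b = .data$de_protein + .data$minus_tds + .data$ddmu)
  if (!is.null(de_int)) {
    if (length(de_int) != nrow(out)) abort("de_int length does not match the grid")
    attr(out, "cor_ddmu_de_int") <- if (nrow(out) >= 3) {
      stats::cor(out$ddmu, de_int)
    } else NA_real_
  }
  class(out) <- c("cycle_components", class(out))
  out
}
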