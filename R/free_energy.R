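#' Construct an umbrella-sampling window
#'
#' @param center Restraint center along the reaction coordinate, Angstrom.
#' @param k Harmonic force constant, kcal/mol/A^2 (default 50).
#' @param x Samples of the reaction coordinate, Angstrom.
#' @param temperature Temperature, K (default 300).
#' @param time Optional per-sample timestamps, ns.
#' @param equilibration Initial time span to discard, ns (default 0; applied
#'   only when `time` is present).
#' @return An `umbrella_window`.
#' @export
umbrella_window <- function(center, k = 50, x, temperature = 300, time = NULL,
                            equilibration = 0) {
  if (k <= 0) abort("force constant must be > 0")
  if (!is.null(time)) {
    if (length(time) != length(x)) abort("time and x lengths differ")
    keep <- time >= (min(time) + equilibration)
    x <- x[keep]
    time <- time[keep]
  }
  if (length(x) < 1) abort("window retains no samples")
  structure(
    list(center = center, k = k, x = x, temperature = temperature, time = time),
    class = "umbrella_window"
  )
}

#' Harmonic umbrella bias energy
#'
#' @param window An [umbrella_window()] (or list with `center`, `k`).
#' @param x Reaction-coordinate values, Angstrom.
#' @return `0.5 k (x - center)^2` in kcal/mol.
#' @export
bias_energy <- function(window, x) {
  0.5 * window$k * (x - window$center)^2
}

#' The umbrella-window schedule used for the binding profile
#'
#' Centers every 0.5 Angstrom from -4.0 to 30.5 plus a finer 0.1-Angstrom
#' sweep from 3.6 to 3.9, force constant 50 kcal/mol/A^2, 300 K.
#'
#' @return Tibble: `center`, `k`, `temperature`.
#' @export
umbrella_schedule <- function() {
  centers <- sort(unique(round(c(seq(-4, 30.5, by = 0.5), seq(3.6, 3.9, by = 0.1)), 6)))
  tibble(center = centers, k = 50, temperature = 300)
}

# pooled sample vector, counts, and the K x N reduced bias matrix beta*b_k(x_n)
mbar_inputs <- function(windows) {
  temps <- vapply(windows, function(w) w$temperature, numeric(1))
  if (length(unique(temps)) != 1) abort("all windows must share one temperature")
  beta <- 1 / kbt(temps[1])
  x <- unlist(lapply(windows, function(w) w$x), use.names = FALSE)
  n_k <- vapply(windows, function(w) length(w$x), numeric(1))
  K <- length(windows)
  u <- matrix(0, K, length(x))
  for (kk in seq_len(K)) u[kk, ] <- beta * bias_energy(windows[[kk]], x)
  list(x = x, n_k = n_k, u = u, beta = beta, temperature = temps[1])
}

col_lse <- function(a) {
  # log-sum-exp over rows of a (K x N), vectorized over columns
  cm <- do.call(pmax, lapply(seq_len(nrow(a)), function(k) a[k, ]))
  cm + log(colSums(exp(sweep(a, 2, cm, "-"))))
}

row_lse <- function(a) {
  rm <- apply(a, 1, max)
  rm + log(rowSums(exp(a - rm)))
}

mbar_logdenom <- function(u, f, log_n) {
  col_lse(sweep(-u, 1, f + log_n, "+"))
}

#' Solve the multistate Bennett acceptance ratio equations
#'
#' Finds the dimensionless window free energies `f_k` satisfying the
#' self-consistent MBAR equations for a set of umbrella windows, anchored at
#' `f_1 = 0`. A few self-consistent sweeps are followed by damped
#' Newton-Raphson steps on the equivalent convex objective until the maximum
#' change in any `f_k` falls below `tol` (iteration cap `max_iter`, default
#' 1000; exceeding it is an error carrying the last gradient norm). A window
#' overlap matrix (fraction of each window's samples whose dominant weight
#' sits in each state) is attached as a diagnostic, and non-overlapping
#' window sets trigger a warning.
#'
#' @param windows List of [umbrella_window()]s (>= 2) sharing a temperature.
#' @param tol Convergence threshold on `max |delta f|` in kcal/mol units of
#'   free energy (internally dimensionless; default 1e-8 kcal/mol).
#' @param max_iter Iteration cap.
#' @param n_sc Number of initial self-consistent sweeps (default 5).
#' @return An `mbar_fit`: list with `f` (tibble `center`, `k`, `f_kcal`),
#'   `f_dimensionless`, `logdenom` (per pooled sample), `x`, `n_k`, `beta`,
#'   `iterations`, `converged`, `overlap`.
#' @export
mbar_solve <- function(windows, tol = 1e-8, max_iter = 1000, n_sc = 5) {
  if (length(windows) < 1) abort("need at least 1 window")
  inp <- mbar_inputs(windows)
  if (length(windows) == 1) {
    # single state: f is trivially 0 and weights are the biased weights
    kT <- 1 / inp$beta
    return(structure(
      list(
        f = tibble(
          center = windows[[1]]$center, k = windows[[1]]$k, f_kcal = 0
        ),
        f_dimensionless = 0,
        logdenom = as.numeric(log(inp$n_k) - inp$u[1, ]),
        x = inp$x, n_k = inp$n_k, beta = inp$beta,
        temperature = inp$temperature,
        iterations = 0, converged = TRUE, overlap = matrix(1, 1, 1)
      ),
      class = "mbar_fit"
    ))
  }
  u <- inp$u
  n_k <- inp$n_k
  K <- nrow(u)
  log_n <- log(n_k)
  tol_dimless <- tol * inp$beta
  f <- numeric(K)
  converged <- FALSE
  iter <- 0
  grad_norm <- Inf
  # convex MBAR objective (up to a constant); its Newton direction with an
  # Armijo backtracking line search after a few self-consistent warm-up
  # sweeps
  objective <- function(ld_vec) sum(ld_vec) - sum(n_k * f_try)
  f_try <- f
  logdenom <- mbar_logdenom(u, f, log_n)
  phi <- sum(logdenom) - sum(n_k * f)
  while (iter < max_iter) {
    iter <- iter + 1
    ld_new <- NULL
    # E_kn = exp(-u_kn - logdenom_n): rowSums give the self-consistent
    # update; row scaling gives the Newton weight matrix
    E <- exp(-sweep(u, 2, logdenom, "+"))
    rs <- rowSums(E)
    if (iter <= n_sc) {
      f_new <- -log(rs)
      f_new <- f_new - f_new[1]
    } else {
      scale_k <- n_k * exp(f)
      g <- rs * scale_k - n_k
      grad_norm <- max(abs(g))
      W <- E * scale_k
      H <- diag(rowSums(W), K) - tcrossprod(W)
      step <- numeric(K)
      sol <- tryCatch(
        solve(H[-1, -1, drop = FALSE], -g[-1]),
        error = function(e) NULL
      )
      if (is.null(sol)) {
        f_new <- -log(rs) - (-log(rs))[1]
      } else {
        step[-1] <- sol
        gd <- sum(g * step)
        gamma <- 1
        ld_new <- NULL
        repeat {
          f_try <- f + gamma * step
          ld_try <- mbar_logdenom(u, f_try, log_n)
          phi_try <- sum(ld_try) - sum(n_k * f_try)
          if (is.finite(phi_try) && phi_try <= phi + 1e-4 * gamma * gd) {
            ld_new <- ld_try - f_try[1] # re-anchoring shifts logdenom too
            break
          }
          gamma <- gamma / 2
          if (gamma < 1 / 64) break
        }
        f_new <- f_try - f_try[1]
      }
    }
    delta <- max(abs(f_new - f))
    f <- f_new
    if (!is.null(ld_new)) {
      logdenom <- ld_new
      ld_new <- NULL
    } else {
      logdenom <- mbar_logdenom(u, f, log_n)
    }
    phi <- sum(logdenom) - sum(n_k * f)
    if (delta < tol_dimless) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "MBAR did not converge in %d iterations (last gradient norm %.3g)",
      max_iter, grad_norm
    ))
  }
  logdenom <- mbar_logdenom(u, f, log_n)
  # overlap diagnostic: O_kj = expected fraction of state-k weight among
  # samples generated in window j
  W <- exp(-sweep(u, 2, logdenom, "+") + f) # K x N, Sum_k N_k W_kn = 1
  bounds <- c(0, cumsum(n_k))
  overlap <- matrix(0, K, K)
  for (j in seq_len(K)) {
    idx <- (bounds[j] + 1):bounds[j + 1]
    overlap[, j] <- rowMeans(W[, idx, drop = FALSE]) * n_k
  }
  neighbor_overlap <- if (K > 1) {
    ords <- order(vapply(windows, function(w) w$center, numeric(1)))
    min(vapply(seq_len(K - 1), function(i) {
      overlap[ords[i], ords[i + 1]] + overlap[ords[i + 1], ords[i]]
    }, numeric(1)))
  } else 1
  if (neighbor_overlap < 1e-6) {
    warn("adjacent umbrella windows barely overlap; free energies are unreliable")
  }
  kT <- 1 / inp$beta
  structure(
    list(
      f = tibble(
        center = vapply(windows, function(w) w$center, numeric(1)),
        k = vapply(windows, function(w) w$k, numeric(1)),
        f_kcal = f * kT
      ),
      f_dimensionless = f,
      logdenom = logdenom,
      x = inp$x,
      n_k = n_k,
      beta = inp$beta,
      temperature = inp$temperature,
      iterations = iter,
      converged = converged,
      overlap = overlap
    ),
    class = "mbar_fit"
  )
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf(
    "<mbar_fit> %d windows, %d samples, converged in %d iterations at %g K\n",
    nrow(x$f), length(x$x), x$iterations, x$temperature
  ))
  invisible(x)
}

#' MBAR free energies by direct minimization of the convex objective
#'
#' Independent solution route: minimizes the MBAR log-likelihood objective
#' `sum_n log sum_k N_k exp(f_k - u_kn) - sum_k N_k f_k` over `f_2..f_K` with
#' L-BFGS-B and the analytic gradient. Used as a cross-check against
#' [mbar_solve()]; the two must agree to high precision on shared input.
#'
#' @inheritParams mbar_solve
#' @return Numeric vector of dimensionless free energies anchored at
#'   `f_1 = 0`.
#' @export
mbar_objective_solve <- function(windows, tol = 1e-12) {
  inp <- mbar_inputs(windows)
  u <- inp$u
  log_n <- log(inp$n_k)
  n_k <- inp$n_k
  K <- nrow(u)
  obj <- function(ftail) {
    f <- c(0, ftail)
    sum(mbar_logdenom(u, f, log_n)) - sum(n_k * f)
  }
  grd <- function(ftail) {
    f <- c(0, ftail)
    ld <- mbar_logdenom(u, f, log_n)
    W <- exp(-sweep(u, 2, ld, "+") + f + log_n)
    (rowSums(W) - n_k)[-1]
  }
  fit <- stats::optim(
    par = numeric(K - 1), fn = obj, gr = grd, method = "L-BFGS-B",
    control = list(maxit = 5000, factr = 10, pgtol = 1e-12)
  )
  # polish with plain first-order fixed-point sweeps (no Newton involved);
  # intended for modest problem sizes, where it reaches ~1e-8 precision
  f <- c(0, fit$par)
  for (it in seq_len(30000)) {
    ld <- mbar_logdenom(u, f, log_n)
    f_new <- -row_lse(-sweep(u, 2, ld, "+"))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < 1e-12) break
  }
  f
}

#' Potential of mean force from MBAR weights
#'
#' Bins the pooled reaction-coordinate samples and converts unbiased MBAR
#' weights to per-bin free energies `-kT log p_i`, anchored so the global
#' minimum is exactly zero. Empty bins are kept, flagged, and carry `NA`
#' free energy. The per-bin uncertainty is a counting estimate
#' `kT / sqrt(n_eff)` with `n_eff` the Kish effective sample size of the
#' weights in the bin; see [pmf_bootstrap()] for resampled uncertainties.
#'
#' @param windows List of [umbrella_window()]s.
#' @param fit An [mbar_solve()] result for those windows (computed if
#'   `NULL`).
#' @param bin_edges Bin edges along the reaction coordinate, Angstrom
#'   (default: 0.5-Angstrom bins spanning the samples).
#' @return A `free_energy_profile`: tibble `bin_center`, `dg` (kcal/mol),
#'   `se`, `n_samples`, `n_eff`, `empty`; attributes `fit`, `kT`.
#' @export
pmf <- function(windows, fit = NULL, bin_edges = NULL) {
  fit <- fit %||% mbar_solve(windows)
  x <- fit$x
  if (is.null(bin_edges)) {
    lo <- floor(min(x) / 0.5) * 0.5
    hi <- ceiling(max(x) / 0.5) * 0.5
    bin_edges <- seq(lo, hi, by = 0.5)
  }
  nb <- length(bin_edges) - 1
  centers <- (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2
  logw <- -fit$logdenom # unbiased log weights (unnormalized)
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= nb
  kT <- 1 / fit$beta
  dg <- rep(NA_real_, nb)
  n_eff <- rep(NA_real_, nb)
  n_samp <- tabulate(bin[inside], nbins = nb)
  for (i in seq_len(nb)) {
    sel <- inside & bin == i
    if (!any(sel)) next
    lw <- logw[sel]
    m <- max(lw)
    s1 <- sum(exp(lw - m))
    s2 <- sum(exp(2 * (lw - m)))
    dg[i] <- -kT * (m + log(s1))
    n_eff[i] <- s1^2 / s2
  }
  dg <- dg - min(dg, na.rm = TRUE)
  out <- tibble(
    bin_center = centers,
    dg = dg,
    se = kT / sqrt(n_eff),
    n_samples = n_samp,
    n_eff = n_eff,
    empty = n_samp == 0
  )
  attr(out, "fit") <- fit
  attr(out, "kT") <- kT
  class(out) <- c("free_energy_profile", class(out))
  out
}

#' Bootstrap uncertainties for a free-energy profile
#'
#' Block bootstrap over whole windows: windows are resampled with
#' replacement, the MBAR equations re-solved and the profile re-binned for
#' each resample; the per-bin standard deviation across resamples is the
#' uncertainty.
#'
#' @param windows List of [umbrella_window()]s.
#' @param bin_edges Bin edges (as in [pmf()]).
#' @param n_boot Number of resamples (default 200).
#' @param seed RNG seed.
#' @return Tibble: `bin_center`, `dg`, `se_boot`, `n_ok` (resamples with the
#'   bin populated).
#' @export
pmf_bootstrap <- function(windows, bin_edges = NULL, n_boot = 200, seed = 1) {
  base <- pmf(windows, bin_edges = bin_edges)
  if (is.null(bin_edges)) {
    nb <- nrow(base)
    half <- diff(base$bin_center[1:2]) / 2
    bin_edges <- c(base$bin_center - half, base$bin_center[nb] + half)
  }
  set.seed(seed)
  boots <- matrix(NA_real_, nrow(base), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample(length(windows), replace = TRUE)
    prof <- tryCatch(
      pmf(windows[idx], bin_edges = bin_edges),
      error = function(e) NULL
    )
    if (!is.null(prof)) boots[, b] <- prof$dg
  }
  tibble(
    bin_center = base$bin_center,
    dg = base$dg,
    se_boot = apply(boots, 1, stats::sd, na.rm = TRUE),
    n_ok = rowSums(!is.na(boots))
  )
}

#' Cumulative-block convergence of the free-energy profile
#'
#' Recomputes the profile on cumulative time blocks of the window samples
#' (each sample must carry a timestamp) and tabulates pairwise maximum
#' deviations between block profiles over bins populated in both.
#'
#' @param windows List of [umbrella_window()]s whose samples carry `time`.
#' @param block_ends Cumulative block end times, ns (e.g. `c(2, 4, 6, 8,
#'   10)`).
#' @param bin_edges Bin edges shared across blocks.
#' @return List with `profiles` (tibble of per-block profiles, column
#'   `block_end`) and `deviations` (tibble `block_a`, `block_b`,
#'   `max_abs_dev`).
#' @export
convergence_blocks <- function(windows, block_ends, bin_edges = NULL) {
  has_time <- all(vapply(windows, function(w) !is.null(w$time), logical(1)))
  if (!has_time) abort("all window samples must carry timestamps")
  t0 <- min(vapply(windows, function(w) min(w$time), numeric(1)))
  tmax <- max(vapply(windows, function(w) max(w$time), numeric(1)))
  if (any(block_ends > tmax - t0 + 1e-9)) abort("block extends beyond the sampled time span")
  if (is.null(bin_edges)) {
    x_all <- unlist(lapply(windows, function(w) w$x))
    lo <- floor(min(x_all) / 0.5) * 0.5
    hi <- ceiling(max(x_all) / 0.5) * 0.5
    bin_edges <- seq(lo, hi, by = 0.5)
  }
  profs <- purrr::map_dfr(block_ends, function(be) {
    ws <- lapply(windows, function(w) {
      keep <- w$time - t0 <= be + 1e-9
      umbrella_window(w$center, w$k, w$x[keep], w$temperature, w$time[keep])
    })
    prof <- pmf(ws, bin_edges = bin_edges)
    mutate(as_tibble(prof), block_end = be)
  })
  devs <- list()
  for (a in seq_along(block_ends)) {
    for (b in seq_along(block_ends)) {
      if (b <= a) next
      pa <- filter(profs, .data$block_end == block_ends[a])
      pb <- filter(profs, .data$block_end == block_ends[b])
      ok <- !pa$empty & !pb$empty
      devs[[length(devs) + 1]] <- tibble(
        block_a = block_ends[a], block_b = block_ends[b],
        max_abs_dev = max(abs(pa$dg[ok] - pb$dg[ok]))
      )
    }
  }
  list(profiles = profs, deviations = bind_rows(devs))
}

#' Binned WHAM free-energy profile
#'
#' Classic weighted-histogram analysis: self-consistent iteration between bin
#' probabilities and window normalization constants on a fixed grid. Included
#' as an independent cross-check of the MBAR route; the two agree within
#' statistical error for well-sampled input.
#'
#' @param windows List of [umbrella_window()]s.
#' @param bin_edges Bin edges along the reaction coordinate.
#' @param tol Convergence threshold on window constants (kcal/mol).
#' @param max_iter Iteration cap.
#' @return Tibble: `bin_center`, `dg` (anchored min 0), `n_samples`.
#' @export
wham_pmf <- function(windows, bin_edges, tol = 1e-8, max_iter = 100000) {
  inp <- mbar_inputs(windows)
  nb <- length(bin_edges) - 1
  centers <- (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2
  bin <- findInterval(inp$x, bin_edges, rightmost.closed = TRUE)
  bounds <- c(0, cumsum(inp$n_k))
  K <- length(windows)
  H <- matrix(0, K, nb) # per-window histograms
  for (j in seq_len(K)) {
    b <- bin[(bounds[j] + 1):bounds[j + 1]]
    H[j, ] <- tabulate(b[b >= 1 & b <= nb], nbins = nb)
  }
  h_tot <- colSums(H)
  # bias factor at bin centers
  # bin-averaged bias factors (11-point quadrature per bin) so that bins
  # need not be narrow relative to the bias width
  quad <- seq(-0.5, 0.5, length.out = 11)
  w_bin <- diff(bin_edges)
  C <- t(vapply(windows, function(w) {
    vapply(seq_len(nb), function(b) {
      mean(exp(-inp$beta * bias_energy(w, centers[b] + quad * w_bin[b])))
    }, numeric(1))
  }, numeric(nb))) # K x nb
  fexp <- rep(1, K) # exp(f_k)
  n_k <- inp$n_k
  for (it in seq_len(max_iter)) {
    denom <- colSums((n_k * fexp) * C) # length nb
    p <- ifelse(h_tot > 0, h_tot / denom, 0)
    fexp_new <- 1 / as.vector(C %*% p)
    fexp_new <- fexp_new / fexp_new[1]
    delta <- max(abs(log(fexp_new) - log(fexp))) / inp$beta
    fexp <- fexp_new
    if (delta < tol) break
  }
  dg <- ifelse(p > 0, -log(p) / inp$beta, NA_real_)
  dg <- dg - min(dg, na.rm = TRUE)
  tibble(bin_center = centers, dg = dg, n_samples = h_tot)
}
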