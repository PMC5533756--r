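# Headgroup center-of-mass positions per lipid for one frame.
# Returns tibble lipid_id, lipid_type, x, y, z.
headgroup_positions <- function(frm, system, headgroup_sel) {
  idx <- headgroup_sel
  key <- paste(system$group[idx], system$residue_id[idx], sep = ":")
  m <- system$mass[idx]
  co <- frm$coordinates[idx, , drop = FALSE]
  agg <- rowsum(cbind(co * m, m), key)
  tibble(
    lipid_key = rownames(agg),
    lipid_type = sub(":.*$", "", rownames(agg)),
    lipid_id = as.integer(sub("^.*:", "", rownames(agg))),
    x = agg[, 1] / agg[, 4],
    y = agg[, 2] / agg[, 4],
    z = agg[, 3] / agg[, 4]
  )
}

#' Assign lipids to bilayer leaflets
#'
#' Labels each lipid upper or lower by the Z of its headgroup center of mass
#' relative to the bilayer midplane, taken as the median headgroup Z. Lipids
#' exactly at the midplane go to the upper leaflet.
#'
#' @param frm A [frame()].
#' @param system A [system_model()].
#' @param headgroup_sel Headgroup atom selection (see [select_headgroups()]).
#' @return Tibble: `lipid_id`, `lipid_type`, `x`, `y`, `z`, `leaflet`.
#' @export
assign_leaflets <- function(frm, system, headgroup_sel) {
  hg <- headgroup_positions(frm, system, headgroup_sel)
  if (nrow(hg) < 2) abort("need at least 2 lipids to assign leaflets")
  midplane <- stats::median(hg$z)
  mutate(hg, leaflet = ifelse(.data$z >= midplane, "upper", "lower"))
}

x_bin_centers <- function(box_x, n_bins) {
  edges <- seq(0, box_x, length.out = n_bins + 1)
  (edges[-1] + edges[-(n_bins + 1)]) / 2
}

# bin index in 1..n_bins for coordinate wrapped into [0, box)
x_bin_index <- function(x, box_x, n_bins) {
  xb <- x %% box_x
  pmin(n_bins, floor(xb / (box_x / n_bins)) + 1L)
}

#' Membrane surface height profile h(X)
#'
#' Mean headgroup-COM Z in X bins for lipids of one leaflet within a Y slab
#' `|Y - Y_center| <= y_half_width`, averaged over frames. Bins that collect
#' no samples are filled by linear interpolation from neighboring bins and
#' flagged.
#'
#' @param traj A [trajectory()].
#' @param system A [system_model()].
#' @param headgroup_sel Headgroup atom selection.
#' @param leaflet `"upper"` (default, the protein-facing leaflet) or
#'   `"lower"`.
#' @param n_bins Number of X bins (>= 8).
#' @param y_half_width Half-width of the Y slab, Angstrom (default 48.3).
#' @param y_center Center of the Y slab (default box-Y/2).
#' @return Tibble: `x`, `h`, `n_samples`, `interpolated`; attribute
#'   `y_half_width`.
#' @export
surface_profile <- function(traj, system, headgroup_sel, leaflet = "upper",
                            n_bins = 64, y_half_width = 48.3, y_center = NULL) {
  if (n_bins < 8) abort("need at least 8 X bins")
  box <- traj[[1]]$box
  y_center <- y_center %||% (box[2] / 2)
  centers <- x_bin_centers(box[1], n_bins)
  zsum <- numeric(n_bins)
  cnt <- numeric(n_bins)
  for (f in traj) {
    lf <- assign_leaflets(f, system, headgroup_sel)
    lf <- filter(
      lf, .data$leaflet == !!leaflet,
      abs(((.data$y - y_center + box[2] / 2) %% box[2]) - box[2] / 2) <= y_half_width
    )
    if (nrow(lf) == 0) next
    b <- x_bin_index(lf$x, box[1], n_bins)
    agg <- rowsum(lf$z, b)
    zsum[as.integer(rownames(agg))] <- zsum[as.integer(rownames(agg))] + agg[, 1]
    cnt <- cnt + tabulate(b, nbins = n_bins)
  }
  if (all(cnt == 0)) abort("all surface bins are empty")
  h <- ifelse(cnt > 0, zsum / pmax(cnt, 1), NA_real_)
  interpolated <- cnt == 0
  if (any(interpolated)) {
    filled <- which(!interpolated)
    h[interpolated] <- stats::approx(
      x = centers[filled], y = h[filled], xout = centers[interpolated],
      rule = 2
    )$y
  }
  out <- tibble(
    x = centers, h = h, n_samples = cnt, interpolated = interpolated
  )
  attr(out, "y_half_width") <- y_half_width
  attr(out, "box") <- box
  out
}

# periodic moving average of odd width
smooth_periodic <- function(v, width) {
  if (width <= 1) return(v)
  if (width %% 2 == 0) abort("smoothing window must be odd")
  n <- length(v)
  half <- (width - 1) / 2
  ext <- c(v[(n - half + 1):n], v, v[1:half])
  stats::filter(ext, rep(1 / width, width), sides = 2)[(half + 1):(half + n)]
}

#' Curvature profile C(X) of a membrane surface
#'
#' Smooths the height profile with an odd-width periodic moving average, then
#' evaluates the plane-curve curvature C = h'' / (1 + h'^2)^(3/2) by periodic
#' central differences, converting to nm^-1. The sign convention is positive
#' when the membrane bends toward the protein: for a protein above the
#' leaflet an upward bulge is positive curvature.
#'
#' @param surface A [surface_profile()] tibble.
#' @param smoothing_window Odd moving-average width in bins (default 5; use 1
#'   for noise-free surfaces).
#' @param footprint Length-2 X range (Angstrom) of the protein's projection,
#'   over which `c_ave`/`c_max` are taken; `NULL` means the whole box.
#' @param protein_above Logical; `TRUE` (default) if the protein sits on the
#'   +Z side of the leaflet.
#' @return A `curvature_profile`: tibble `x`, `h_smooth`, `curvature`
#'   (nm^-1) with attributes `c_ave`, `c_max` (over the footprint) and
#'   `footprint`.
#' @export
curvature_profile <- function(surface, smoothing_window = 5, footprint = NULL,
                              protein_above = TRUE) {
  usable <- sum(!surface$interpolated)
  if (usable < 5) abort("need at least 5 usable surface bins")
  n <- nrow(surface)
  dx <- surface$x[2] - surface$x[1]
  h <- smooth_periodic(surface$h, smoothing_window)
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  h1 <- (h[ip] - h[im]) / (2 * dx)
  h2 <- (h[ip] - 2 * h + h[im]) / dx^2
  sign_factor <- if (protein_above) -1 else 1
  curv <- sign_factor * h2 / (1 + h1^2)^1.5 * 10 # A^-1 -> nm^-1
  box <- attr(surface, "box")
  if (!is.null(footprint)) {
    if (!is.null(box) && (footprint[1] > box[1] || footprint[2] < 0)) {
      abort("footprint lies outside the box")
    }
    in_fp <- surface$x >= footprint[1] & surface$x <= footprint[2]
    if (!any(in_fp)) abort("footprint contains no bins")
  } else {
    in_fp <- rep(TRUE, n)
    footprint <- range(surface$x)
  }
  out <- tibble(x = surface$x, h_smooth = as.numeric(h), curvature = curv)
  attr(out, "c_ave") <- mean(curv[in_fp])
  attr(out, "c_max") <- max(curv[in_fp])
  attr(out, "footprint") <- footprint
  class(out) <- c("curvature_profile", class(out))
  out
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf(
    "<curvature_profile> C_ave = %.4g nm^-1, C_max = %.4g nm^-1 over X in [%.1f, %.1f] A\n",
    attr(x, "c_ave"), attr(x, "c_max"),
    attr(x, "footprint")[1], attr(x, "footprint")[2]
  ))
  NextMethod()
}

#' Convert a curvature to the diameter of the corresponding tubule
#'
#' @param curvature Curvature in nm^-1 (nonzero).
#' @return Diameter `2 / C` in nm.
#' @export
curvature_to_diameter <- function(curvature) {
  if (any(curvature == 0)) abort("diameter is undefined for zero curvature")
  2 / curvature
}

#' X-range of a protein's heavy-atom projection
#'
#' Used as the default binding-footprint for curvature statistics.
#'
#' @param frm A [frame()].
#' @param protein_sel Heavy-atom selection.
#' @return Length-2 numeric X range, Angstrom.
#' @export
protein_footprint <- function(frm, protein_sel) {
  range(frm$coordinates[protein_sel, 1])
}

#' Local lipid density profile N_lipid(X)
#'
#' Time-averaged headgroup-COM counts per X bin for one leaflet within the
#' usual Y slab.
#'
#' @inheritParams surface_profile
#' @return Tibble: `x`, `n_lipid` (time-averaged count per bin).
#' @export
local_density <- function(traj, system, headgroup_sel, leaflet = "upper",
                          n_bins = 64, y_half_width = 48.3, y_center = NULL) {
  box <- traj[[1]]$box
  y_center <- y_center %||% (box[2] / 2)
  centers <- x_bin_centers(box[1], n_bins)
  cnt <- numeric(n_bins)
  for (f in traj) {
    lf <- assign_leaflets(f, system, headgroup_sel)
    lf <- filter(
      lf, .data$leaflet == !!leaflet,
      abs(((.data$y - y_center + box[2] / 2) %% box[2]) - box[2] / 2) <= y_half_width
    )
    if (nrow(lf) == 0) next
    cnt <- cnt + tabulate(x_bin_index(lf$x, box[1], n_bins), nbins = n_bins)
  }
  tibble(x = centers, n_lipid = cnt / length(traj))
}

#' Lateral mean-square displacement of lipids
#'
#' MSD in the bilayer (XY) plane averaged over lipids and multiple time
#' origins, after unwrapping periodic coordinates and removing the leaflet
#' center-of-mass drift. Optionally resolved by the X bin of each lipid at
#' the origin frame.
#'
#' @param traj A [trajectory()] (wrapped or unwrapped coordinates).
#' @param system A [system_model()].
#' @param headgroup_sel Headgroup atom selection.
#' @param lags Lag times in ns; must be multiples of the frame spacing.
#' @param origin_spacing Frames between successive time origins (default 10).
#' @param leaflet Which leaflet to analyze (`"upper"`, `"lower"`, or
#'   `"both"`).
#' @param n_x_bins If not `NULL`, additionally resolve the MSD by origin-frame
#'   X bin.
#' @return An `msd_result` tibble: `lag`, `msd` (A^2), `n_pairs`, `se`, and
#'   `x_bin` when binned.
#' @export
lateral_msd <- function(traj, system, headgroup_sel, lags,
                        origin_spacing = 10, leaflet = "upper",
                        n_x_bins = NULL) {
  times <- frame_times(traj)
  dt <- times[2] - times[1]
  span <- times[length(times)] - times[1]
  if (any(lags > span)) abort("lag exceeds trajectory span")
  lag_frames <- as.integer(round(lags / dt))
  utraj <- unwrap_trajectory(traj)
  # headgroup COM per lipid per frame
  hg0 <- assign_leaflets(traj[[1]], system, headgroup_sel)
  keep_lipids <- if (leaflet == "both") hg0$lipid_key else {
    hg0$lipid_key[hg0$leaflet == leaflet]
  }
  pos <- lapply(utraj, function(f) {
    hg <- headgroup_positions(f, system, headgroup_sel)
    hg <- hg[match(keep_lipids, hg$lipid_key), ]
    cbind(hg$x, hg$y)
  })
  # remove leaflet COM drift
  coms <- t(vapply(pos, colMeans, numeric(2)))
  pos <- lapply(seq_along(pos), function(i) sweep(pos[[i]], 2, coms[i, ]))
  n_frames <- length(pos)
  box <- traj[[1]]$box
  bin0 <- if (!is.null(n_x_bins)) {
    x0 <- traj[[1]]$coordinates # wrapped frame-1 positions for binning
    hgw <- headgroup_positions(traj[[1]], system, headgroup_sel)
    hgw <- hgw[match(keep_lipids, hgw$lipid_key), ]
    x_bin_index(hgw$x, box[1], n_x_bins)
  } else NULL

  rows <- list()
  for (li in seq_along(lag_frames)) {
    lf <- lag_frames[li]
    origins <- seq(1L, n_frames - lf, by = origin_spacing)
    if (lf == 0) {
      disp2 <- matrix(0, length(keep_lipids), length(origins))
    } else {
      disp2 <- vapply(origins, function(o) {
        d <- pos[[o + lf]] - pos[[o]]
        rowSums(d * d)
      }, numeric(length(keep_lipids)))
      disp2 <- matrix(disp2, nrow = length(keep_lipids))
    }
    per_lipid <- rowMeans(disp2)
    if (is.null(n_x_bins)) {
      rows[[length(rows) + 1]] <- tibble(
        lag = lags[li], msd = mean(per_lipid),
        n_pairs = length(per_lipid) * length(origins),
        se = stats::sd(per_lipid) / sqrt(length(per_lipid))
      )
    } else {
      for (b in seq_len(n_x_bins)) {
        sel <- bin0 == b
        rows[[length(rows) + 1]] <- tibble(
          lag = lags[li], x_bin = b,
          msd = if (any(sel)) mean(per_lipid[sel]) else NA_real_,
          n_pairs = sum(sel) * length(origins),
          se = if (sum(sel) > 1) stats::sd(per_lipid[sel]) / sqrt(sum(sel)) else NA_real_
        )
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("msd_result", class(out))
  out
}
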