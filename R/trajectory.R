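#' Construct a single trajectory frame
#'
#' @param coordinates N x 3 numeric matrix, Angstrom.
#' @param box Length-3 numeric vector of orthorhombic box lengths, Angstrom.
#' @param time Frame time in ns.
#' @return A `frame` object.
#' @export
frame <- function(coordinates, box, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) abort("coordinates must be N x 3")
  if (!all(is.finite(coordinates))) abort("coordinates must all be finite")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) abort("box must be 3 positive lengths")
  structure(
    list(coordinates = unname(coordinates), box = box, time = as.numeric(time)),
    class = "frame"
  )
}

#' Construct a trajectory from frames
#'
#' Frames must share one atom count and be in strictly increasing time order.
#'
#' @param frames List of [frame()] objects.
#' @param system Optional [system_model()] the frames refer to.
#' @return A `trajectory` object (list of frames with attributes).
#' @export
trajectory <- function(frames, system = NULL) {
  if (length(frames) == 0) abort("trajectory needs at least one frame")
  n_atoms <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (length(unique(n_atoms)) != 1) abort("all frames must have the same atom count")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  if (!is.null(system) && nrow(system) != n_atoms[1]) {
    abort(sprintf(
      "atom-count mismatch: system has %d atoms, frames have %d",
      nrow(system), n_atoms[1]
    ))
  }
  structure(frames, class = "trajectory", system = system)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(
    "<trajectory> ", length(x), " frames, ",
    nrow(x[[1]]$coordinates), " atoms, t = ",
    x[[1]]$time, " .. ", x[[length(x)]]$time, " ns\n",
    sep = ""
  )
  invisible(x)
}

#' Frame times of a trajectory
#'
#' @param traj A [trajectory()].
#' @return Numeric vector of times in ns.
#' @export
frame_times <- function(traj) vapply(traj, function(f) f$time, numeric(1))

fmt_num <- function(x) formatC(x, format = "f", digits = 6)

#' Write a trajectory in the native text frame format
#'
#' Each frame is a header line `#atoms N box Lx Ly Lz time t_ns` followed by
#' N lines `atom_id x y z` (coordinates printed with 6 decimals). The format
#' round-trips bit-exactly through [load_trajectory()].
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (f in traj) {
    header <- paste(
      "#atoms", nrow(f$coordinates),
      "box", fmt_num(f$box[1]), fmt_num(f$box[2]), fmt_num(f$box[3]),
      "time", fmt_num(f$time)
    )
    lines <- paste(
      seq_len(nrow(f$coordinates)),
      fmt_num(f$coordinates[, 1]),
      fmt_num(f$coordinates[, 2]),
      fmt_num(f$coordinates[, 3])
    )
    writeLines(c(header, lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a trajectory in the native text frame format
#'
#' @param path File written by [write_trajectory()] (or by hand in the same
#'   layout).
#' @param system Optional [system_model()]; if given, the atom count of every
#'   frame must match.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(path, system = NULL) {
  if (!file.exists(path)) abort(paste0("no such trajectory file: ", path))
  lines <- readLines(path)
  headers <- grep("^#atoms ", lines)
  if (length(headers) == 0) abort("no frame headers ('#atoms ...') found")
  frames <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    h <- strsplit(lines[headers[i]], " +")[[1]]
    if (length(h) != 8 || h[3] != "box" || h[7] != "time") {
      abort(sprintf("malformed frame header at line %d", headers[i]))
    }
    n <- as.integer(h[2])
    box <- as.numeric(h[4:6])
    t_ns <- as.numeric(h[8])
    body <- lines[(headers[i] + 1):(headers[i] + n)]
    m <- matrix(as.numeric(unlist(strsplit(body, " +"), use.names = FALSE)),
      ncol = 4, byrow = TRUE
    )
    if (anyNA(m)) abort(sprintf("unparsable coordinates in frame %d", i))
    frames[[i]] <- frame(m[, 2:4, drop = FALSE], box, t_ns)
  }
  trajectory(frames, system = system)
}

#' Minimum-image displacement between two points
#'
#' @param p,q Length-3 coordinates (Angstrom) or N x 3 matrices.
#' @param box Orthorhombic box lengths, Angstrom.
#' @return Displacement `p - q` wrapped into `(-L/2, L/2]` per component.
#' @export
minimum_image_displacement <- function(p, q, box) {
  box <- as.numeric(box)
  if (any(box <= 0)) abort("box lengths must be > 0")
  d <- p - q
  if (is.matrix(d)) {
    for (k in 1:3) {
      dk <- d[, k] - box[k] * round(d[, k] / box[k])
      # round() can land exactly on -L/2; fold to +L/2 per the convention
      dk[dk <= -box[k] / 2] <- dk[dk <= -box[k] / 2] + box[k]
      d[, k] <- dk
    }
  } else {
    d <- d - box * round(d / box)
    low <- d <= -box / 2
    d[low] <- d[low] + box[low]
  }
  d
}

# Pairwise minimum-image squared distances between coordinate sets A (n x 3)
# and B (m x 3). Returns n x m matrix.
min_image_dist2 <- function(A, B, box) {
  n <- nrow(A)
  m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  out
}

#' Unwrap periodic coordinates along a trajectory
#'
#' Reconstructs continuous coordinates by accumulating minimum-image
#' displacements between consecutive frames, so that lateral displacements can
#' be measured across box boundaries (a prerequisite for diffusion analysis).
#'
#' @param traj A [trajectory()].
#' @return A trajectory with unwrapped coordinates (same times and boxes).
#' @export
unwrap_trajectory <- function(traj) {
  out <- vector("list", length(traj))
  out[[1]] <- traj[[1]]
  prev_wrapped <- traj[[1]]$coordinates
  prev_unwrapped <- traj[[1]]$coordinates
  for (i in seq_along(traj)[-1]) {
    f <- traj[[i]]
    step <- minimum_image_displacement(f$coordinates, prev_wrapped, f$box)
    cur <- prev_unwrapped + step
    out[[i]] <- frame(cur, f$box, f$time)
    prev_wrapped <- f$coordinates
    prev_unwrapped <- cur
  }
  trajectory(out, system = attr(traj, "system"))
}
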