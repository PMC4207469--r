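#' Construct a trajectory
#'
#' Time-ordered membrane snapshots with consistent molecule indexing. Two
#' storage levels are supported: a compact per-molecule reference-point
#' array (always present) and, optionally, the full bead-level
#' [membrane_frame] list for analyses that need individual beads (contacts,
#' curvature grids). Generators that only move whole molecules (diffusion,
#' flip-flop) emit compact trajectories.
#'
#' @param coords numeric array `n_molecules x 3 x n_frames` of reference
#'   coordinates, Å.
#' @param times numeric vector of frame times, ns, strictly increasing.
#' @param molecules data.frame with `mol`, `species` and optionally
#'   `leaflet` (initial tags).
#' @param box numeric length-3 box, Å.
#' @param frames optional list of [membrane_frame]s.
#' @param wrapped logical: are coordinates wrapped into the box? MSD
#'   analysis requires unwrapped coordinates.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, times, molecules, box, frames = NULL,
                       wrapped = FALSE) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(molecules),
            dim(coords)[3] == length(times))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  dt <- if (length(times) > 1) times[2] - times[1] else NA_real_
  structure(list(coords = coords, times = as.numeric(times), dt = dt,
                 molecules = molecules, box = as.numeric(box),
                 frames = frames, wrapped = isTRUE(wrapped)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames (%.1f-%.1f ns), %d molecules%s%s>\n",
              length(x$times), min(x$times), max(x$times),
              nrow(x$molecules),
              if (is.null(x$frames)) ", compact" else ", bead-level",
              if (x$wrapped) ", wrapped" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory] or list of frames.
#' @export
n_frames <- function(traj) {
  if (inherits(traj, "trajectory")) return(length(traj$times))
  length(traj)
}

#' Assemble a trajectory from a list of frames
#'
#' Checks that every frame has the same molecules in the same order, then
#' extracts per-molecule reference points (head centroid; ROH for
#' cholesterol) into the compact coordinate array, keeping the frames.
#'
#' @param frames list of [membrane_frame]s, time-ordered.
#' @param dt optional frame spacing (ns) used when frame times are all
#'   zero/missing.
#' @return a [trajectory].
#' @export
as_trajectory <- function(frames, dt = NULL) {
  stopifnot(length(frames) >= 1L)
  m0 <- frames[[1]]$molecules
  for (k in seq_along(frames)) {
    mk <- frames[[k]]$molecules
    if (nrow(mk) != nrow(m0) || any(mk$mol != m0$mol) ||
        any(mk$species != m0$species))
      stop("inconsistent molecule ordering at frame ", k)
  }
  times <- vapply(frames, `[[`, 0, "time")
  if (all(times == times[1]) && length(frames) > 1) {
    if (is.null(dt)) dt <- 1
    times <- (seq_along(frames) - 1) * dt
  }
  coords <- array(NA_real_, c(nrow(m0), 3L, length(frames)))
  for (k in seq_along(frames)) {
    rp <- reference_points(frames[[k]])
    coords[, , k] <- as.matrix(rp[, c("x", "y", "z")])
  }
  trajectory(coords, times, m0, frames[[1]]$box, frames = frames,
             wrapped = TRUE)
}

# Internal: frames list from trajectory-or-list input.
get_frames <- function(x) {
  if (inherits(x, "membrane_frame")) return(list(x))
  if (inherits(x, "trajectory")) {
    if (is.null(x$frames))
      stop("this analysis needs bead-level frames; the trajectory is compact")
    return(x$frames)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "membrane_frame")))
  x
}

# Internal: select frame indices by time window (ns) and stride (ns).
window_indices <- function(times, window = NULL, stride = NULL) {
  idx <- seq_along(times)
  if (!is.null(window)) {
    if (window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9)
      stop("window [", window[1], ", ", window[2], "] ns outside trajectory")
    idx <- idx[times >= window[1] - 1e-9 & times <= window[2] + 1e-9]
  }
  if (!is.null(stride) && length(idx) > 1L) {
    dt <- min(diff(times[idx]))
    step <- max(1L, as.integer(round(stride / dt)))
    idx <- idx[seq(1L, length(idx), by = step)]
  }
  idx
}
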