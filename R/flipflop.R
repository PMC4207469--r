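# Internal: three-state matrix (+1 outer / 0 core / -1 inner) for one
# species across a trajectory. Bead-level trajectories use the grid-local
# midplane of assign_leaflets(); compact trajectories use the per-frame
# global midplane (mean reference z of all non-cholesterol lipids).
leaflet_state_matrix <- function(traj, species = "CHOL",
                                 core_half_width = 10, grid_dims = c(4, 4)) {
  stopifnot(inherits(traj, "trajectory"))
  sp <- resolve_species(species)
  sel <- which(traj$molecules$species == sp)
  if (!length(sel)) stop("species ", sp, " not present in trajectory")
  nf <- length(traj$times)
  states <- matrix(NA_integer_, length(sel), nf)
  if (!is.null(traj$frames)) {
    for (k in seq_len(nf)) {
      fr <- assign_leaflets(traj$frames[[k]], core_half_width, grid_dims)
      tags <- fr$molecules$leaflet[sel]
      states[, k] <- ifelse(tags == "outer", 1L,
                            ifelse(tags == "inner", -1L, 0L))
    }
  } else {
    other <- which(traj$molecules$species != sp &
                   traj$molecules$species != "PROT")
    if (!length(other)) other <- seq_len(nrow(traj$molecules))
    z <- matrix(traj$coords[sel, 3, ], nrow = length(sel))
    mid <- colMeans(matrix(traj$coords[other, 3, ], nrow = length(other)))
    dz <- sweep(z, 2, mid)
    states <- matrix(0L, length(sel), nf)
    states[dz > core_half_width] <- 1L
    states[dz < -core_half_width] <- -1L
  }
  rownames(states) <- traj$molecules$mol[sel]
  states
}

#' Detect cholesterol inter-leaflet flip-flop events
#'
#' Assigns each molecule a three-state (outer / core / inner) label per
#' frame and records a flip-flop whenever a molecule completes a full
#' crossing: its confirmed leaflet changes from outer to inner or vice
#' versa, with core passages allowed in between, and the new leaflet is
#' only confirmed after `min_dwell` consecutive frames there (debouncing
#' against boundary noise). Excursions into the core that return to the
#' same leaflet are not events.
#'
#' @param traj a [trajectory].
#' @param species species to track (default cholesterol).
#' @param core_half_width core slab half-width, Å.
#' @param min_dwell frames a new leaflet must persist to confirm a
#'   crossing.
#' @return object of class `flipflop_result`: list with `events`
#'   (data.frame `mol`, `time`, `direction`), `n_events`, `rate`
#'   (events/ns over the analyzed time, summed over molecules),
#'   `occupancy` (time-mean outer/core/inner fractions) and `params`.
#' @export
detect_flipflops <- function(traj, species = "CHOL", core_half_width = 10,
                             min_dwell = 5) {
  if (length(traj$times) < 2L) stop("need at least 2 frames")
  states <- leaflet_state_matrix(traj, species, core_half_width)
  times <- traj$times
  events <- list()
  for (r in seq_len(nrow(states))) {
    runs <- rle(states[r, ])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    confirmed <- 0L
    for (q in seq_along(runs$values)) {
      v <- runs$values[q]
      if (v == 0L) next
      if (confirmed == 0L) { confirmed <- v; next }
      if (v != confirmed && runs$lengths[q] >= min_dwell) {
        events[[length(events) + 1L]] <- data.frame(
          mol = as.integer(rownames(states)[r]),
          time = times[starts[q]],
          direction = if (v == 1L) "inner->outer" else "outer->inner",
          stringsAsFactors = FALSE)
        confirmed <- v
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(mol = integer(0), time = numeric(0), direction = character(0))
  span <- max(times) - min(times)
  occ <- c(outer = mean(states == 1L), core = mean(states == 0L),
           inner = mean(states == -1L))
  structure(list(events = ev, n_events = nrow(ev), rate = nrow(ev) / span,
                 occupancy = occ,
                 params = list(species = species,
                               core_half_width = core_half_width,
                               min_dwell = min_dwell,
                               analyzed_ns = span,
                               n_molecules = nrow(states))),
            class = "flipflop_result")
}

#' @export
print.flipflop_result <- function(x, ...) {
  cat(sprintf("Flip-flop: %d events over %.0f ns (%d molecules) -> %.4f events/ns\n",
              x$n_events, x$params$analyzed_ns, x$params$n_molecules, x$rate))
  cat(sprintf("Occupancy outer/core/inner: %.3f / %.3f / %.3f\n",
              x$occupancy[1], x$occupancy[2], x$occupancy[3]))
  invisible(x)
}

#' Leaflet occupancy time series
#'
#' Per-frame outer/core/inner fractions for one species, with running
#' means.
#'
#' @inheritParams detect_flipflops
#' @return data.frame `time`, `outer`, `core`, `inner`, `outer_run`,
#'   `core_run`, `inner_run`.
#' @export
leaflet_occupancy_timeseries <- function(traj, species = "CHOL",
                                         core_half_width = 10) {
  states <- leaflet_state_matrix(traj, species, core_half_width)
  run <- function(v) cumsum(v) / seq_along(v)
  out <- data.frame(time = traj$times,
                    outer = colMeans(states == 1L),
                    core = colMeans(states == 0L),
                    inner = colMeans(states == -1L))
  out$outer_run <- run(out$outer)
  out$core_run <- run(out$core)
  out$inner_run <- run(out$inner)
  out
}
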