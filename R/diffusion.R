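# FFT-based single-series MSD over all time origins:
#   msd(k) = mean_t (x[t+k] - x[t])^2, k = 0..n-1
# via the standard S1 - 2*S2 decomposition (S2 = autocorrelation by FFT).
msd_fft_1d <- function(x) {
  n <- length(x)
  fx <- fft(c(x, rep(0, n)))
  s2 <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:n] / (2 * n)
  s2 <- s2 / (n - 0:(n - 1))
  d <- x^2
  q <- 2 * sum(d)
  s1 <- numeric(n)
  for (k in 0:(n - 1)) {
    if (k > 0) q <- q - d[k] - d[n - k + 1]
    s1[k + 1] <- q / (n - k)
  }
  s1 - 2 * s2
}

#' Lateral mean square displacement per species
#'
#' MSD(tau) averaged over all molecules of each species and all time
#' origins at each lag, using lateral (x, y) components only. Requires
#' unwrapped coordinates. The per-leaflet center of motion is removed
#' frame-by-frame before accumulation, so collective leaflet drift does
#' not inflate the MSD.
#'
#' @param traj a [trajectory] with unwrapped coordinates.
#' @param species species to include (default: all present).
#' @param remove_drift remove per-leaflet center-of-motion drift.
#' @return object of class `msd_result`: data.frame `lag_ns` plus one MSD
#'   column (Å²) per species; attributes record dt and molecule counts.
#' @export
lateral_msd <- function(traj, species = NULL, remove_drift = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$times) < 3L) stop("need at least 3 frames")
  if (traj$wrapped)
    stop("MSD requires unwrapped coordinates; this trajectory is wrapped ",
         "(rebuild it from unwrapped positions or stored period images)")
  mols <- traj$molecules
  if (is.null(species)) species <- unique(mols$species)
  species <- resolve_species(species)
  xy <- traj$coords[, 1:2, , drop = FALSE]
  if (remove_drift) {
    lf <- mols$leaflet
    if (all(is.na(lf))) lf <- rep("all", nrow(mols))
    for (g in unique(lf)) {
      idx <- which(lf == g)
      for (ax in 1:2) {
        com <- colMeans(matrix(xy[idx, ax, ], nrow = length(idx)))
        xy[idx, ax, ] <- sweep(matrix(xy[idx, ax, ], nrow = length(idx)),
                               2, com - com[1])
      }
    }
  }
  nf <- dim(xy)[3]
  out <- data.frame(lag_ns = (0:(nf - 1)) * traj$dt)
  counts <- integer(0)
  for (sp in species) {
    idx <- which(mols$species == sp)
    if (!length(idx)) stop("species ", sp, " not in trajectory")
    acc <- numeric(nf)
    for (i in idx)
      acc <- acc + msd_fft_1d(xy[i, 1, ]) + msd_fft_1d(xy[i, 2, ])
    out[[sp]] <- acc / length(idx)
    counts[sp] <- length(idx)
  }
  structure(out, class = c("msd_result", "data.frame"),
            dt = traj$dt, n_molecules = counts)
}

#' Fit lateral diffusion coefficients from an MSD curve
#'
#' Least-squares straight line over lags within a fractional window of the
#' maximum lag (default 10-50%: short lags carry crossover effects, long
#' lags few time origins). The lateral diffusion coefficient is slope/4,
#' converted from Å²/ns to cm²/s (1 Å²/ns = 1e-7 cm²/s).
#'
#' @param msd an `msd_result` from [lateral_msd()].
#' @param fit_fraction `c(lo, hi)` fraction of the maximum lag to fit.
#' @return data.frame `species`, `D_cm2_s`, `se_cm2_s`, `slope_A2_ns`,
#'   `n_lags`.
#' @export
fit_diffusion <- function(msd, fit_fraction = c(0.1, 0.5)) {
  stopifnot(inherits(msd, "msd_result"))
  lag <- msd$lag_ns
  lo <- fit_fraction[1] * max(lag)
  hi <- fit_fraction[2] * max(lag)
  sel <- lag >= lo & lag <= hi
  if (sum(sel) < 10L) stop("fewer than 10 lags inside the fit window")
  species <- setdiff(names(msd), "lag_ns")
  rows <- lapply(species, function(sp) {
    fit <- lm(msd[[sp]][sel] ~ lag[sel])
    slope <- unname(coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    if (slope < 0)
      warning("negative MSD slope for ", sp, "; D reported with its sign")
    data.frame(species = sp,
               D_cm2_s = slope / 4 * 1e-7,
               se_cm2_s = se / 4 * 1e-7,
               slope_A2_ns = slope,
               n_lags = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diffusion coefficients over consecutive time windows
#'
#' Splits the trajectory into non-overlapping windows (default 1 µs) and
#' fits an independent MSD + diffusion coefficient in each, giving the
#' time evolution of the mobility per species.
#'
#' @param traj a [trajectory] with unwrapped coordinates.
#' @param species species to include (default: all).
#' @param window_ns window length, ns.
#' @param fit_fraction forwarded to [fit_diffusion()].
#' @return data.frame `window_start_ns`, `window_end_ns`, `species`,
#'   `D_cm2_s`, `se_cm2_s`.
#' @export
windowed_diffusion <- function(traj, species = NULL, window_ns = 1000,
                               fit_fraction = c(0.1, 0.5)) {
  span <- max(traj$times) - min(traj$times)
  if (window_ns > span + 1e-9) stop("window longer than the trajectory")
  edges <- seq(min(traj$times), max(traj$times), by = window_ns)
  if (max(edges) < max(traj$times) - 1e-9) edges <- c(edges, max(traj$times))
  rows <- list()
  for (w in seq_len(length(edges) - 1)) {
    idx <- which(traj$times >= edges[w] - 1e-9 &
                 traj$times <= edges[w + 1] + 1e-9)
    sub <- trajectory(traj$coords[, , idx, drop = FALSE],
                      traj$times[idx], traj$molecules, traj$box,
                      wrapped = traj$wrapped)
    fits <- fit_diffusion(lateral_msd(sub, species), fit_fraction)
    fits$window_start_ns <- edges[w]
    fits$window_end_ns <- edges[w + 1]
    rows[[w]] <- fits
  }
  out <- do.call(rbind, rows)
  out[, c("window_start_ns", "window_end_ns", "species", "D_cm2_s",
          "se_cm2_s")]
}
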