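# Synthetic membrane generators. Each generator is deterministic under a
# fixed seed and returns its ground truth ("manifest") alongside the data,
# so every downstream statistic can be scored by parameter recovery.

# Internal: build the bead table for one leaflet from lateral head positions
# and species labels. Beads per lipid: full head-bead stack (centroid at the
# planted lateral position), the linker pair and the interface bead, at
# species-typical depths. `side` is +1 (outer) or -1 (inner); `dz` is an
# optional per-lipid vertical displacement (surface undulation).
leaflet_atoms <- function(xy, species, side, mid = 50, dz = NULL,
                          mol_offset = 0L,
                          registry = default_lipid_registry()) {
  n <- nrow(xy)
  if (is.null(dz)) dz <- numeric(n)
  pieces <- vector("list", length(unique(species)))
  ptr <- 1L
  for (sp in unique(species)) {
    idx <- which(species == sp)
    s <- get_species(sp, registry)
    hb <- s$head_beads
    # head beads stacked 0.8 A apart with their centroid exactly at z 13
    offs <- 0.8 * (seq_along(hb) - 1)
    beads <- c(hb, s$linker_beads, s$interface_bead)
    bx <- c(rep(0, length(hb)),
            if (length(s$linker_beads)) c(-1.5, 1.5), 0)
    bz <- c(13 + offs - mean(offs),
            rep(10, length(s$linker_beads)), 8)
    nb <- length(beads)
    pieces[[ptr]] <- data.frame(
      mol = rep(mol_offset + idx, each = nb),
      species = sp,
      bead = rep(beads, length(idx)),
      x = rep(xy[idx, 1], each = nb) + rep(bx, length(idx)),
      y = rep(xy[idx, 2], each = nb),
      z = mid + side * rep(bz, length(idx)) + rep(dz[idx], each = nb),
      stringsAsFactors = FALSE)
    ptr <- ptr + 1L
  }
  do.call(rbind, pieces)
}

#' Generate a randomly mixed leaflet
#'
#' Lipid head positions are laid down by random sequential adsorption
#' (uniform with a hard-core minimum spacing), and species labels are a
#' uniform random permutation of the target composition — the
#' random-mixing null against which fractional interaction matrices are
#' calibrated (expected fraction 1/k for k species).
#'
#' @param n number of lipids.
#' @param composition named fractions (default: four species at 25%).
#' @param apl area per lipid, Å² (sets the lateral box edge).
#' @param min_spacing hard-core minimum head-head spacing, Å.
#' @param leaflet `"outer"` or `"inner"`.
#' @param seed integer seed.
#' @return a [membrane_frame] with leaflets tagged and a `manifest`
#'   attribute recording the planted parameters.
#' @export
make_random_leaflet <- function(n = 1000,
                                composition = c(POPC = 0.25, POPE = 0.25,
                                                PPCS = 0.25, GM3 = 0.25),
                                apl = 90, min_spacing = 7,
                                leaflet = "outer", seed = NULL) {
  names(composition) <- resolve_species(names(composition))
  counts <- largest_remainder(composition, n)
  L <- sqrt(n * apl)
  with_seed(seed, {
    xy <- cpp_rsa_positions(n, L, L, min_spacing, 400L)
    species <- sample(rep(names(counts), counts))
    side <- if (leaflet == "outer") 1 else -1
    atoms <- leaflet_atoms(xy, species, side)
    fr <- membrane_frame(atoms, box = c(L, L, 100),
                         leaflet = rep(leaflet, n))
    attr(fr, "manifest") <- list(kind = "random_mixing", n = n,
                                 composition = composition, apl = apl,
                                 min_spacing = min_spacing, seed = seed)
    fr
  })
}

# Hexagonal disc of m points with the given spacing, centred at the origin,
# innermost-first.
hex_disc <- function(m, spacing) {
  r <- ceiling(sqrt(m)) + 2
  g <- expand.grid(i = -r:r, j = -r:r)
  x <- (g$i + g$j / 2) * spacing
  y <- g$j * spacing * sqrt(3) / 2
  ord <- order(x^2 + y^2)
  cbind(x[ord[seq_len(m)]], y[ord[seq_len(m)]])
}

#' Generate a leaflet with planted nano-clusters
#'
#' Places the target species in compact discs of the requested sizes
#' (hexagonally packed at `intra_spacing`, well below the DBSCAN
#' neighborhood radius) plus isolated singletons, with inter-cluster gaps
#' large enough that density-based clustering must recover the planted
#' partition exactly. Remaining (filler) species are placed at random with
#' the hard-core spacing. The manifest lists the ground-truth cluster
#' membership of every target lipid.
#'
#' @param target_species species forming the planted clusters.
#' @param cluster_sizes integer vector of planted disc sizes (each >= 4 to
#'   fall outside the non-clustered bin).
#' @param n_singletons isolated target lipids (planted noise).
#' @param n_filler random lipids of `filler_species`.
#' @param filler_species species name for the random background.
#' @param apl area per lipid used for the initial box guess, Å².
#' @param intra_spacing in-disc neighbor spacing, Å.
#' @param min_gap minimum edge-to-edge gap between discs, Å.
#' @param singleton_spacing minimum distance between singletons (and from
#'   any other target lipid), Å.
#' @param leaflet leaflet tag.
#' @param seed integer seed.
#' @return a [membrane_frame]; attribute `manifest` holds a data.frame
#'   (`mol`, `species`, `cluster`; cluster 0 = planted noise) plus the
#'   parameters.
#' @export
make_clustered_leaflet <- function(target_species = "GM3",
                                   cluster_sizes = c(10, 25, 50),
                                   n_singletons = 21, n_filler = 150,
                                   filler_species = "POPC", apl = 90,
                                   intra_spacing = 8, min_gap = 45,
                                   singleton_spacing = 20,
                                   leaflet = "outer", seed = NULL) {
  stopifnot(all(cluster_sizes >= 1), n_singletons >= 0)
  n_target <- sum(cluster_sizes) + n_singletons
  n_total <- n_target + n_filler
  radii <- intra_spacing * (0.53 * sqrt(cluster_sizes) + 1)
  with_seed(seed, {
    L <- max(sqrt(n_total * apl), 2.2 * (sum(2 * radii) + min_gap))
    for (attempt in 1:6) {
      res <- try(.place_clusters(cluster_sizes, radii, n_singletons, L,
                                 intra_spacing, min_gap, singleton_spacing),
                 silent = TRUE)
      if (!inherits(res, "try-error")) break
      L <- L * 1.25
    }
    if (inherits(res, "try-error"))
      stop("infeasible planted-cluster packing: ", attr(res, "condition")$message)
    tgt_xy <- res$xy
    cluster_id <- res$cluster

    # filler: rejection sampling with hard core against everything placed
    fill_xy <- matrix(NA_real_, n_filler, 2)
    placed <- tgt_xy
    budget <- 400L * n_filler
    k <- 0L
    while (k < n_filler) {
      if (budget <= 0L) stop("hard-core packing failed for filler lipids")
      budget <- budget - 1L
      p <- runif(2) * L
      d2 <- .min_image_d2(p, placed, L)
      if (min(d2) >= 7^2) {
        k <- k + 1L
        fill_xy[k, ] <- p
        placed <- rbind(placed, p)
      }
    }
    xy <- rbind(tgt_xy, fill_xy)
    species <- c(rep(target_species, n_target), rep(filler_species, n_filler))
    side <- if (leaflet == "outer") 1 else -1
    atoms <- leaflet_atoms(xy, species, side)
    fr <- membrane_frame(atoms, box = c(L, L, 100),
                         leaflet = rep(leaflet, n_total))
    attr(fr, "manifest") <- list(
      kind = "planted_clusters",
      membership = data.frame(mol = seq_len(n_target),
                              species = target_species,
                              cluster = cluster_id),
      cluster_sizes = cluster_sizes, n_singletons = n_singletons,
      box_edge = L, seed = seed)
    fr
  })
}

# squared min-image lateral distances from point p to rows of mat (L x L box)
.min_image_d2 <- function(p, mat, L) {
  dx <- p[1] - mat[, 1]; dx <- dx - L * round(dx / L)
  dy <- p[2] - mat[, 2]; dy <- dy - L * round(dy / L)
  dx * dx + dy * dy
}

.place_clusters <- function(sizes, radii, n_singletons, L, intra_spacing,
                            min_gap, singleton_spacing) {
  centers <- matrix(NA_real_, length(sizes), 2)
  for (i in seq_along(sizes)) {
    ok <- FALSE
    for (try in 1:2000) {
      p <- runif(2) * L
      if (i == 1 || all(.min_image_d2(p, centers[seq_len(i - 1), , drop = FALSE], L) >=
                        (radii[i] + radii[seq_len(i - 1)] + min_gap)^2)) {
        centers[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place cluster centers")
  }
  xy <- NULL; cluster <- integer(0)
  for (i in seq_along(sizes)) {
    disc <- hex_disc(sizes[i], intra_spacing)
    xy <- rbind(xy, sweep(disc, 2, centers[i, ], `+`))
    cluster <- c(cluster, rep(i, sizes[i]))
  }
  if (n_singletons > 0) {
    guard <- max(singleton_spacing, 18)  # stay outside the DBSCAN radius
    for (s in seq_len(n_singletons)) {
      ok <- FALSE
      for (try in 1:4000) {
        p <- runif(2) * L
        if (all(.min_image_d2(p, xy, L) >= guard^2)) {
          xy <- rbind(xy, p); cluster <- c(cluster, 0L); ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place singletons")
    }
  }
  list(xy = xy, cluster = cluster)
}

#' Generate a bilayer frame with curvature-coupled composition
#'
#' The bilayer surface is a sum of sinusoidal modes; both leaflets are
#' displaced congruently (no local thinning or thickening). Each species is
#' laid down by thinning a Poisson process with intensity proportional to
#' `1 + coupling * ẑ(x, y)`, where `ẑ` is the surface height normalized to
#' its maximum amplitude (so `|coupling| <= 1` guarantees a nonnegative
#' intensity). Negative coupling for an outer-leaflet species plants
#' enrichment in the concave (viewed from outside) regions.
#'
#' @param n_per_leaflet lipids per leaflet.
#' @param composition named fractions used for both leaflets.
#' @param coupling list with elements `outer` and `inner`, each a named
#'   numeric vector of per-species coupling coefficients in [-1, 1]
#'   (unlisted species couple with 0).
#' @param amplitude peak surface displacement, Å.
#' @param modes two-column matrix of integer lateral wave numbers, one mode
#'   per row (default: one wave along x and one along y).
#' @param apl area per lipid, Å².
#' @param time frame time stamp, ns.
#' @param seed integer seed.
#' @return a [membrane_frame] (both leaflets) with `manifest` attribute.
#' @export
make_curved_frame <- function(n_per_leaflet = 3000,
                              composition = c(POPC = 0.40, POPE = 0.10,
                                              PPCS = 0.15, GM3 = 0.10,
                                              CHOL = 0.25),
                              coupling = list(outer = c(GM3 = -0.9),
                                              inner = NULL),
                              amplitude = 20,
                              modes = rbind(c(1, 0), c(0, 1)),
                              apl = 90, time = 0, seed = NULL) {
  names(composition) <- resolve_species(names(composition))
  counts <- largest_remainder(composition, n_per_leaflet)
  L <- sqrt(n_per_leaflet * apl)
  nm <- nrow(modes)
  with_seed(seed, {
    phases <- runif(nm, 0, 2 * pi)
    surf <- function(x, y) {
      u <- 0
      for (m in seq_len(nm))
        u <- u + sin(2 * pi * (modes[m, 1] * x + modes[m, 2] * y) / L +
                     phases[m])
      (amplitude / nm) * u
    }
    zhat <- function(x, y) if (amplitude == 0) rep(0, length(x)) else
      surf(x, y) / amplitude
    atoms_list <- list(); tags <- character(0); moff <- 0L
    manifest_c <- list()
    for (lf in c("outer", "inner")) {
      cpl <- coupling[[lf]]
      if (!is.null(cpl)) {
        names(cpl) <- resolve_species(names(cpl))
        if (any(abs(cpl) > 1))
          stop("coupling outside [-1, 1] makes the placement intensity negative")
      }
      xy <- matrix(NA_real_, n_per_leaflet, 2)
      species <- rep(names(counts), counts)
      done <- 0L
      for (sp in names(counts)) {
        c_sp <- if (!is.null(cpl) && sp %in% names(cpl)) cpl[[sp]] else 0
        need <- counts[[sp]]
        got <- 0L
        while (got < need) {
          m <- max(64L, 2L * (need - got))
          px <- runif(m) * L; py <- runif(m) * L
          acc <- runif(m) < (1 + c_sp * zhat(px, py)) / (1 + abs(c_sp))
          na <- min(sum(acc), need - got)
          if (na > 0) {
            sel <- which(acc)[seq_len(na)]
            xy[done + got + seq_len(na), ] <- cbind(px[sel], py[sel])
            got <- got + na
          }
        }
        done <- done + need
      }
      dz <- surf(xy[, 1], xy[, 2])
      side <- if (lf == "outer") 1 else -1
      atoms_list[[lf]] <- leaflet_atoms(xy, species, side, dz = dz,
                                        mol_offset = moff)
      tags <- c(tags, rep(lf, n_per_leaflet))
      moff <- moff + n_per_leaflet
      manifest_c[[lf]] <- cpl
    }
    fr <- membrane_frame(do.call(rbind, atoms_list), box = c(L, L, 140),
                         time = time, leaflet = tags)
    attr(fr, "manifest") <- list(kind = "curvature_coupled",
                                 coupling = manifest_c,
                                 amplitude = amplitude, modes = modes,
                                 phases = phases, seed = seed)
    fr
  })
}

#' Generate a sequence of independent curvature-coupled frames
#'
#' Repeated [make_curved_frame()] calls with fresh surface phases and
#' positions per frame, emulating a fluctuating undulation spectrum.
#'
#' @param n_frames number of frames.
#' @param dt frame spacing, ns.
#' @param seed integer seed (per-frame seeds are derived from it).
#' @param ... forwarded to [make_curved_frame()].
#' @return list of [membrane_frame]s.
#' @export
make_curved_frames <- function(n_frames = 20, dt = 1, seed = NULL, ...) {
  lapply(seq_len(n_frames), function(k) {
    make_curved_frame(..., time = (k - 1) * dt,
                      seed = if (is.null(seed)) NULL else seed + k)
  })
}

#' Generate a trajectory of laterally diffusing lipids
#'
#' Every lipid performs an independent lateral Gaussian random walk with
#' per-axis step variance `2 * D * dt` (so the lateral mean square
#' displacement is `4 * D * t`); z is fixed per leaflet. Coordinates are
#' unwrapped. Half of each species is placed in each leaflet.
#'
#' @param n_per_species named integer vector of molecule counts.
#' @param D named numeric vector of planted diffusion coefficients in
#'   cm²/s (defaults on the scale of the CG plasma-membrane species:
#'   2.6e-7 for bulk lipids, 2.0e-7 for PIP2, 1.5e-7 for GM3).
#' @param dt frame interval, ns.
#' @param n_frames number of stored frames (>= 3).
#' @param apl area per lipid, Å² (sets the box).
#' @param seed integer seed.
#' @return a compact [trajectory]; `manifest` attribute records the planted
#'   `D` (cm²/s) per species.
#' @export
make_diffusion_trajectory <- function(n_per_species = c(POPC = 167,
                                                        PIP2 = 167,
                                                        GM3 = 166),
                                      D = c(POPC = 2.6e-7, PIP2 = 2.0e-7,
                                            GM3 = 1.5e-7),
                                      dt = 1, n_frames = 5000, apl = 90,
                                      seed = NULL) {
  stopifnot(n_frames >= 3, all(D >= 0), all(names(n_per_species) %in% names(D)))
  n <- sum(n_per_species)
  L <- sqrt(2 * n * apl / 2)
  species <- rep(names(n_per_species), n_per_species)
  leaflet <- unlist(lapply(n_per_species, function(m)
    rep(c("outer", "inner"), length.out = m)), use.names = FALSE)
  with_seed(seed, {
    coords <- array(NA_real_, c(n, 3L, n_frames))
    x0 <- runif(n) * L; y0 <- runif(n) * L
    d_ang <- D[species] * 1e7          # cm^2/s -> A^2/ns
    sd_step <- sqrt(2 * d_ang * dt)    # per-axis step SD
    for (ax in 1:2) {
      steps <- matrix(rnorm(n * (n_frames - 1)), n, n_frames - 1) * sd_step
      coords[, ax, ] <- cbind(if (ax == 1) x0 else y0, steps)
      coords[, ax, ] <- t(apply(coords[, ax, ], 1, cumsum))
    }
    coords[, 3, ] <- rep(50 + ifelse(leaflet == "outer", 16, -16), n_frames)
    tr <- trajectory(coords, times = (seq_len(n_frames) - 1) * dt,
                     molecules = data.frame(mol = seq_len(n),
                                            species = species,
                                            leaflet = leaflet,
                                            stringsAsFactors = FALSE),
                     box = c(L, L, 100), wrapped = FALSE)
    attr(tr, "manifest") <- list(kind = "diffusion", D = D, dt = dt,
                                 n_frames = n_frames, seed = seed)
    tr
  })
}

#' Generate a cholesterol flip-flop trajectory
#'
#' Cholesterol z-coordinates follow a three-state (outer / core / inner)
#' Markov jump process with the requested stationary occupancy and total
#' full-crossing rate (completed outer-to-inner or inner-to-outer passages
#' per ns, summed over molecules). Initial states are stratified exactly to
#' the target occupancy, mirroring the equal initial leaflet split of the
#' builder. Static non-cholesterol lipids provide the midplane. The
#' manifest lists every true crossing event.
#'
#' Kinetics: with occupancy pi and system rate R over N molecules, the
#' leaflet exit rate is `a_X = R / (N * pi_X)` and the core exit rate is
#' `b = R / (N * pi_core)` split equally toward either leaflet; detailed
#' balance then yields exactly the requested stationary occupancy, and the
#' completed-crossing flux equals `R`.
#'
#' @param n_chol cholesterol molecules (default: the 6000-lipid membrane's
#'   cholesterol pool).
#' @param n_other static background lipids (half per leaflet).
#' @param rate planted full-crossing rate, events/ns (system total).
#' @param occupancy stationary fractions `c(outer, core, inner)`, sum 1.
#' @param duration trajectory length, ns.
#' @param dt frame interval, ns.
#' @param z_leaflet leaflet reference-bead |z| offset from the midplane, Å.
#' @param z_noise per-frame Gaussian jitter on z, Å.
#' @param seed integer seed.
#' @return a compact [trajectory]; `manifest` holds the event table
#'   (`mol`, `time`, `direction`) and planted parameters.
#' @export
make_flipflop_trajectory <- function(n_chol = 1500, n_other = 500,
                                     rate = 0.14,
                                     occupancy = c(outer = 0.49, core = 0.02,
                                                   inner = 0.49),
                                     duration = 1000, dt = 1,
                                     z_leaflet = 16, z_noise = 1,
                                     seed = NULL) {
  stopifnot(rate >= 0, duration > 0, dt > 0)
  if (abs(sum(occupancy) - 1) > 1e-9) stop("occupancy must sum to 1")
  pi_o <- occupancy[[1]]; pi_c <- occupancy[[2]]; pi_i <- occupancy[[3]]
  n_other <- 2L * (n_other %/% 2L)  # balanced leaflets -> midplane at 0
  times <- seq(0, duration, by = dt)
  nf <- length(times)
  init <- rep(c(1L, 0L, -1L), largest_remainder(
    c(a = pi_o, b = pi_c, c = pi_i), n_chol))

  with_seed(seed, {
    states <- matrix(init, n_chol, nf)
    events <- list()
    if (rate > 0) {
      a_o <- rate / (n_chol * pi_o)
      a_i <- rate / (n_chol * pi_i)
      b <- if (pi_c > 0) rate / (n_chol * pi_c) else Inf
      for (m in seq_len(n_chol)) {
        t <- 0; s <- init[m]
        last_leaflet <- s  # 0 = no leaflet yet: first arrival is not a crossing
        jt <- numeric(0); js <- integer(0)
        while (t < duration) {
          r_out <- if (s == 0L) 2 * b else if (s == 1L) a_o else a_i
          t <- t + rexp(1, r_out)
          if (t >= duration) break
          if (s == 0L) {
            s <- sample(c(1L, -1L), 1)
          } else if (pi_c > 0) {
            s <- 0L
          } else {
            s <- -s
          }
          if (s != 0L && s != last_leaflet) {
            if (last_leaflet != 0L)
              events[[length(events) + 1L]] <-
                data.frame(mol = m, time = t,
                           direction = if (s == 1L) "inner->outer"
                                       else "outer->inner")
            last_leaflet <- s
          }
          jt <- c(jt, t); js <- c(js, s)
        }
        if (length(jt))
          states[m, ] <- c(init[m], js)[findInterval(times, jt) + 1L]
      }
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(mol = integer(0), time = numeric(0), direction = character(0))

    n <- n_chol + n_other
    L <- sqrt(n * 2 * 90 / 2)
    coords <- array(NA_real_, c(n, 3L, nf))
    coords[, 1, ] <- runif(n) * L
    coords[, 2, ] <- runif(n) * L
    other_z <- rep(c(16, -16), n_other / 2)
    zs <- rbind(states * z_leaflet,
                matrix(other_z, n_other, nf))
    coords[, 3, ] <- 50 + zs + rnorm(n * nf, sd = z_noise)
    tr <- trajectory(coords, times,
                     molecules = data.frame(
                       mol = seq_len(n),
                       species = c(rep("CHOL", n_chol),
                                   rep("POPC", n_other)),
                       leaflet = NA_character_,
                       stringsAsFactors = FALSE),
                     box = c(L, L, 100), wrapped = TRUE)
    attr(tr, "manifest") <- list(kind = "flipflop", events = ev,
                                 rate = rate, occupancy = occupancy,
                                 duration = duration, states = states,
                                 seed = seed)
    tr
  })
}
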