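# Independent reference implementations used as oracles. These deliberately
# avoid the package's computational path: periodic geometry is handled by
# explicit enumeration of periodic images, and accumulations are naive
# O(n^2) loops.

# Pairwise squared lateral minimum-image distances by brute force over the
# 9 lateral periodic images.
image_dist2_lateral <- function(pts, box) {
  n <- nrow(pts)
  d2 <- matrix(Inf, n, n)
  for (sx in -1:1) for (sy in -1:1) {
    dx <- outer(pts[, 1], pts[, 1] + sx * box[1], "-")
    dy <- outer(pts[, 2], pts[, 2] + sy * box[2], "-")
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  d2
}

# Classic DBSCAN (seed-set expansion in ascending point order) with
# neighborhoods from explicit image enumeration; noise points get singleton
# labels, matching the package's partition semantics.
dbscan_reference <- function(pts, box, eps = 15, min_elements = 3) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  d2 <- image_dist2_lateral(pts, box)
  nb <- lapply(seq_len(n), function(i)
    setdiff(which(d2[i, ] <= eps^2 + 1e-9), i))
  core <- (lengths(nb) + 1L) >= min_elements
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- nb[[i]]
    while (length(seeds)) {
      j <- seeds[1]
      seeds <- seeds[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) seeds <- c(seeds, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  for (i in seq_len(n)) if (labels[i] == 0L) { cl <- cl + 1L; labels[i] <- cl }
  labels
}

# Canonical form of a partition: relabel clusters by first appearance.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# Brute-force single-count molecule contacts: minimum over all bead pairs
# and all periodic images, strict < cutoff.
contacts_reference <- function(coords, mol, box, cutoff, lateral = TRUE) {
  ids <- unique(mol)
  out <- NULL
  shifts <- if (lateral) expand.grid(sx = -1:1, sy = -1:1, sz = 0) else
    expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    pa <- coords[mol == ids[a], , drop = FALSE]
    pb <- coords[mol == ids[b], , drop = FALSE]
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      for (i in seq_len(nrow(pa))) {
        dx <- pa[i, 1] - pb[, 1] - shifts$sx[s] * box[1]
        dy <- pa[i, 2] - pb[, 2] - shifts$sy[s] * box[2]
        d2 <- dx^2 + dy^2
        if (!lateral) d2 <- d2 + (pa[i, 3] - pb[, 3] - shifts$sz[s] * box[3])^2
        best <- min(best, min(d2))
      }
    }
    if (best < cutoff^2) out <- rbind(out, c(ids[a], ids[b]))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Naive O(n^2) time-origin-averaged MSD of one coordinate series.
msd_direct <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    mean((x[seq_len(n - k) + k] - x[seq_len(n - k)])^2)
  }, 0)
}

# Frame with box-piecewise-constant structure: per grid box, a prescribed
# number of GM3 lipids plus one POPC "surface" lipid whose interface bead
# sits at the prescribed height. dims boxes over an `edge` A box.
grid_frame <- function(counts, z_surface, dims = c(4, 4), edge = 80) {
  nb <- prod(dims)
  stopifnot(length(counts) == nb, length(z_surface) == nb)
  wx <- edge / dims[1]; wy <- edge / dims[2]
  xy <- NULL; species <- character(0); zi <- numeric(0)
  for (b in seq_len(nb)) {
    cx <- ((b - 1) %/% dims[2]) * wx + wx / 2
    cy <- ((b - 1) %% dims[2]) * wy + wy / 2
    xy <- rbind(xy, c(cx, cy))
    species <- c(species, "POPC")
    zi <- c(zi, 60 + z_surface[b])
    if (counts[b] > 0) {
      off <- seq_len(counts[b])
      xy <- rbind(xy, cbind(cx + 0.1 * off - 0.05 * counts[b], cy))
      species <- c(species, rep("GM3", counts[b]))
      zi <- c(zi, rep(60 + z_surface[b], counts[b]))
    }
  }
  minimal_frame(xy, species, zi, box = c(edge, edge, 120))
}
grid_acceptance_frame <- grid_frame

# Minimal two-bead lipids (first head bead + interface bead) placed at given
# lateral positions, for hand-built frames with exact box-level structure.
minimal_frame <- function(xy, species, z_interface, box,
                          leaflet = rep("outer", nrow(xy)), z_head_off = 5) {
  reg <- default_lipid_registry()
  xy <- as.matrix(xy)
  dimnames(xy) <- NULL
  n <- nrow(xy)
  rows <- lapply(seq_len(n), function(i) {
    s <- reg[[species[i]]]
    data.frame(mol = i, species = species[i],
               bead = c(s$head_beads[1], s$interface_bead),
               x = xy[i, 1], y = xy[i, 2],
               z = c(z_interface[i] + z_head_off, z_interface[i]),
               stringsAsFactors = FALSE)
  })
  membrane_frame(do.call(rbind, rows), box = box, leaflet = leaflet)
}
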