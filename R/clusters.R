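#' DBSCAN with periodic lateral distances
#'
#' Standard density-based clustering (Ester et al.) over lateral (xy)
#' minimum-image distances. A point is core when its eps-neighborhood,
#' including the point itself, holds at least `min_elements` points.
#' Clusters are grown from core points in ascending point order with a
#' sorted seed queue, so border points reachable from two clusters are
#' deterministically assigned to the first cluster discovered. Noise points
#' receive singleton labels (their own cluster of size 1), so every label
#' partitions the input.
#'
#' @param points numeric matrix (n x 2 or n x 3; only x, y are used).
#' @param box numeric box edges, Å (only the lateral components are used).
#' @param eps neighborhood radius, Å (default 15; neighbors at distance
#'   <= eps).
#' @param min_elements minimum neighborhood size including the point
#'   itself (default 3).
#' @return integer vector of cluster labels (1-based); attribute `core`
#'   flags core points, attribute `n_dense` gives the number of density
#'   clusters (before singleton labeling).
#' @export
dbscan_periodic <- function(points, box, eps = 15, min_elements = 3) {
  stopifnot(eps > 0, min_elements >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L)
    return(structure(integer(0), core = logical(0), n_dense = 0L))
  z <- if (ncol(points) > 2) points[, 3] else numeric(n)
  # neighbor pairs at distance <= eps: use a slightly padded strict-< search,
  # then filter, so boundary-equal distances are kept
  pr <- cpp_close_mol_pairs(points[, 1], points[, 2], z, seq_len(n),
                            as.numeric(box), eps * (1 + 1e-12) + 1e-9, TRUE)
  keep <- rep(TRUE, nrow(pr))
  if (nrow(pr)) {
    d <- vapply(seq_len(nrow(pr)), function(r)
      minimum_image_distance(points[pr[r, 1], 1:2], points[pr[r, 2], 1:2],
                             box, "xy"), 0)
    keep <- d <= eps + 1e-9
  }
  adj <- vector("list", n)
  if (any(keep)) {
    pr <- pr[keep, , drop = FALSE]
    adj <- split(c(pr[, 2], pr[, 1]), factor(c(pr[, 1], pr[, 2]),
                                             levels = seq_len(n)))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  nbr_count <- lengths(adj) + 1L  # including the point itself
  core <- nbr_count >= min_elements

  labels <- integer(n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- sort(adj[[i]])
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- sort(unique(c(queue, adj[[j]][labels[adj[[j]]] == 0L])))
      }
    }
  }
  n_dense <- cl
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      cl <- cl + 1L
      labels[i] <- cl
    }
  }
  structure(labels, core = core, n_dense = n_dense)
}

# The size-class boundaries used for nano-cluster bookkeeping:
# 1-3 lipids non-clustered, 4-20 small, 21-40 medium, > 40 large.
cluster_size_bins <- function() c(nonclustered = 3, small = 20, medium = 40)

# fraction of lipids per size class
bin_fractions <- function(sizes_per_lipid) {
  b <- cluster_size_bins()
  n <- length(sizes_per_lipid)
  c(nonclustered = sum(sizes_per_lipid <= b[1]) / n,
    small = sum(sizes_per_lipid > b[1] & sizes_per_lipid <= b[2]) / n,
    medium = sum(sizes_per_lipid > b[2] & sizes_per_lipid <= b[3]) / n,
    large = sum(sizes_per_lipid > b[3]) / n)
}

#' Nano-cluster size distribution over time
#'
#' Runs periodic DBSCAN over one species' head-bead centroids per frame and
#' reports the fraction of lipids in each size class (1-3 non-clustered,
#' 4-20 small, 21-40 medium, > 40 large), plus a convergence summary (mean
#' class fractions over the final part of the trajectory).
#'
#' @param x frames input ([trajectory] with frames, list, or single frame).
#' @param species species to cluster.
#' @param leaflet leaflet restriction.
#' @param eps DBSCAN radius, Å.
#' @param min_elements DBSCAN minimum neighborhood size.
#' @param final_fraction fraction of trailing frames used for the
#'   convergence summary.
#' @return list with `series` (data.frame: time, class fractions,
#'   n_clusters, largest), `records` (per-frame label vectors with molecule
#'   ids) and `summary` (mean class fractions over the final window).
#' @export
cluster_timeseries <- function(x, species, leaflet = "outer", eps = 15,
                               min_elements = 3, final_fraction = 0.5) {
  frames <- get_frames(x)
  sp <- resolve_species(species)
  records <- vector("list", length(frames))
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    pts <- mol_points(fr, "head")
    sel <- pts$species == sp
    if (!identical(leaflet, "all"))
      sel <- sel & pts$mol %in% select_leaflet(fr, leaflet)
    if (!any(sel)) stop("no ", sp, " lipids in ", leaflet, " leaflet")
    sub <- pts[sel, ]
    labels <- dbscan_periodic(as.matrix(sub[, c("x", "y")]), fr$box,
                              eps, min_elements)
    sizes <- table(labels)
    per_lipid <- as.numeric(sizes[as.character(labels)])
    fb <- bin_fractions(per_lipid)
    records[[k]] <- data.frame(mol = sub$mol, label = as.integer(labels),
                               size = per_lipid)
    rows[[k]] <- data.frame(time = fr$time, t(fb),
                            n_clusters = sum(sizes > cluster_size_bins()[1]),
                            largest = max(sizes))
  }
  series <- do.call(rbind, rows)
  tail_n <- max(1L, ceiling(nrow(series) * final_fraction))
  summ <- colMeans(series[seq(nrow(series) - tail_n + 1L, nrow(series)),
                          c("nonclustered", "small", "medium", "large")])
  list(series = series, records = records, summary = summ,
       params = list(species = sp, leaflet = leaflet, eps = eps,
                     min_elements = min_elements))
}

#' Protein connectivity clusters over time
#'
#' Single-linkage connected components of the protein set: two proteins are
#' linked when any pair of their beads lies within the cutoff (3-D minimum
#' image, default 8 Å); connectivity is transitive.
#'
#' @param x frames input.
#' @param cutoff linkage cutoff, Å.
#' @return list with `series` (data.frame: time, n_clusters, largest) and
#'   `sizes` (per-frame list of component sizes).
#' @export
protein_clusters <- function(x, cutoff = 8) {
  frames <- get_frames(x)
  out_sizes <- vector("list", length(frames))
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    at <- fr$atoms
    prot <- at[at$species == "PROT", ]
    if (!nrow(prot)) stop("no proteins in frame")
    ids <- sort(unique(prot$mol))
    # bead pairs within cutoff (<=), different proteins
    pr <- cpp_close_mol_pairs(prot$x, prot$y, prot$z, prot$mol,
                              fr$box, cutoff * (1 + 1e-12) + 1e-9, FALSE)
    # union-find over protein ids
    parent <- seq_along(ids)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    if (nrow(pr)) for (r in seq_len(nrow(pr))) {
      i <- find(match(pr[r, 1], ids)); j <- find(match(pr[r, 2], ids))
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
    comp <- vapply(seq_along(ids), find, 0L)
    sizes <- as.integer(table(comp))
    out_sizes[[k]] <- sort(sizes, decreasing = TRUE)
    rows[[k]] <- data.frame(time = fr$time, n_clusters = length(sizes),
                            largest = max(sizes))
  }
  list(series = do.call(rbind, rows), sizes = out_sizes,
       params = list(cutoff = cutoff))
}
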