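# Internal: lateral grid box index (0-based boxes, half-open [lo, hi) with
# periodic wrap; a lipid exactly on an edge belongs to the higher box).
grid_box_index <- function(x, y, box, dims) {
  cx <- pmin(floor(wrap_coords(x, box[1]) / (box[1] / dims[1])), dims[1] - 1)
  cy <- pmin(floor(wrap_coords(y, box[2]) / (box[2] / dims[2])), dims[2] - 1)
  as.integer(cx * dims[2] + cy + 1L)
}

#' Grid decomposition of a leaflet
#'
#' Bins the lipids of one leaflet into a lateral grid (default 8x8) by
#' head-bead centroid position and computes, per box, the species counts
#' and the surface height `z_n`: the mean z of the head/tail interface
#' beads of the lipids in the box, excluding the species whose counts are
#' being correlated (so a species cannot correlate with a surface defined
#' by itself).
#'
#' @param frame a [membrane_frame] with leaflets assigned.
#' @param leaflet `"outer"` or `"inner"`.
#' @param dims grid dimensions, `c(nx, ny)`, each >= 2.
#' @param exclude_species species excluded from the surface estimate
#'   (NULL = none).
#' @return list: `counts` (species x boxes matrix), `z` (per-box surface
#'   height, NA where no surface lipids), `n_in_box`, `dims`, `box`.
#' @export
grid_decompose <- function(frame, leaflet = "outer", dims = c(8, 8),
                           exclude_species = NULL) {
  if (any(dims < 2)) stop("grid dims must be at least 2x2")
  ids <- select_leaflet(frame, leaflet)
  if (!length(ids)) stop("leaflet ", leaflet, " is empty")
  heads <- mol_points(frame, "head")
  heads <- heads[heads$mol %in% ids, ]
  ifc <- mol_points(frame, "interface")
  ifc <- ifc[ifc$mol %in% ids, ]
  nbox <- prod(dims)
  bi <- grid_box_index(heads$x, heads$y, frame$box, dims)
  species <- sort(unique(heads$species))
  counts <- matrix(0L, length(species), nbox,
                   dimnames = list(species, NULL))
  tab <- table(factor(heads$species, levels = species), factor(bi, levels = 1:nbox))
  counts[, ] <- as.integer(tab)
  if (!is.null(exclude_species))
    ifc <- ifc[!(ifc$species %in% resolve_species(exclude_species)), ]
  z <- rep(NA_real_, nbox)
  if (nrow(ifc)) {
    bz <- grid_box_index(ifc$x, ifc$y, frame$box, dims)
    agg <- rowsum(ifc$z, bz)
    z[as.integer(rownames(agg))] <- agg[, 1] / tabulate(bz, nbox)[as.integer(rownames(agg))]
  }
  n_in_box <- tabulate(bi, nbox)
  if (all(n_in_box == 0)) stop("all grid boxes empty")
  list(counts = counts, z = z, n_in_box = n_in_box, dims = dims,
       box = frame$box)
}

# Pearson cross-correlation by the explicit sum formula; zero-variance
# input yields 0 (flagged by the caller).
.rlz <- function(l, z) {
  lm_ <- mean(l); zm <- mean(z)
  num <- sum((l - lm_) * (z - zm))
  den <- sqrt(sum((l - lm_)^2) * sum((z - zm)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Correlation between local composition and surface height
#'
#' For each frame, the normalized cross-correlation R over grid boxes
#' between the number of lipids of one species in a box and the local
#' head/tail interface height of that box (surface computed from the other
#' species), Pearson-normalized so R is bounded in [-1, 1]:
#' R = sum_n (L_n - L̄)(z_n - z̄) / sqrt(sum (L_n - L̄)² sum (z_n - z̄)²).
#' Boxes without surface lipids are excluded. A negative R for an
#' outer-leaflet species means enrichment in regions deflected toward the
#' cell interior — concave when viewed from the extracellular side.
#' Zero-variance frames contribute R = 0 and are flagged.
#'
#' @param x frames input ([trajectory] with frames, list, or single frame).
#' @param species species whose counts are correlated.
#' @param leaflet leaflet analyzed.
#' @param dims grid dimensions.
#' @return object of class `curvature_correlation`: list with `mean`,
#'   `sd`, `per_frame`, `n_frames`, `zero_variance_frames`, `params`.
#' @export
curvature_composition_correlation <- function(x, species, leaflet = "outer",
                                              dims = c(8, 8)) {
  frames <- get_frames(x)
  sp <- resolve_species(species)
  per <- numeric(length(frames))
  flagged <- 0L
  for (k in seq_along(frames)) {
    gd <- grid_decompose(frames[[k]], leaflet, dims, exclude_species = sp)
    if (!sp %in% rownames(gd$counts))
      stop("species ", sp, " absent from ", leaflet, " leaflet")
    ok <- !is.na(gd$z)
    if (sum(ok) < 2) stop("fewer than 2 non-empty grid boxes")
    r <- .rlz(gd$counts[sp, ok], gd$z[ok])
    if (is.na(r)) { r <- 0; flagged <- flagged + 1L }
    per[k] <- r
  }
  structure(list(mean = mean(per), sd = if (length(per) > 1) sd(per) else 0,
                 per_frame = per, n_frames = length(frames),
                 zero_variance_frames = flagged,
                 params = list(species = sp, leaflet = leaflet, dims = dims)),
            class = "curvature_correlation")
}

#' @export
print.curvature_correlation <- function(x, ...) {
  cat(sprintf("R_L,z(%s, %s leaflet): %.3f +/- %.3f over %d frames\n",
              x$params$species, x$params$leaflet, x$mean, x$sd, x$n_frames))
  invisible(x)
}

#' Interleaflet composition correlation
#'
#' For every pair (outer species A, inner species B), the correlation
#' across grid boxes (pooled over frames) between A's counts in the outer
#' boxes and B's counts in the laterally corresponding inner boxes.
#' Species co-enriched on the same surface deflection correlate
#' positively; species on opposite deflections anti-correlate.
#'
#' @param x frames input.
#' @param dims grid dimensions.
#' @return matrix (outer species x inner species) of correlations.
#' @export
interleaflet_correlation <- function(x, dims = c(8, 8)) {
  frames <- get_frames(x)
  outer_counts <- NULL; inner_counts <- NULL
  for (fr in frames) {
    go <- grid_decompose(fr, "outer", dims)
    gi <- grid_decompose(fr, "inner", dims)
    outer_counts <- cbind(outer_counts, go$counts)
    inner_counts <- cbind(inner_counts, gi$counts)
  }
  out <- matrix(NA_real_, nrow(outer_counts), nrow(inner_counts),
                dimnames = list(rownames(outer_counts),
                                rownames(inner_counts)))
  for (a in rownames(out)) for (b in colnames(out)) {
    sa <- sd(outer_counts[a, ]); sb <- sd(inner_counts[b, ])
    out[a, b] <- if (sa == 0 || sb == 0) 0 else
      cor(outer_counts[a, ], inner_counts[b, ])
  }
  out
}

#' Local bilayer thickness and its coupling to surface height
#'
#' Per grid box, the separation between the outer and inner head/tail
#' interfaces, pooled over frames, plus the correlation between local
#' thickness and local mid-surface height. Congruently displaced leaflets
#' (pure bending) give near-constant thickness and near-zero correlation.
#'
#' @param x frames input.
#' @param dims grid dimensions.
#' @return list: `mean_thickness` (Å), `sd_thickness`,
#'   `height_correlation`, `per_box` (data.frame pooled over frames).
#' @export
local_thickness <- function(x, dims = c(8, 8)) {
  frames <- get_frames(x)
  rows <- list()
  for (k in seq_along(frames)) {
    go <- grid_decompose(frames[[k]], "outer", dims)
    gi <- grid_decompose(frames[[k]], "inner", dims)
    ok <- !is.na(go$z) & !is.na(gi$z)  # boxes empty on either side skipped
    rows[[k]] <- data.frame(frame = k, bx = which(ok),
                            thickness = go$z[ok] - gi$z[ok],
                            height = (go$z[ok] + gi$z[ok]) / 2)
  }
  per <- do.call(rbind, rows)
  hc <- if (sd(per$thickness) == 0 || sd(per$height) == 0) 0 else
    cor(per$thickness, per$height)
  list(mean_thickness = mean(per$thickness),
       sd_thickness = sd(per$thickness),
       height_correlation = hc, per_box = per)
}
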