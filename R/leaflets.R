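#' Assign leaflet tags to every molecule of a frame
#'
#' Three-state assignment against a local bilayer midplane: a lipid is
#' `outer` when its reference bead lies more than `core_half_width` above
#' the midplane, `inner` when more than `core_half_width` below, otherwise
#' `core`. The reference bead is the head-bead centroid for lipids and the
#' ROH bead for cholesterol. The midplane is local: the frame is divided
#' into a lateral grid (default 4x4) and the midplane of a cell is the mean
#' z of all lipid linker beads whose own lateral position falls in that
#' cell, so the assignment stays correct in undulating membranes. Cells
#' without linker beads fall back to the global linker mean. Protein
#' molecules are tagged `protein`.
#'
#' @param frame a [membrane_frame] with at least 2 lipid molecules.
#' @param core_half_width half-width of the membrane-core slab, Å.
#' @param grid_dims lateral grid used for the local midplane, default
#'   `c(4, 4)`.
#' @param registry species registry.
#' @return the frame with `molecules$leaflet` filled in.
#' @export
assign_leaflets <- function(frame, core_half_width = 10, grid_dims = c(4, 4),
                            registry = default_lipid_registry()) {
  stopifnot(inherits(frame, "membrane_frame"))
  lipids <- frame$molecules$species != "PROT"
  if (sum(lipids) < 2L) stop("frame must contain at least 2 lipid molecules")

  box <- frame$box
  nx <- as.integer(grid_dims[1]); ny <- as.integer(grid_dims[2])
  cell_of <- function(x, y) {
    cx <- pmin(floor(wrap_coords(x, box[1]) / (box[1] / nx)), nx - 1)
    cy <- pmin(floor(wrap_coords(y, box[2]) / (box[2] / ny)), ny - 1)
    as.integer(cx * ny + cy + 1)
  }

  # linker beads, bead-level, assigned to cells by their own xy
  at <- frame$atoms
  is_linker <- logical(nrow(at))
  for (sp in setdiff(unique(at$species), "PROT")) {
    lb <- get_species(sp, registry)$linker_beads
    if (length(lb)) is_linker <- is_linker | (at$species == sp & at$bead %in% lb)
  }
  if (!any(is_linker))
    stop("no linker beads present; cannot locate the bilayer midplane")
  lk <- at[is_linker, ]
  lk_cell <- cell_of(lk$x, lk$y)
  mid <- rep(NA_real_, nx * ny)
  agg <- rowsum(lk$z, lk_cell)
  cnt <- tabulate(lk_cell, nbins = nx * ny)
  mid[as.integer(rownames(agg))] <- agg[, 1] / cnt[as.integer(rownames(agg))]
  mid[is.na(mid)] <- mean(lk$z)

  ref <- reference_points(frame, registry)
  tags <- frame$molecules$leaflet
  li <- which(lipids)
  dz <- ref$z[li] - mid[cell_of(ref$x[li], ref$y[li])]
  tags[li] <- ifelse(dz > core_half_width, "outer",
                     ifelse(dz < -core_half_width, "inner", "core"))
  tags[!lipids] <- "protein"
  frame$molecules$leaflet <- tags
  frame
}
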