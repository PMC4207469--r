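#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' Euclidean distance between two points with each coordinate wrapped to the
#' nearest periodic image. In mode `"xy"` only the lateral (x, y) components
#' are wrapped and used, giving the in-plane distance all lateral cutoff
#' rules assume.
#'
#' @param p1,p2 numeric length-3 (or length-2 for mode `"xy"`) coordinates, Å.
#' @param box numeric length-3 orthorhombic box edge lengths, Å.
#' @param mode `"xyz"` (full 3-D) or `"xy"` (lateral only).
#' @return minimum-image distance in Å.
#' @export
minimum_image_distance <- function(p1, p2, box, mode = c("xyz", "xy")) {
  mode <- match.arg(mode)
  if (!all(is.finite(p1)) || !all(is.finite(p2)))
    stop("non-finite coordinates")
  if (any(box <= 0)) stop("box edges must be > 0")
  nd <- if (mode == "xy") 2L else 3L
  d <- (p1[seq_len(nd)] - p2[seq_len(nd)])
  L <- box[seq_len(nd)]
  d <- d - L * round(d / L)
  sqrt(sum(d * d))
}

# Wrap coordinates into [0, L).
wrap_coords <- function(x, L) x - L * floor(x / L)

# Internal: unique molecule pairs with any bead pair closer than `cutoff`
# (strict <) under minimum-image convention. Returns a 2-column integer
# matrix of molecule ids (i < j). `lateral` switches to xy distances.
close_molecule_pairs <- function(coords, mol, box, cutoff, lateral = TRUE) {
  stopifnot(ncol(coords) == 3L, length(mol) == nrow(coords))
  if (nrow(coords) == 0L) return(matrix(integer(0), ncol = 2))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  m <- cpp_close_mol_pairs(coords[, 1], coords[, 2], coords[, 3],
                           as.integer(mol), as.numeric(box),
                           as.numeric(cutoff), isTRUE(lateral))
  m
}

# Internal: all (i, j, d) pairs between point sets A and B with minimum-image
# distance < rmax. Used by RDFs and residue contact mapping.
cross_pair_distances <- function(a, b, box, rmax, lateral = TRUE) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  out <- cpp_cross_pairs(a[, 1], a[, 2], if (ncol(a) > 2) a[, 3] else numeric(nrow(a)),
                         b[, 1], b[, 2], if (ncol(b) > 2) b[, 3] else numeric(nrow(b)),
                         as.numeric(box), as.numeric(rmax), isTRUE(lateral))
  data.frame(i = out$i, j = out$j, d = out$d)
}
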