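#' Lipid-lipid pair contacts in one frame
#'
#' Two lipids are in contact when the minimum-image distance between any of
#' their linker beads (the glycerol ester moiety of glycerolipids, the
#' amino-alcohol backbone of sphingolipids) is strictly less than the
#' cutoff. However many bead pairs qualify, the pair is counted once.
#' Cholesterol carries no linker beads and cannot be assigned to a leaflet
#' over time, so it is excluded.
#'
#' @param frame a [membrane_frame] with leaflets assigned.
#' @param leaflet `"outer"` or `"inner"`.
#' @param cutoff contact cutoff, Å (default 11).
#' @param lateral use lateral (xy) distances (default) or full 3-D.
#' @return data.frame `mol_i`, `mol_j`, `species_i`, `species_j`, one row
#'   per contacting pair (`mol_i < mol_j`).
#' @export
lipid_pair_contacts <- function(frame, leaflet = "outer", cutoff = 11,
                                lateral = TRUE) {
  ids <- select_leaflet(frame, leaflet)
  m <- frame$molecules
  sel_mol <- m$mol[m$mol %in% ids & !(m$species %in% c("CHOL", "PROT"))]
  at <- frame$atoms
  reg <- default_lipid_registry()
  keep <- logical(nrow(at))
  for (sp in unique(m$species[m$mol %in% sel_mol])) {
    lb <- get_species(sp, reg)$linker_beads
    if (!length(lb))
      stop("species ", sp, " has no linker beads defined")
    keep <- keep | (at$species == sp & at$bead %in% lb & at$mol %in% sel_mol)
  }
  sub <- at[keep, ]
  pairs <- close_molecule_pairs(as.matrix(sub[, c("x", "y", "z")]), sub$mol,
                                frame$box, cutoff, lateral = lateral)
  sp_of <- m$species[match(pairs, m$mol)]
  dim(sp_of) <- dim(pairs)
  data.frame(mol_i = pairs[, 1], mol_j = pairs[, 2],
             species_i = sp_of[, 1], species_j = sp_of[, 2],
             stringsAsFactors = FALSE)
}

#' Abundance-corrected fractional lipid-lipid interaction matrix
#'
#' Accumulates single-count lipid-lipid contacts over the selected frames
#' and converts them into the fractional interaction matrix: the ordered
#' contact count C(A->B) is normalized by the number of ordered pairs
#' available, `r(A->B) = C(A->B) / (N_A * Ñ_B)` with `Ñ_B = N_B` for
#' B != A and `N_A - 1` for B = A, and each row is then normalized to sum
#' to 1. The abundance correction makes the expectation under uniform
#' random mixing equal to 1/k for k species regardless of composition
#' (0.5 for two species, 0.25 for four). The matrix need not be symmetric:
#' clustering makes A's neighborhood of B differ from B's of A. Counts are
#' pooled over frames before normalization.
#'
#' @param x a [trajectory] with bead-level frames, a list of
#'   [membrane_frame]s, or a single frame.
#' @param leaflet `"outer"` or `"inner"`.
#' @param cutoff contact cutoff, Å.
#' @param window optional `c(start, end)` time window, ns.
#' @param stride frame stride within the window, ns.
#' @return object of class `fractional_interactions`: list with `fractions`
#'   (row-stochastic k x k matrix), `pair_counts` (ordered contact counts),
#'   `n_lipids` (mean per-frame species counts), `params`.
#' @export
fractional_interactions <- function(x, leaflet = "outer", cutoff = 11,
                                    window = NULL, stride = NULL) {
  frames <- get_frames(x)
  times <- vapply(frames, `[[`, 0, "time")
  frames <- frames[window_indices(times, window, stride)]
  if (!length(frames)) stop("no frames in the requested window")

  counts <- NULL; denom <- NULL; nsum <- NULL
  for (fr in frames) {
    pc <- lipid_pair_contacts(fr, leaflet, cutoff)
    ids <- select_leaflet(fr, leaflet)
    m <- fr$molecules
    sp <- m$species[m$mol %in% ids & !(m$species %in% c("CHOL", "PROT"))]
    nsp <- table(sp)
    k <- names(nsp)
    if (is.null(counts)) {
      counts <- matrix(0, length(k), length(k), dimnames = list(k, k))
      denom <- counts
      nsum <- setNames(numeric(length(k)), k)
    } else if (!identical(sort(k), sort(rownames(counts)))) {
      stop("species sets differ across frames")
    }
    n <- as.numeric(nsp[rownames(counts)])
    names(n) <- rownames(counts)
    if (nrow(pc)) {
      tab <- table(factor(pc$species_i, levels = rownames(counts)),
                   factor(pc$species_j, levels = rownames(counts)))
      counts <- counts + tab + t(tab)  # ordered counts; AA pairs add 2
    }
    avail <- outer(n, n)
    diag(avail) <- n * (n - 1)
    denom <- denom + avail
    nsum <- nsum + n
  }
  rate <- counts / denom
  rate[denom == 0] <- NA
  zero_rows <- rowSums(rate, na.rm = TRUE) == 0
  if (any(zero_rows))
    warning("species with no contacts: ",
            paste(rownames(rate)[zero_rows], collapse = ", "))
  fractions <- rate / rowSums(rate, na.rm = TRUE)
  structure(list(fractions = fractions, pair_counts = counts,
                 n_lipids = nsum / length(frames),
                 params = list(leaflet = leaflet, cutoff = cutoff,
                               window = window, stride = stride,
                               n_frames = length(frames))),
            class = "fractional_interactions")
}

#' @export
print.fractional_interactions <- function(x, ...) {
  cat(sprintf("Fractional interactions (%s leaflet, %d frame%s, %.1f A cutoff)\n",
              x$params$leaflet, x$params$n_frames,
              if (x$params$n_frames > 1) "s" else "", x$params$cutoff))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Lateral radial distribution function
#'
#' In-plane g(r) of target lipids around centers (protein lateral centers
#' of geometry, another species' head centroids, or fixed points), averaged
#' over frames: shell counts are normalized by shell area and the target's
#' mean planar density, so g(r) tends to 1 at large r for random placement.
#'
#' @param x frames input as in [fractional_interactions()].
#' @param center `"protein"`, a species name, or a 2-column matrix of fixed
#'   lateral points.
#' @param target_species species whose head centroids are counted.
#' @param bin_width radial bin width, Å.
#' @param r_max maximum radius, Å (must be below half the smallest lateral
#'   box edge).
#' @param leaflet leaflet restriction for the targets (`"all"` for none).
#' @return data.frame `r` (bin centers), `g`.
#' @export
lateral_rdf <- function(x, center = "protein", target_species,
                        bin_width = 2, r_max = 50, leaflet = "all") {
  frames <- get_frames(x)
  box <- frames[[1]]$box
  if (r_max > min(box[1:2]) / 2)
    stop("r_max exceeds half the smallest lateral box edge")
  breaks <- seq(0, r_max, by = bin_width)
  mids <- head(breaks, -1) + bin_width / 2
  acc <- numeric(length(mids))
  norm <- 0
  for (fr in frames) {
    pts <- mol_points(fr, "head")
    tgt_sel <- pts$species == resolve_species(target_species)
    if (!identical(leaflet, "all")) {
      ids <- select_leaflet(fr, leaflet)
      tgt_sel <- tgt_sel & pts$mol %in% ids
    }
    tgt <- as.matrix(pts[tgt_sel, c("x", "y")])
    if (is.matrix(center) || is.data.frame(center)) {
      ctr <- as.matrix(center)[, 1:2, drop = FALSE]
      self <- FALSE
    } else if (identical(center, "protein")) {
      prot <- mol_points(fr, "all")
      prot <- prot[prot$species == "PROT", ]
      if (!nrow(prot)) stop("no protein present in frame")
      ctr <- as.matrix(prot[, c("x", "y")])
      self <- FALSE
    } else {
      csp <- resolve_species(center)
      ctr <- as.matrix(pts[pts$species == csp, c("x", "y")])
      self <- identical(csp, resolve_species(target_species))
    }
    if (!nrow(ctr) || !nrow(tgt)) stop("empty center or target selection")
    pd <- cross_pair_distances(ctr, tgt, box, r_max, lateral = TRUE)
    if (self) pd <- pd[pd$d > 1e-9, ]
    acc <- acc + tabulate(findInterval(pd$d, breaks, rightmost.closed = TRUE),
                          nbins = length(mids))
    dens <- (nrow(tgt) - as.numeric(self)) / (box[1] * box[2])
    norm <- norm + nrow(ctr) * dens
  }
  shell <- pi * (breaks[-1]^2 - head(breaks, -1)^2)
  data.frame(r = mids, g = acc / (norm * shell))
}

#' Per-residue protein-lipid contact statistics
#'
#' For each protein residue, the time-mean number of selected lipid beads
#' within the cutoff (default 6 Å, 3-D minimum image) and the persistence:
#' the fraction of protein-frames with at least one contact. Residues with
#' persistence above 0.5 are flagged persistent.
#'
#' @param x frames input.
#' @param lipid_species lipid species to count.
#' @param lipid_beads bead names to count (default: the species' head
#'   beads; e.g. `"PO3"` for the PIP2 phosphate, `"ROH"` for cholesterol).
#' @param cutoff contact cutoff, Å.
#' @return data.frame `residue`, `mean_contacts`, `persistence`,
#'   `persistent`.
#' @export
residue_lipid_contacts <- function(x, lipid_species, lipid_beads = NULL,
                                   cutoff = 6) {
  frames <- get_frames(x)
  sp <- resolve_species(lipid_species)
  if (is.null(lipid_beads))
    lipid_beads <- get_species(sp)$head_beads
  first <- frames[[1]]$atoms
  prot0 <- first[first$species == "PROT", ]
  if (!nrow(prot0)) stop("no protein beads in frames")
  residues <- sort(unique(prot0$residue))
  nprot <- length(unique(prot0$mol))
  mean_ct <- setNames(numeric(length(residues)), residues)
  hit_ct <- mean_ct
  for (fr in frames) {
    at <- fr$atoms
    prot <- at[at$species == "PROT", ]
    lip <- at[at$species == sp & at$bead %in% lipid_beads, ]
    if (!nrow(lip))
      stop("lipid bead selector matches no beads (species ", sp, ")")
    pd <- cross_pair_distances(as.matrix(prot[, c("x", "y", "z")]),
                               as.matrix(lip[, c("x", "y", "z")]),
                               fr$box, cutoff, lateral = FALSE)
    per_bead <- table(factor(prot$residue[pd$i], levels = residues))
    mean_ct <- mean_ct + as.numeric(per_bead)
    # persistence: protein-frames with >= 1 contact at the residue
    got <- unique(prot[pd$i, c("mol", "residue")])
    hit <- table(factor(got$residue, levels = residues))
    hit_ct <- hit_ct + as.numeric(hit)
  }
  nf <- length(frames)
  out <- data.frame(residue = residues,
                    mean_contacts = as.numeric(mean_ct) / (nf * nprot),
                    persistence = as.numeric(hit_ct) / (nf * nprot))
  out$persistent <- out$persistence > 0.5
  out
}
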