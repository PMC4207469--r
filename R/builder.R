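#' Idealized straight-chain template coordinates for one species
#'
#' Internal coordinates (Å) for every bead of a species in an upright,
#' straight-chain conformation: linker beads at z = 0, head beads stacked
#' above, the two tails descending below. These templates replace the
#' "transfer coordinates from a simulated POPC" step of trajectory-based
#' workflows: no MD snapshot is required, and the analyses operate on
#' configurations, not energies.
#'
#' @param species species name or alias.
#' @param registry species registry.
#' @return numeric matrix (beads x 3) with bead-name rownames and an
#'   `anchor_beads` attribute naming the beads used for rigid
#'   superimposition during lipid exchange.
#' @export
lipid_template <- function(species, registry = default_lipid_registry()) {
  sp <- get_species(species, registry)
  xyz <- matrix(NA_real_, nrow = length(sp$bead_names), ncol = 3,
                dimnames = list(sp$bead_names, c("x", "y", "z")))
  if (sp$name == "CHOL") {
    xyz["ROH", ] <- c(0, 0, 2.5)
    ring <- c("R1", "R2", "R3", "R4", "R5")
    for (i in seq_along(ring))
      xyz[ring[i], ] <- c(0.7 * (-1)^i, 0, -2 * (i - 1))
    xyz["C1", ] <- c(0, 0, -10.5)
    xyz["C2", ] <- c(0, 0, -13)
    attr(xyz, "anchor_beads") <- c("ROH", "R1", "R2", "R3")
    return(xyz)
  }
  lk <- sp$linker_beads
  xyz[lk[1], ] <- c(-1.5, 0, 0)
  xyz[lk[2], ] <- c(1.5, 0, 0)
  hb <- sp$head_beads
  nh <- length(hb)
  for (i in seq_len(nh))  # listed top-down; topmost head bead highest
    xyz[hb[i], ] <- c(0.4 * (-1)^i, 0, 2.5 * (nh - i + 1))
  tails <- sp$bead_names[!(sp$bead_names %in% c(hb, lk))]
  ta <- tails[seq_len(sp$tail_lengths[1])]
  tb <- tails[-seq_len(sp$tail_lengths[1])]
  # 3 A bead spacing; beads beyond the 4-bead reference tail are packed
  # tighter so long tails stay on their own side of the midplane
  tail_z <- function(j) -3 * pmin(j, 4) - 1.2 * pmax(0, j - 4)
  for (j in seq_along(ta)) xyz[ta[j], ] <- c(-1.5, 0, tail_z(j))
  for (j in seq_along(tb)) xyz[tb[j], ] <- c(1.5, 0, tail_z(j))
  # superimposition anchors: the first two tail beads carry the alignment;
  # the adjacent linker bead (congruent across templates) pins the
  # otherwise-free azimuthal orientation to the replaced molecule's
  attr(xyz, "anchor_beads") <- c(lk[1], ta[1], ta[2])
  xyz
}

# Rotation matrix mapping direction u onto direction v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  a <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(a^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)  # any axis ⊥ u
    a <- p - sum(p * u) * u; a <- a / sqrt(sum(a^2))
    return(2 * outer(a, a) - diag(3))
  }
  a <- a / s
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

# Rigid transform (rotation + translation, no reflection) taking point set P
# onto Q in the least-squares sense; Kabsch for >= 3 points, minimal rotation
# for 2. Returns function(X) applying the transform to an n x 3 matrix.
rigid_align <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) == 2L) {
    r <- rotation_between(p[2, ] - p[1, ], q[2, ] - q[1, ])
    t0 <- q[1, ] - as.numeric(r %*% p[1, ])
  } else {
    pc <- colMeans(p); qc <- colMeans(q)
    h <- t(sweep(p, 2, pc)) %*% sweep(q, 2, qc)
    s <- svd(h)
    d <- sign(det(s$v %*% t(s$u)))
    r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    t0 <- qc - as.numeric(r %*% pc)
  }
  function(x) sweep(as.matrix(x) %*% t(r), 2, t0, `+`)
}

#' Generate a flat all-POPC template bilayer
#'
#' Places `n_per_leaflet` POPC molecules per leaflet on a jittered square
#' lattice with the requested area per lipid, heads pointing outward and
#' tails toward the midplane (at `box_z / 2`). This is the starting point
#' the lipid-exchange builder edits.
#'
#' @param n_per_leaflet lipids per leaflet (>= 1).
#' @param apl area per lipid, Å²; the lateral box edge is
#'   `sqrt(n_per_leaflet * apl)`.
#' @param box_z box height, Å.
#' @param seed integer seed for the lattice jitter (NULL = current RNG).
#' @param jitter maximum lattice jitter per coordinate, Å.
#' @return a [membrane_frame] with leaflets tagged.
#' @export
generate_template_bilayer <- function(n_per_leaflet, apl = 53.3, box_z = 100,
                                      seed = NULL, jitter = 0.5) {
  stopifnot(n_per_leaflet >= 1)
  if (apl <= 0) stop("apl must be > 0")
  n <- as.integer(n_per_leaflet)
  L <- sqrt(n * apl)
  k <- ceiling(sqrt(n))
  spacing <- L / k
  idx <- seq_len(n) - 1L
  with_seed(seed, {
    sx <- (idx %% k + 0.5) * spacing + runif(2L * n, -jitter, jitter)[seq_len(n)]
    sy <- (idx %/% k + 0.5) * spacing + runif(n, -jitter, jitter)
    tpl <- lipid_template("POPC")
    nb <- nrow(tpl)
    gap <- 1.2  # tail-end clearance from the midplane, Å
    zs <- tpl[, 3] - min(tpl[, 3]) + gap
    mid <- box_z / 2
    up <- cbind(x = rep(sx, each = nb) + tpl[, 1],
                y = rep(sy, each = nb) + tpl[, 2],
                z = mid + zs)
    # lower-leaflet lattice staggered by half a cell so molecules reaching
    # the midplane from opposite sides are laterally offset
    lo <- cbind(x = rep(wrap_coords(sx + spacing / 2, L), each = nb) - tpl[, 1],
                y = rep(wrap_coords(sy + spacing / 2, L), each = nb) + tpl[, 2],
                z = mid - zs)
    atoms <- data.frame(
      mol = rep(seq_len(2L * n), each = nb),
      species = "POPC",
      bead = rep(rownames(tpl), 2L * n),
      x = c(up[, 1], lo[, 1]), y = c(up[, 2], lo[, 2]), z = c(up[, 3], lo[, 3]),
      stringsAsFactors = FALSE)
    membrane_frame(atoms, box = c(L, L, box_z),
                   leaflet = rep(c("outer", "inner"), each = n))
  })
}

#' Per-leaflet target composition
#'
#' @param outer,inner named numeric vectors of species fractions per leaflet
#'   (each summing to 1; aliases like "Sph" accepted).
#' @return object of class `composition_spec`.
#' @export
composition_spec <- function(outer, inner = outer) {
  check <- function(f, which) {
    if (is.null(names(f))) stop(which, " fractions must be named by species")
    if (any(f < 0)) stop("fractions must be >= 0")
    if (abs(sum(f) - 1) > 1e-9)
      stop(which, " fractions must sum to 1 (got ", format(sum(f)), ")")
    names(f) <- resolve_species(names(f))
    f
  }
  structure(list(outer = check(outer, "outer"), inner = check(inner, "inner")),
            class = "composition_spec")
}

#' The model plasma-membrane composition
#'
#' Outer leaflet POPC:POPE:Sph:GM3:Chol = 40:10:15:10:25, inner leaflet
#' POPC:POPE:POPS:PIP2:Chol = 10:40:15:10:25 — the asymmetric composition
#' mimicking a mammalian plasma membrane.
#' @return a [composition_spec].
#' @export
pm_composition <- function() {
  composition_spec(
    outer = c(POPC = 0.40, POPE = 0.10, PPCS = 0.15, GM3 = 0.10, CHOL = 0.25),
    inner = c(POPC = 0.10, POPE = 0.40, POPS = 0.15, PIP2 = 0.10, CHOL = 0.25))
}

#' Exchange POPC molecules for a target multi-species composition
#'
#' Edits an all-POPC template bilayer into the requested per-leaflet
#' composition. Per leaflet, integer species counts come from
#' largest-remainder rounding of the fractions; the molecules to convert
#' are drawn uniformly without replacement. Species of equal or shorter
#' chain length than POPC (POPE, POPS, sphingomyelin) are relabeled in
#' place bead-for-bead; larger species (PIP2, GM3, DOPC, DOPE, DOPS) are
#' rigid-superimposed via their idealized template onto the first two tail
#' beads of the selected POPC; cholesterol is superimposed onto the head
#' group plus the first three tail beads. The exchange is one-for-one, so
#' per-leaflet totals (and hence the equal non-cholesterol percentage per
#' leaflet) are preserved exactly.
#'
#' @param template all-POPC [membrane_frame] with leaflets assigned.
#' @param composition a [composition_spec].
#' @param seed integer seed controlling molecule selection.
#' @param registry species registry.
#' @return edited [membrane_frame]; per-leaflet target counts are attached
#'   as attribute `target_counts`.
#' @export
exchange_lipids <- function(template, composition, seed = NULL,
                            registry = default_lipid_registry()) {
  stopifnot(inherits(template, "membrane_frame"),
            inherits(composition, "composition_spec"))
  if (!all(template$molecules$species == "POPC"))
    stop("template must be an all-POPC bilayer")
  if (any(is.na(template$molecules$leaflet)))
    stop("template leaflets must be assigned")
  relabel_set <- c("POPE", "POPS", "PPCS")
  superimpose_set <- c("PIP2", "GM3", "DOPC", "DOPE", "DOPS")
  popc <- get_species("POPC", registry)
  popc_tails <- c("C1A", "D2A", "C3A")
  popc_anchor <- c("GL1", "C1A", "D2A")  # mirrors the template anchors

  with_seed(seed, {
    atoms <- template$atoms
    molecules <- template$molecules
    new_species <- molecules$species
    names(new_species) <- as.character(molecules$mol)
    assignments <- list()
    targets <- list()
    for (lf in c("outer", "inner")) {
      ids <- molecules$mol[molecules$leaflet == lf]
      if (!length(ids)) next
      fr <- composition[[lf]]
      counts <- largest_remainder(fr, length(ids))
      targets[[lf]] <- counts
      conv <- counts[setdiff(names(counts), "POPC")]
      if (sum(conv) > length(ids))
        stop("target counts exceed available POPC in ", lf, " leaflet")
      pool <- sample(ids)
      off <- 0L
      for (sp in names(conv)) {
        if (conv[[sp]] == 0L) next
        take <- pool[(off + 1L):(off + conv[[sp]])]
        off <- off + conv[[sp]]
        new_species[as.character(take)] <- sp
        assignments[[paste(lf, sp)]] <- take
      }
    }

    changed <- names(new_species)[new_species != molecules$species]
    # Order POPC beads canonically within each molecule (template frames
    # already are; GRO-read templates may not be).
    ord <- order(atoms$mol, match(atoms$bead, popc$bead_names))
    atoms <- atoms[ord, ]
    keep <- !(atoms$mol %in% as.integer(changed))
    pieces <- list(atoms[keep, c("mol", "species", "bead", "x", "y", "z")])

    for (sp in unique(new_species[changed])) {
      mols <- as.integer(names(new_species)[new_species == sp &
                                            names(new_species) %in% changed])
      spec <- get_species(sp, registry)
      if (sp %in% relabel_set) {
        sub <- atoms[atoms$mol %in% mols, ]
        nb <- length(spec$bead_names)
        within <- stats::ave(seq_len(nrow(sub)), sub$mol, FUN = seq_along)
        sub <- sub[within <= nb, ]
        sub$bead <- spec$bead_names[stats::ave(seq_len(nrow(sub)), sub$mol,
                                               FUN = seq_along)]
        sub$species <- sp
        pieces[[length(pieces) + 1L]] <-
          sub[, c("mol", "species", "bead", "x", "y", "z")]
      } else {
        tpl <- lipid_template(sp, registry)
        anchors <- attr(tpl, "anchor_beads")
        tgt_beads <- if (sp == "CHOL") c("PO4", popc_tails) else popc_anchor
        out <- vector("list", length(mols))
        for (k in seq_along(mols)) {
          m <- mols[k]
          old <- atoms[atoms$mol == m, ]
          q <- as.matrix(old[match(tgt_beads, old$bead), c("x", "y", "z")])
          tr <- rigid_align(tpl[anchors, , drop = FALSE], q)
          xyz <- tr(tpl)
          out[[k]] <- data.frame(mol = m, species = sp,
                                 bead = rownames(tpl),
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 stringsAsFactors = FALSE)
        }
        pieces[[length(pieces) + 1L]] <- do.call(rbind, out)
      }
    }
    new_atoms <- do.call(rbind, pieces)
    new_atoms <- new_atoms[order(new_atoms$mol), ]
    rownames(new_atoms) <- NULL
    out <- membrane_frame(new_atoms, template$box, template$time,
                          leaflet = molecules$leaflet, registry = registry)
    attr(out, "target_counts") <- targets
    attr(out, "seed") <- seed
    out
  })
}

#' Build a membrane from a recipe in one call
#'
#' Convenience wrapper: template generation + lipid exchange (+ optional
#' protein grid). Attaches a build report (per-leaflet counts, area per
#' lipid, seed) as attribute `build_report`.
#'
#' @param composition a [composition_spec].
#' @param n_lipids total lipid count (split equally between leaflets).
#' @param apl template area per lipid, Å².
#' @param seed integer seed.
#' @param protein optional list(n, spacing, exclusion_radius) forwarded to
#'   [place_protein_grid()].
#' @return a [membrane_frame].
#' @export
build_membrane <- function(composition = pm_composition(), n_lipids = 1500,
                           apl = 53.3, seed = NULL, protein = NULL) {
  if (n_lipids %% 2L != 0L) stop("n_lipids must be even")
  tpl <- generate_template_bilayer(n_lipids / 2L, apl = apl, seed = seed)
  out <- exchange_lipids(tpl, composition, seed = seed)
  if (!is.null(protein))
    out <- do.call(place_protein_grid,
                   c(list(frame = out), protein))
  attr(out, "build_report") <- list(
    seed = seed, n_lipids = n_lipids, apl_template = apl,
    counts = list(outer = as.list(composition_counts(out, "outer")),
                  inner = as.list(composition_counts(out, "inner"))),
    apl = list(outer = area_per_lipid(out, "outer"),
               inner = area_per_lipid(out, "inner")))
  out
}

# Idealized transmembrane helix: one backbone bead per residue, 1.5 Å rise,
# 100 degrees per residue, 2.3 Å helical radius, centered on z_center.
tm_helix_coords <- function(n_res = 24, z_center = 0) {
  r <- seq_len(n_res)
  cbind(x = 2.3 * cos(r * 100 * pi / 180),
        y = 2.3 * sin(r * 100 * pi / 180),
        z = z_center + (r - (n_res + 1) / 2) * 1.5)
}

#' Place transmembrane proteins on a regular lateral grid
#'
#' Inserts `n_proteins` idealized single-helix transmembrane domains at the
#' nodes of a regular grid with the given spacing (so the minimum pairwise
#' lateral center distance equals `spacing` exactly, periodic images
#' included, when the grid spans the box). Lipid molecules with any bead
#' within `exclusion_radius` of any protein bead are deleted.
#'
#' @param frame a [membrane_frame] with leaflets assigned.
#' @param n_proteins number of proteins; a perfect square unless
#'   `grid_dims` is given.
#' @param spacing grid spacing, Å.
#' @param exclusion_radius lipid deletion radius around protein beads, Å.
#' @param n_res residues (backbone beads) per helix.
#' @param grid_dims optional `c(gx, gy)` with `gx * gy == n_proteins`.
#' @return frame with proteins added (species `"PROT"`, bead `"BB"`,
#'   residue indices 1..n_res) and clashing lipids removed.
#' @export
place_protein_grid <- function(frame, n_proteins, spacing = 60,
                               exclusion_radius = 3, n_res = 24,
                               grid_dims = NULL) {
  stopifnot(inherits(frame, "membrane_frame"), n_proteins >= 1)
  if (is.null(grid_dims)) {
    g <- round(sqrt(n_proteins))
    if (g * g != n_proteins)
      stop("n_proteins must be a perfect square (or give grid_dims)")
    grid_dims <- c(g, g)
  }
  if (prod(grid_dims) != n_proteins) stop("grid_dims do not match n_proteins")
  if (grid_dims[1] * spacing > frame$box[1] + 1e-6 ||
      grid_dims[2] * spacing > frame$box[2] + 1e-6)
    stop("protein grid does not fit in the lateral box")

  # bilayer midplane from linker beads
  at <- frame$atoms
  reg <- default_lipid_registry()
  is_lk <- logical(nrow(at))
  for (sp in setdiff(unique(at$species), "PROT")) {
    lb <- reg[[sp]]$linker_beads
    if (length(lb)) is_lk <- is_lk | (at$species == sp & at$bead %in% lb)
  }
  zc <- mean(at$z[is_lk])

  helix <- tm_helix_coords(n_res, z_center = zc)
  centers <- expand.grid(gx = seq_len(grid_dims[1]), gy = seq_len(grid_dims[2]))
  base_mol <- max(frame$molecules$mol)
  prot_atoms <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    data.frame(mol = base_mol + i, species = "PROT", bead = "BB",
               x = helix[, 1] + (centers$gx[i] - 0.5) * spacing,
               y = helix[, 2] + (centers$gy[i] - 0.5) * spacing,
               z = helix[, 3], residue = seq_len(n_res),
               stringsAsFactors = FALSE)
  }))

  drop_mol <- integer(0)
  if (exclusion_radius > 0) {
    lip <- at[at$species != "PROT", ]
    hits <- cross_pair_distances(
      as.matrix(lip[, c("x", "y", "z")]),
      as.matrix(prot_atoms[, c("x", "y", "z")]),
      frame$box, exclusion_radius, lateral = FALSE)
    drop_mol <- unique(lip$mol[hits$i])
  }
  keep <- !(at$mol %in% drop_mol)
  at2 <- at[keep, c("mol", "species", "bead", "x", "y", "z")]
  at2$residue <- at$residue[keep]
  new_atoms <- rbind(at2, prot_atoms[, names(at2)])
  tags <- c(frame$molecules$leaflet[!(frame$molecules$mol %in% drop_mol)],
            rep("protein", n_proteins))
  out <- membrane_frame(new_atoms, frame$box, frame$time, leaflet = tags)
  attr(out, "deleted_lipids") <- drop_mol
  out
}

#' Tile a frame laterally
#'
#' Replicates the frame `nx` by `ny` times in the membrane plane (the
#' genconf-style construction of larger patches), scaling the lateral box
#' and renumbering molecules uniquely.
#'
#' @param frame a [membrane_frame].
#' @param nx,ny replication counts (>= 1).
#' @return the tiled [membrane_frame].
#' @export
replicate_frame <- function(frame, nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx == 1L && ny == 1L) return(frame)
  nmol <- max(frame$molecules$mol)
  tiles <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  pieces <- lapply(seq_len(nrow(tiles)), function(t) {
    a <- frame$atoms
    a$x <- a$x + tiles$ix[t] * frame$box[1]
    a$y <- a$y + tiles$iy[t] * frame$box[2]
    a$mol <- a$mol + (t - 1L) * nmol
    a
  })
  atoms <- do.call(rbind, pieces)
  membrane_frame(atoms,
                 box = frame$box * c(nx, ny, 1),
                 time = frame$time,
                 leaflet = rep(frame$molecules$leaflet, nrow(tiles)))
}

#' Area per lipid of a leaflet
#'
#' Lateral box area divided by the number of lipid molecules carrying the
#' leaflet tag. Cholesterol is counted in the leaflet it is currently
#' tagged with (set `include_cholesterol = FALSE` to exclude it).
#'
#' @param frame a [membrane_frame] with leaflets assigned.
#' @param leaflet `"outer"` or `"inner"`.
#' @param include_cholesterol logical.
#' @return area per lipid in Å².
#' @export
area_per_lipid <- function(frame, leaflet, include_cholesterol = TRUE) {
  ids <- select_leaflet(frame, leaflet)
  m <- frame$molecules
  sel <- m$mol %in% ids & m$species != "PROT"
  if (!include_cholesterol) sel <- sel & m$species != "CHOL"
  n <- sum(sel)
  if (n == 0L) stop("no lipids in ", leaflet, " leaflet")
  frame$box[1] * frame$box[2] / n
}
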