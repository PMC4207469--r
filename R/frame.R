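#' Construct a membrane frame
#'
#' A `membrane_frame` is one snapshot of a CG membrane: a bead table grouped
#' into molecules, orthorhombic box vectors in Å, an optional per-molecule
#' leaflet tag (`outer`, `inner`, `core` or `protein`) and a time stamp in
#' ns. Protein molecules use the reserved species name `"PROT"`; every other
#' species must exist in the registry.
#'
#' @param atoms data.frame with columns `mol` (integer molecule id),
#'   `species`, `bead` (character), `x`, `y`, `z` (Å) and optionally
#'   `residue` (integer, used for protein beads) and velocities `vx`, `vy`,
#'   `vz` (nm/ps, carried through I/O only).
#' @param box numeric length-3 box edge lengths, Å (orthorhombic).
#' @param time frame time in ns.
#' @param leaflet optional character vector of leaflet tags, one per
#'   molecule in order of first appearance in `atoms`.
#' @param registry species registry used for validation.
#' @return object of class `membrane_frame` with elements `atoms`, `box`,
#'   `time` and `molecules` (data.frame `mol`, `species`, `leaflet`).
#' @export
membrane_frame <- function(atoms, box, time = 0, leaflet = NULL,
                           registry = default_lipid_registry()) {
  stopifnot(is.data.frame(atoms),
            all(c("mol", "species", "bead", "x", "y", "z") %in% names(atoms)))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive orthorhombic edge lengths (A)")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("all coordinates must be finite")
  if (!"residue" %in% names(atoms)) atoms$residue <- 1L
  atoms$mol <- as.integer(atoms$mol)

  first <- !duplicated(atoms$mol)
  mol_ids <- atoms$mol[first]
  if (anyDuplicated(mol_ids)) stop("molecule ids must be unique (non-contiguous bead groups)")
  mol_species <- atoms$species[first]
  lipid <- mol_species != "PROT"
  resolve_species(unique(mol_species[lipid]), registry)  # errors on unknown

  if (is.null(leaflet)) {
    leaflet <- rep(NA_character_, length(mol_ids))
    leaflet[!lipid] <- "protein"
  } else {
    if (length(leaflet) != length(mol_ids))
      stop("leaflet must have one tag per molecule")
    ok <- is.na(leaflet) | leaflet %in% c("outer", "inner", "core", "protein")
    if (!all(ok)) stop("leaflet tags must be outer/inner/core/protein")
  }
  molecules <- data.frame(mol = mol_ids, species = mol_species,
                          leaflet = leaflet, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, box = box, time = as.numeric(time),
                 molecules = molecules),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  tab <- table(x$molecules$species)
  cat(sprintf("<membrane_frame t=%.3f ns, %d molecules / %d beads, box %.1f x %.1f x %.1f A>\n",
              x$time, nrow(x$molecules), nrow(x$atoms),
              x$box[1], x$box[2], x$box[3]))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  if (!all(is.na(x$molecules$leaflet))) {
    lt <- table(x$molecules$leaflet, useNA = "ifany")
    cat("  leaflets:", paste(sprintf("%s:%d", names(lt), lt), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of molecules in a frame
#' @param frame a [membrane_frame].
#' @export
n_molecules <- function(frame) nrow(frame$molecules)

# Internal: molecule ids selected by leaflet label.
select_leaflet <- function(frame, leaflet) {
  if (identical(leaflet, "all")) return(frame$molecules$mol)
  if (!leaflet %in% c("outer", "inner", "core", "protein"))
    stop("unknown leaflet label: ", leaflet)
  tags <- frame$molecules$leaflet
  if (leaflet != "protein" && all(is.na(tags[frame$molecules$species != "PROT"])))
    stop("leaflets not assigned; call assign_leaflets() first")
  frame$molecules$mol[!is.na(tags) & tags == leaflet]
}

# Internal: per-molecule reference points.
# role "head": head-bead centroid (ROH for cholesterol, since it is the only
#   head bead); "linker": linker-bead centroid; "interface": the interface
#   bead; "all": centroid of all beads (used for proteins).
# Returns data.frame(mol, species, x, y, z) in frame molecule order,
# dropping molecules that lack beads of the requested role.
mol_points <- function(frame, role = c("head", "linker", "interface", "all"),
                       registry = default_lipid_registry()) {
  role <- match.arg(role)
  at <- frame$atoms
  if (role == "all") {
    keep <- rep(TRUE, nrow(at))
  } else {
    sel_beads <- function(sp) {
      if (sp == "PROT") return(character(0))
      s <- get_species(sp, registry)
      switch(role, head = s$head_beads, linker = s$linker_beads,
             interface = s$interface_bead)
    }
    specs <- unique(at$species)
    want <- lapply(specs, sel_beads)
    names(want) <- specs
    keep <- logical(nrow(at))
    for (sp in specs) {
      w <- want[[sp]]
      if (length(w)) keep <- keep | (at$species == sp & at$bead %in% w)
    }
  }
  sub <- at[keep, c("mol", "species", "x", "y", "z")]
  if (nrow(sub) == 0L)
    return(data.frame(mol = integer(0), species = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  g <- factor(sub$mol, levels = unique(sub$mol))
  n <- tabulate(g)
  out <- data.frame(
    mol = as.integer(levels(g)),
    species = sub$species[!duplicated(sub$mol)],
    x = as.numeric(rowsum(sub$x, g)) / n,
    y = as.numeric(rowsum(sub$y, g)) / n,
    z = as.numeric(rowsum(sub$z, g)) / n,
    stringsAsFactors = FALSE)
  out
}

# Reference point used for leaflet assignment and clustering:
# head-bead centroid for lipids (= ROH for cholesterol), all-bead centroid
# for proteins.
reference_points <- function(frame, registry = default_lipid_registry()) {
  pts <- mol_points(frame, "head", registry)
  prot <- frame$molecules$mol[frame$molecules$species == "PROT"]
  if (length(prot)) {
    allp <- mol_points(frame, "all", registry)
    pts <- rbind(pts, allp[allp$mol %in% prot, ])
  }
  pts[match(frame$molecules$mol, pts$mol), ]
}

#' Per-species molecule counts in a leaflet
#'
#' Exact integer composition counts over the molecules carrying a given
#' leaflet tag (or all non-protein molecules for `"all"`).
#'
#' @param frame a [membrane_frame].
#' @param leaflet one of `"all"`, `"outer"`, `"inner"`, `"core"`.
#' @return named integer vector of counts (species present in the frame).
#' @export
composition_counts <- function(frame, leaflet = "all") {
  ids <- select_leaflet(frame, leaflet)
  m <- frame$molecules
  sel <- m$mol %in% ids & m$species != "PROT"
  tab <- table(factor(m$species[sel],
                      levels = sort(unique(m$species[m$species != "PROT"]))))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
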