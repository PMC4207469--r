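#' Define a coarse-grained lipid species
#'
#' A `lipid_species` records the static bead topology of one CG lipid type:
#' the ordered bead names, which beads form the head group (used for cluster
#' and grid positions), which beads are the linkers joining head to tails
#' (the glycerol ester moiety of glycerolipids or the amino-alcohol backbone
#' of sphingolipids; these carry the lipid-lipid contact rule), the first
#' tail bead adjacent to the head group (defining the head/tail interface
#' surface), the tail lengths in beads, and the net charge.
#'
#' @param name short species identifier, e.g. "POPC".
#' @param bead_names ordered character vector of bead names.
#' @param head_beads subset of `bead_names` forming the head group.
#' @param linker_beads subset of `bead_names` used by the lipid-lipid
#'   contact rule; may be empty (cholesterol).
#' @param interface_bead single bead name marking the head/tail interface.
#' @param tail_lengths integer vector, beads per tail (each >= 1).
#' @param net_charge integer net charge in elementary charges.
#' @return an object of class `lipid_species`.
#' @export
lipid_species <- function(name, bead_names, head_beads, linker_beads,
                          interface_bead, tail_lengths, net_charge = 0L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bead_names), !anyDuplicated(bead_names))
  if (!all(head_beads %in% bead_names))
    stop("head_beads must be a subset of bead_names for ", name)
  if (!all(linker_beads %in% bead_names))
    stop("linker_beads must be a subset of bead_names for ", name)
  if (!all(interface_bead %in% bead_names) || length(interface_bead) != 1L)
    stop("interface_bead must be one of bead_names for ", name)
  if (any(tail_lengths < 1)) stop("tail_lengths must be >= 1 for ", name)
  structure(list(name = name,
                 bead_names = bead_names,
                 head_beads = head_beads,
                 linker_beads = linker_beads,
                 interface_bead = interface_bead,
                 tail_lengths = as.integer(tail_lengths),
                 net_charge = as.integer(net_charge)),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species %s: %d beads, head {%s}, linker {%s}, charge %+d>\n",
              x$name, length(x$bead_names),
              paste(x$head_beads, collapse = ","),
              paste(x$linker_beads, collapse = ","),
              x$net_charge))
  invisible(x)
}

# Glycerophospholipid constructor: <head bead> PO4 GL1 GL2 + two tails.
.glycerolipid <- function(name, head_bead, tail_a, tail_b, charge = 0L) {
  lipid_species(name,
                bead_names = c(head_bead, "PO4", "GL1", "GL2", tail_a, tail_b),
                head_beads = c(head_bead, "PO4"),
                linker_beads = c("GL1", "GL2"),
                interface_bead = tail_a[1],
                tail_lengths = c(length(tail_a), length(tail_b)),
                net_charge = charge)
}

#' Default registry of CG lipid species
#'
#' MARTINI-style bead topologies for the ten species handled by the builder
#' and analyses: POPC, POPE, POPS, DOPC, DOPE, DOPS, PPCS (sphingomyelin),
#' GM3, PIP2 and CHOL. Sphingomyelin and GM3 carry two 4-bead ceramide
#' tails on an AM1/AM2 amino-alcohol backbone; PIP2 carries a 4- and a
#' 5-bead unsaturated tail and an exposed PO3 phosphate bead; cholesterol
#' is a rigid ROH + ring body with no glycerol linker. The GM3 sugar head
#' group here is an idealized 9-bead (three 3-bead hexose/sialic-acid rings)
#' topology: bead geometry is idealized, only topology-level roles (head,
#' linker, interface) matter to the analyses.
#'
#' @return named list of [lipid_species] objects.
#' @export
default_lipid_registry <- function() {
  po_a <- c("C1A", "D2A", "C3A", "C4A")   # palmitoyl-oleoyl tail pair
  po_b <- c("C1B", "C2B", "C3B", "C4B")
  do_b <- c("C1B", "D2B", "C3B", "C4B")   # di-oleoyl second tail
  sph_a <- c("C1A", "C2A", "C3A", "C4A")  # ceramide tails: sphingosine first
  sph_b <- c("D1B", "C2B", "C3B", "C4B")  # bead of tail B unsaturated
  species <- list(
    .glycerolipid("POPC", "NC3", po_a, po_b),
    .glycerolipid("POPE", "NH3", po_a, po_b),
    .glycerolipid("POPS", "CNO", po_a, po_b, charge = -1L),
    .glycerolipid("DOPC", "NC3", po_a, do_b),
    .glycerolipid("DOPE", "NH3", po_a, do_b),
    .glycerolipid("DOPS", "CNO", po_a, do_b, charge = -1L),
    lipid_species("PPCS",
                  bead_names = c("NC3", "PO4", "AM1", "AM2", sph_a, sph_b),
                  head_beads = c("NC3", "PO4"),
                  linker_beads = c("AM1", "AM2"),
                  interface_bead = "C1A",
                  tail_lengths = c(4L, 4L)),
    lipid_species("GM3",
                  bead_names = c("GC1", "GC2", "GC3",  # glucose
                                 "GA1", "GA2", "GA3",  # galactose
                                 "SA1", "SA2", "SA3",  # sialic acid
                                 "AM1", "AM2", sph_a, sph_b),
                  head_beads = c("GC1", "GC2", "GC3", "GA1", "GA2", "GA3",
                                 "SA1", "SA2", "SA3"),
                  linker_beads = c("AM1", "AM2"),
                  interface_bead = "C1A",
                  tail_lengths = c(4L, 4L),
                  net_charge = -1L),
    lipid_species("PIP2",
                  bead_names = c("C1", "C2", "C3", "PO3", "PO4", "GL1", "GL2",
                                 "D1A", "C2A", "C3A", "C4A",
                                 "D1B", "C2B", "C3B", "C4B", "C5B"),
                  head_beads = c("C1", "C2", "C3", "PO3", "PO4"),
                  linker_beads = c("GL1", "GL2"),
                  interface_bead = "D1A",
                  tail_lengths = c(4L, 5L),
                  net_charge = -4L),
    lipid_species("CHOL",
                  bead_names = c("ROH", "R1", "R2", "R3", "R4", "R5",
                                 "C1", "C2"),
                  head_beads = "ROH",
                  linker_beads = character(0),
                  interface_bead = "R1",
                  tail_lengths = 2L)
  )
  names(species) <- vapply(species, `[[`, "", "name")
  species
}

# Alias table: common synonyms accepted on input.
.species_aliases <- c(Sph = "PPCS", SM = "PPCS", CHO = "CHOL", Chol = "CHOL")

#' Resolve species names against a registry
#'
#' Accepts canonical names and common aliases ("Sph" for PPCS, "Chol" for
#' CHOL) and returns canonical names, erroring on unknown species.
#'
#' @param x character vector of species names.
#' @param registry species registry, default [default_lipid_registry()].
#' @return character vector of canonical names.
#' @export
resolve_species <- function(x, registry = default_lipid_registry()) {
  out <- ifelse(x %in% names(.species_aliases), .species_aliases[x], x)
  bad <- setdiff(out, names(registry))
  if (length(bad))
    stop("unknown lipid species: ", paste(unique(bad), collapse = ", "))
  unname(out)
}

#' Look up one species in a registry
#' @inheritParams resolve_species
#' @param name species name or alias.
#' @return a [lipid_species].
#' @export
get_species <- function(name, registry = default_lipid_registry()) {
  registry[[resolve_species(name, registry)]]
}
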