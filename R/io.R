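# GRO fixed-column I/O. Files are in nm (GROMACS convention); everything
# internal is Å. Residue numbering is 1-based in files; molecules are
# recovered from consecutive runs of the residue number.

.parse_gro_block <- function(lines, offset, registry) {
  if (length(lines) < offset + 2L)
    stop("truncated GRO record at line ", offset)
  natoms <- suppressWarnings(as.integer(trimws(lines[offset + 1L])))
  if (is.na(natoms))
    stop("malformed atom count at line ", offset + 1L)
  if (length(lines) < offset + 1L + natoms + 1L)
    stop("file ends before the ", natoms, " atom records starting at line ",
         offset + 2L, " complete")
  rec <- lines[(offset + 2L):(offset + 1L + natoms)]
  bad <- which(nchar(rec) < 44)
  if (length(bad))
    stop("truncated atom record at line ", offset + 1L + bad[1])
  resid <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  bead <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28)) * 10
  y <- as.numeric(substr(rec, 29, 36)) * 10
  z <- as.numeric(substr(rec, 37, 44)) * 10
  if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("unparseable atom record at line ",
         offset + 1L + which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))[1])
  vel <- NULL
  if (all(nchar(rec) >= 68)) {
    vel <- cbind(vx = as.numeric(substr(rec, 45, 52)),
                 vy = as.numeric(substr(rec, 53, 60)),
                 vz = as.numeric(substr(rec, 61, 68)))
    if (anyNA(vel)) vel <- NULL
  }
  boxline <- strsplit(trimws(lines[offset + 2L + natoms]), "\\s+")[[1]]
  boxv <- suppressWarnings(as.numeric(boxline))
  if (anyNA(boxv) || length(boxv) < 3)
    stop("malformed box line at line ", offset + 2L + natoms)
  if (length(boxv) > 3 && any(abs(boxv[4:length(boxv)]) > 1e-9))
    stop("triclinic boxes are not supported (line ", offset + 2L + natoms, ")")
  # molecule grouping: lipids are one residue each (new molecule when the
  # residue number changes); protein beads carry their residue number, so a
  # protein molecule is a run of non-decreasing PROT residues
  isp <- resname == "PROT"
  newmol <- c(TRUE, ifelse(isp[-1] & isp[-natoms],
                           resid[-1] < resid[-natoms],
                           resid[-1] != resid[-natoms] |
                             resname[-1] != resname[-natoms]))
  mol <- cumsum(newmol)
  title <- lines[offset]
  tm <- regmatches(title, regexpr("t= *[0-9.eE+-]+", title))
  time <- if (length(tm)) as.numeric(sub("t= *", "", tm)) else 0
  atoms <- data.frame(mol = mol, species = resname, bead = bead,
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  atoms$residue <- 1L
  if (!is.null(vel)) {
    atoms$vx <- vel[, 1]; atoms$vy <- vel[, 2]; atoms$vz <- vel[, 3]
  }
  # residue index within protein molecules: each residue number is one bead
  prot <- atoms$species == "PROT"
  if (any(prot)) atoms$residue[prot] <- ave(resid[prot], mol[prot],
                                            FUN = function(r) r - r[1] + 1L)
  list(frame = membrane_frame(atoms, box = boxv[1:3] * 10, time = time,
                              registry = registry),
       next_offset = offset + 3L + natoms)
}

#' Read a GRO coordinate file
#'
#' Fixed-column GROMACS GRO dialect; coordinates are converted from nm to
#' the internal Å. Molecules are inferred from consecutive runs of the
#' residue number; velocities, if present, are carried through. Multi-frame
#' files: use [read_trajectory()].
#'
#' @param path file path.
#' @param registry species registry used for validation.
#' @return a [membrane_frame].
#' @export
read_gro <- function(path, registry = default_lipid_registry()) {
  lines <- readLines(path)
  .parse_gro_block(lines, 1L, registry)$frame
}

.format_gro_block <- function(frame) {
  at <- frame$atoms
  resid <- at$mol
  prot <- at$species == "PROT"
  # proteins: the GRO residue number is the within-protein residue index,
  # so per-residue identity survives the round trip
  if (any(prot)) resid[prot] <- at$residue[prot]
  has_vel <- all(c("vx", "vy", "vz") %in% names(at)) &&
    !anyNA(at$vx)
  atomid <- seq_len(nrow(at))
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  resid %% 100000L, at$species, at$bead,
                  atomid %% 100000L, at$x / 10, at$y / 10, at$z / 10)
  if (has_vel)
    body <- paste0(body, sprintf("%8.4f%8.4f%8.4f", at$vx, at$vy, at$vz))
  c(sprintf("membrane frame t= %.4f ns", frame$time),
    sprintf("%5d", nrow(at)),
    body,
    sprintf("%10.5f%10.5f%10.5f", frame$box[1] / 10, frame$box[2] / 10,
            frame$box[3] / 10))
}

#' Write a frame to a GRO coordinate file
#'
#' @param frame a [membrane_frame].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path) {
  writeLines(.format_gro_block(frame), path)
  invisible(path)
}

#' Read a multi-frame GRO trajectory
#'
#' Reads one file with concatenated GRO frames (or a character vector of
#' single-frame files) into a [trajectory]. All frames must share molecule
#' count and ordering. Frame times are taken from the `t=` stamp in each
#' title line, falling back to `0, dt, 2 dt, ...`.
#'
#' @param paths one multi-frame file or several single-frame files.
#' @param dt frame spacing in ns used when no time stamps are present.
#' @param registry species registry.
#' @return a [trajectory] (bead-level frames retained).
#' @export
read_trajectory <- function(paths, dt = NULL,
                            registry = default_lipid_registry()) {
  frames <- list()
  for (p in paths) {
    lines <- readLines(p)
    offset <- 1L
    while (offset <= length(lines) && nzchar(trimws(paste(
           lines[offset], collapse = "")))) {
      blk <- .parse_gro_block(lines, offset, registry)
      frames[[length(frames) + 1L]] <- blk$frame
      offset <- blk$next_offset
      if (offset > length(lines)) break
    }
  }
  as_trajectory(frames, dt = dt)
}

#' Write a multi-frame GRO trajectory
#'
#' @param frames list of [membrane_frame]s (or a [trajectory] with frames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  frames <- get_frames(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) writeLines(.format_gro_block(fr), con)
  invisible(path)
}

#' Write a GROMACS-style molecule-count topology listing
#'
#' Emits a `[ molecules ]` block listing consecutive runs of identical
#' species with their counts, in frame order.
#'
#' @param frame a [membrane_frame].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_counts <- function(frame, path) {
  r <- rle(frame$molecules$species)
  writeLines(c("[ molecules ]",
               "; name   count",
               sprintf("%-8s %6d", r$values, r$lengths)), path)
  invisible(path)
}

#' Write a JSON build/analysis report with provenance
#'
#' Serializes a named list (parameters, seeds, counts, results) to JSON so
#' every output can be regenerated from its inputs.
#'
#' @param report named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
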