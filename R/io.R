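# Trajectory and table I/O. Structures and multi-frame trajectories are
# written as multi-model PDB, GRO, or binary DCD; PDB and DCD are read back
# through bio3d. GRO has no R reader, so a fixed-width parser lives here.

.res_name <- function(atoms) {
  if (!is.null(atoms$resname)) return(substr(atoms$resname, 1, 3))
  rn <- ifelse(atoms$role == "water", "WAT",
        ifelse(atoms$role == "cation", substr(atoms$species, 1, 3),
        ifelse(atoms$role == "anion", substr(atoms$species, 1, 3), "UNK")))
  rn
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' One MODEL block per frame, with a CRYST1 record carrying the cubic box.
#' Species labels survive through residue and atom names.
#'
#' @param traj a [sim_trajectory()].
#' @param file output path.
#' @param frames frame indices to write (default all).
#' @return `file`, invisibly.
#' @export
write_pdb_frames <- function(traj, file, frames = seq_len(n_frames(traj))) {
  L <- traj$box$edge_length
  atoms <- traj$atoms
  rn <- .res_name(atoms)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", L, L, L,
    90, 90, 90), con)
  serial <- seq_len(nrow(atoms))
  for (f in frames) {
    writeLines(sprintf("MODEL %8d", f), con)
    x <- traj$coords[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial %% 100000, substr(atoms$name, 1, 4), rn,
      atoms$resid %% 10000, x[, 1], x[, 2], x[, 3], 1, 0,
      substr(atoms$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a (multi-model) PDB file into a trajectory
#'
#' Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param file PDB path.
#' @param timestep frame spacing to stamp on the result (ps).
#' @return a [sim_trajectory()].
#' @export
read_pdb_frames <- function(file, timestep = 1) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(pdb$atom)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3,
                                                 byrow = TRUE)
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  role <- ifelse(pdb$atom$resid == "WAT" | pdb$atom$resid == "HOH",
                 "water",
          ifelse(trimws(elem) == "H", "protein_hydrogen", "protein_heavy"))
  role[trimws(pdb$atom$resid) %in% c("K", "NA", "LI", "CS")] <- "cation"
  role[trimws(pdb$atom$resid) %in% c("CL", "BR", "I", "ACE")] <- "anion"
  role[role == "water" & substr(trimws(pdb$atom$elety), 1, 1) == "H"] <- "water"
  atoms <- data.frame(species = trimws(pdb$atom$resid), role = role,
                      name = trimws(pdb$atom$elety), element = trimws(elem),
                      resid = pdb$atom$resno,
                      resname = trimws(pdb$atom$resid),
                      stringsAsFactors = FALSE)
  atoms$name[atoms$role == "water" & atoms$name %in% c("OW", "OH2")] <- "O"
  L <- if (!is.null(pdb$cryst1$abc)) pdb$cryst1$abc[1] else {
    cl <- grep("^CRYST1", readLines(file, n = 50), value = TRUE)
    if (length(cl)) as.numeric(substr(cl[1], 7, 15)) else NA_real_
  }
  box <- box_spec(if (is.finite(L) && L > 0) L else
    max(apply(coords, 2, max)) + 1)
  sim_trajectory(coords, atoms, box, timestep = timestep, wrapped = TRUE)
}

#' Write a trajectory in GRO format
#'
#' Multi-frame GRO: concatenated frame blocks, positions in nm, cubic box
#' line per frame. Format precision is 0.001 nm.
#'
#' @inheritParams write_pdb_frames
#' @export
write_gro <- function(traj, file, frames = seq_len(n_frames(traj))) {
  atoms <- traj$atoms
  rn <- .res_name(atoms)
  Lnm <- angstrom_to_nm(traj$box$edge_length)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in frames) {
    x <- angstrom_to_nm(traj$coords[, , f])
    writeLines(sprintf("halosolv synthetic frame %d, t= %.3f", f,
                       (f - 1) * traj$timestep), con)
    writeLines(sprintf("%5d", nrow(atoms)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resid %% 100000, substr(rn, 1, 5),
                       substr(atoms$name, 1, 5),
                       seq_len(nrow(atoms)) %% 100000,
                       x[, 1], x[, 2], x[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", Lnm, Lnm, Lnm), con)
  }
  invisible(file)
}

#' Read a (multi-frame) GRO file
#'
#' @param file GRO path.
#' @param timestep frame spacing (ps).
#' @return a [sim_trajectory()].
#' @export
read_gro <- function(file, timestep = 1) {
  lines <- readLines(file)
  frames <- list(); atoms <- NULL; Lnm <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i + 1L]))
    block <- lines[(i + 2L):(i + 1L + n)]
    x <- cbind(as.numeric(substr(block, 21, 28)),
               as.numeric(substr(block, 29, 36)),
               as.numeric(substr(block, 37, 44)))
    if (is.null(atoms)) {
      resname <- trimws(substr(block, 6, 10))
      name <- trimws(substr(block, 11, 15))
      role <- ifelse(resname %in% c("WAT", "SOL", "HOH"), "water",
              ifelse(resname %in% c("K", "NA", "LI", "CS"), "cation",
              ifelse(resname %in% c("CL", "ACE", "BR"), "anion",
                     "protein_heavy")))
      atoms <- data.frame(species = resname, role = role, name = name,
                          element = substr(name, 1, 1),
                          resid = as.integer(substr(block, 1, 5)),
                          resname = resname, stringsAsFactors = FALSE)
      Lnm <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]][1])
    }
    frames[[length(frames) + 1L]] <- nm_to_angstrom(x)
    i <- i + 3L + n
  }
  coords <- array(NA_real_, c(nrow(atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  sim_trajectory(coords, atoms, box_spec(nm_to_angstrom(Lnm)),
                 timestep = timestep, wrapped = TRUE)
}

#' Write a trajectory in binary DCD format
#'
#' CHARMM-flavour DCD (single precision, no unit-cell records), readable by
#' [bio3d::read.dcd()] and standard analysis toolkits.
#'
#' @inheritParams write_pdb_frames
#' @export
write_dcd <- function(traj, file, frames = seq_len(n_frames(traj))) {
  con <- file(file, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, size) {
    writeBin(as.integer(size), con, size = 4)
    payload_writer()
    writeBin(as.integer(size), con, size = 4)
  }
  nf <- length(frames)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "halosolv synthetic trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(n_atoms(traj), con, size = 4), 4)
  sz <- 4L * n_atoms(traj)
  for (f in frames) {
    x <- traj$coords[, , f]
    for (d in 1:3) rec(function() writeBin(as.numeric(x[, d]), con, size = 4),
                       sz)
  }
  invisible(file)
}

#' Read a DCD trajectory (via bio3d) given an atom table
#'
#' DCD carries no topology, so the atom table must come from a companion
#' structure (e.g. the PDB written alongside).
#'
#' @param file DCD path.
#' @param atoms atom table (as in [sim_trajectory()]).
#' @param box a [box_spec()].
#' @param timestep frame spacing (ps).
#' @return a [sim_trajectory()].
#' @export
read_dcd_frames <- function(file, atoms, box, timestep = 1) {
  xyz <- bio3d::read.dcd(file, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3,
                                                 byrow = TRUE)
  sim_trajectory(coords, atoms, box, timestep = timestep, wrapped = TRUE)
}

#' Write / read a radial distribution function as two-column text
#'
#' Whitespace-separated columns (distance, g value) with a header line naming
#' the distance unit
#' (`r_A` or `r_nm`).
#'
#' @param rdf an object of class `rdf` (see [compute_rdf()]).
#' @param file path.
#' @param unit `"A"` or `"nm"`.
#' @return `file` (write) or an `rdf` object (read).
#' @export
write_rdf <- function(rdf, file, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  r <- if (unit == "A") rdf$r else angstrom_to_nm(rdf$r)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# r_%s g  pair=%s-%s", unit, rdf$pair[1], rdf$pair[2]),
             con)
  writeLines(sprintf("%.6f %.8f", r, rdf$g), con)
  invisible(file)
}

#' @rdname write_rdf
#' @export
read_rdf <- function(file) {
  first <- readLines(file, n = 1)
  d <- utils::read.table(file, comment.char = "#")
  r <- d[[1]]
  if (grepl("r_nm", first)) r <- nm_to_angstrom(r)
  pair <- c(NA_character_, NA_character_)
  m <- regmatches(first, regexec("pair=([^- ]+)-([^ ]+)", first))[[1]]
  if (length(m) == 3) pair <- m[2:3]
  bw <- if (length(r) > 1) r[2] - r[1] else NA_real_
  structure(list(r = r, g = d[[2]], bin_width = bw, r_max = max(r) + bw / 2,
                 pair = pair, n_frames = NA_integer_, box_edge = NA_real_),
            class = "rdf")
}
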