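#' Structure and trajectory containers
#'
#' A `structure3d` holds an atom table plus one coordinate matrix; a
#' `trajectory` holds the same atom table (the topology) plus one
#' coordinate matrix per frame. Coordinates are in Angstrom. Atom tables
#' carry the PDB author fields: serial, name, element, resname, resid,
#' chain, occupancy, bfactor.
#'
#' @param atoms Atom data.frame (see fields above).
#' @param xyz Numeric n_atoms x 3 coordinate matrix.
#' @param id Label for the structure.
#' @return A `structure3d` object.
#' @export
structure3d <- function(atoms, xyz, id = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3)
    stop("coordinate matrix must be n_atoms x 3")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "occupancy", "bfactor")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks fields: ", paste(miss, collapse = ", "))
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, atom name) after altloc resolution: ",
         key[anyDuplicated(key)])
  out <- list(atoms = atoms, xyz = xyz, id = id)
  class(out) <- "structure3d"
  out
}

#' @param topology A `structure3d` giving the shared atom topology.
#' @param frames List of n_atoms x 3 coordinate matrices, one per frame.
#' @param dt Frame spacing in ps (NA if unknown).
#' @param t0 Time of the first frame in ps.
#' @rdname structure3d
#' @export
trajectory <- function(topology, frames, dt = NA_real_, t0 = 0) {
  stopifnot(inherits(topology, "structure3d"), length(frames) >= 1)
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != n || ncol(f) != 3)
      stop(sprintf("frame %d has %d atoms; topology has %d", i, nrow(f), n))
    frames[[i]] <- f
  }
  if (!is.na(dt) && dt <= 0) stop("dt must be positive")
  out <- list(topology = topology, frames = frames, dt = dt, t0 = t0)
  class(out) <- "trajectory"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d atoms, %d residues, chains [%s]\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %s ps\n",
              length(x$frames), nrow(x$topology$atoms),
              format(x$dt)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame times in ps
#' @param traj A `trajectory`.
#' @return Numeric vector of times (t0 + (i-1) * dt); frame indices when
#'   dt is unset.
#' @export
frame_times <- function(traj) {
  if (is.na(traj$dt)) return(seq_along(traj$frames) - 1)
  traj$t0 + (seq_along(traj$frames) - 1) * traj$dt
}

#' Extract one frame as a structure
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @return A `structure3d` with the topology's atoms and frame i coordinates.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > length(traj$frames)) stop("frame index out of range")
  structure3d(traj$topology$atoms, traj$frames[[i]],
              id = sprintf("%s[frame %d]", traj$topology$id, i))
}

.parse_pdb_atom_lines <- function(lines, lineno) {
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(lines, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("unparseable %s field in PDB line %d: '%s'",
                   what, lineno[bad[1]], lines[bad[1]]))
    v
  }
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  name <- substr(lines, 13, 16)
  altloc <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  if (anyNA(resid))
    stop(sprintf("unparseable residue number in PDB line %d: '%s'",
                 lineno[which(is.na(resid))[1]], lines[which(is.na(resid))[1]]))
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(substr(lines, 61, 66)))
  bf[is.na(bf)] <- 0
  el <- trimws(substr(lines, 77, 78))
  el <- ifelse(el == "" | is.na(el), .element_from_name(name),
               .normalise_element(el))
  data.frame(serial = serial, name = trimws(name), element = el,
             resname = resname, resid = resid, chain = chain,
             occupancy = occ, bfactor = bf, altloc = altloc,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# Resolve alternate locations: keep the highest-occupancy conformer of
# each (chain, resid, name); ties keep the first in file order.
.resolve_altloc <- function(tab) {
  has_alt <- tab$altloc != " " & tab$altloc != ""
  if (!any(has_alt)) return(tab)
  key <- paste(tab$chain, tab$resid, tab$name)
  ord <- order(key, -tab$occupancy, seq_len(nrow(tab)))
  keep <- ord[!duplicated(key[ord])]
  tab[sort(keep), , drop = FALSE]
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames in model order; a file without MODEL
#' records yields a single-frame trajectory. All models must share one atom
#' topology. Alternate locations are resolved to the highest-occupancy
#' conformer (ties: first in file). Author residue numbering is preserved.
#'
#' @param path Path to a PDB file.
#' @param dt Frame spacing in ps to attach as metadata (optional).
#' @param keep_water Keep water residues (HOH/WAT)? Default TRUE.
#' @return A [trajectory].
#' @export
read_multimodel_pdb <- function(path, dt = NA_real_, keep_water = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  model_id <- model_id[is_atom]
  if (any(model_id == 0))
    stop("ATOM records before the first MODEL line in ", path)
  tabs <- lapply(split(seq_len(sum(is_atom)), model_id), function(ii) {
    sel <- which(is_atom)[ii]
    t <- .parse_pdb_atom_lines(lines[sel], sel)
    if (!keep_water) t <- t[!(t$resname %in% c("HOH", "WAT")), , drop = FALSE]
    .resolve_altloc(t)
  })
  ref <- tabs[[1]]
  refkey <- paste(ref$chain, ref$resid, ref$name)
  frames <- vector("list", length(tabs))
  for (m in seq_along(tabs)) {
    t <- tabs[[m]]
    if (nrow(t) != nrow(ref) ||
        !identical(paste(t$chain, t$resid, t$name), refkey))
      stop(sprintf(
        "model %d does not match the topology of model 1 (%d vs %d atoms)",
        m, nrow(t), nrow(ref)))
    frames[[m]] <- cbind(t$x, t$y, t$z)
  }
  atoms <- ref[, c("serial", "name", "element", "resname", "resid",
                   "chain", "occupancy", "bfactor")]
  rownames(atoms) <- NULL
  topo <- structure3d(atoms, frames[[1]],
                      id = sub("\\.pdb$", "", basename(path)))
  trajectory(topo, frames, dt = dt)
}

#' Read a single-model PDB file as a structure
#' @inheritParams read_multimodel_pdb
#' @return A [structure3d] (first model if the file has several).
#' @export
read_pdb_structure <- function(path, keep_water = TRUE) {
  get_frame(read_multimodel_pdb(path, keep_water = keep_water), 1)
}

.format_pdb_atom <- function(atoms, xyz) {
  name <- ifelse(nchar(atoms$name) <= 3 & nchar(atoms$element) == 1,
                 sprintf(" %-3s", atoms$name), sprintf("%-4s", atoms$name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name, atoms$resname, atoms$chain,
          atoms$resid, xyz[, 1], xyz[, 2], xyz[, 3],
          atoms$occupancy, atoms$bfactor, toupper(atoms$element))
}

#' Write a trajectory (or structure) as a multi-model PDB file
#'
#' @param x A [trajectory] or [structure3d].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "structure3d"))
    x <- trajectory(x, list(x$xyz))
  stopifnot(inherits(x, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x$frames) > 1
  for (m in seq_along(x$frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(.format_pdb_atom(x$topology$atoms, x$frames[[m]]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
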