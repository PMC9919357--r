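# ---- trajectory container --------------------------------------------------

.segcats <- c("receptor", "ligand", "lipid", "cage", "xenon", "solvent")

#' Labelled MD trajectory
#'
#' Minimal in-memory trajectory: an atom table, a coordinate array and
#' per-frame times. Atoms carry a residue index, residue name, a heavy-atom
#' flag and a segment category out of \code{receptor}, \code{ligand},
#' \code{lipid}, \code{cage}, \code{xenon}, \code{solvent}. Lipid and
#' solvent molecules are identified by their residue index like protein
#' residues.
#'
#' @param atoms data frame with columns \code{name} (atom name),
#'   \code{resid} (integer), \code{resname}, \code{segcat} (one of the six
#'   categories), \code{heavy} (logical).
#' @param coords numeric array \code{n_atoms x 3 x n_frames}, Angstrom.
#' @param times_ns per-frame times in ns, strictly increasing.
#' @param box optional \code{n_frames x 3} matrix of orthorhombic box
#'   lengths (Angstrom) for minimum-image distances; \code{NULL} for
#'   non-periodic toys.
#' @return An object of class \code{xe_trajectory}.
#' @export
trajectory <- function(atoms, coords, times_ns, box = NULL) {
  need <- c("name", "resid", "resname", "segcat", "heavy")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("atoms must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (!all(atoms$segcat %in% .segcats))
    stop("segcat must be one of: ", paste(.segcats, collapse = ", "))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(atoms))
  nf <- dim(coords)[3]
  stopifnot(length(times_ns) == nf)
  if (nf > 1L && any(diff(times_ns) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    stopifnot(nrow(box) == nf)
  }
  atoms$resid <- as.integer(atoms$resid)
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times_ns),
                 box = box),
            class = "xe_trajectory")
}

#' @export
print.xe_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, %.3g .. %.3g ns\n",
              nrow(x$atoms), dim(x$coords)[3], x$times[1],
              x$times[length(x$times)]))
  print(table(x$atoms$segcat))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{xe_trajectory}.
#' @return integer count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "xe_trajectory"))
  dim(traj$coords)[3]
}

#' Coordinates of one frame
#' @param traj an \code{xe_trajectory}.
#' @param i frame index.
#' @return \code{n_atoms x 3} matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "xe_trajectory"))
  matrix(traj$coords[, , i], ncol = 3)
}

# ---- readers ---------------------------------------------------------------

#' Read a trajectory from a PDB topology plus DCD coordinates
#'
#' Standard-format reader built on \pkg{bio3d} (PDB topologies, DCD
#' coordinate sets; for other trajectory formats convert to DCD or to the
#' plain CSV pair format of [read_trajectory_csv()]). Segment categories are
#' assigned from a residue-name map (YAML file or named list,
#' resname -> category); unmapped residue names fall back to
#' \code{"solvent"} with a warning. Heavy atoms are all atoms whose element
#' (first character of the atom name after digits) is not hydrogen.
#'
#' @param pdb_path PDB file path (topology; coordinates therein are used
#'   only if \code{dcd_path} is NULL).
#' @param dcd_path optional DCD file path.
#' @param category_map YAML path or named list mapping residue names to
#'   segment categories.
#' @param dt_ns time per frame in ns (DCD files do not always carry times).
#' @return an \code{xe_trajectory}.
#' @export
read_trajectory <- function(pdb_path, dcd_path = NULL, category_map,
                            dt_ns = 0.1) {
  pdb <- bio3d::read.pdb(pdb_path)
  if (is.character(category_map) && length(category_map) == 1L &&
      file.exists(category_map))
    category_map <- yaml::read_yaml(category_map)
  category_map <- unlist(category_map)
  at <- pdb$atom
  # bio3d convention: "resid" holds the residue NAME, "resno" the number
  seg <- unname(unlist(category_map)[at$resid])
  if (anyNA(seg)) {
    warning("unmapped residue names treated as solvent: ",
            paste(unique(at$resid[is.na(seg)]), collapse = ", "))
    seg[is.na(seg)] <- "solvent"
  }
  elem <- sub("^[0-9]*", "", at$elety)
  atoms <- data.frame(name = at$elety, resid = at$resno, resname = at$resid,
                      segcat = seg, heavy = substr(elem, 1, 1) != "H")
  if (is.null(dcd_path)) {
    coords <- array(cbind(at$x, at$y, at$z), c(nrow(at), 3, 1))
    times <- 0
  } else {
    xyz <- bio3d::read.dcd(dcd_path, verbose = FALSE)
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(nrow(at), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    times <- seq_len(nf) * dt_ns
  }
  trajectory(atoms, coords, times)
}

#' Read a trajectory from plain CSV tables
#'
#' Fixture-friendly format: an atom table CSV (columns \code{name},
#' \code{resid}, \code{resname}, \code{segcat}, \code{heavy}) and a frame
#' table CSV with columns \code{frame}, \code{time_ns}, \code{x}, \code{y},
#' \code{z}, rows grouped by frame in atom-table order.
#'
#' @param atoms_csv,frames_csv file paths.
#' @return an \code{xe_trajectory}.
#' @export
read_trajectory_csv <- function(atoms_csv, frames_csv) {
  atoms <- utils::read.csv(atoms_csv)
  fr <- utils::read.csv(frames_csv)
  frames <- sort(unique(fr$frame))
  na <- nrow(atoms)
  coords <- array(NA_real_, c(na, 3, length(frames)))
  times <- numeric(length(frames))
  for (k in seq_along(frames)) {
    sub <- fr[fr$frame == frames[k], ]
    if (nrow(sub) != na) stop("frame ", frames[k], " has ", nrow(sub),
                              " rows for ", na, " atoms")
    coords[, , k] <- cbind(sub$x, sub$y, sub$z)
    times[k] <- sub$time_ns[1]
  }
  trajectory(atoms, coords, times)
}

#' Write a trajectory to the plain CSV pair format
#'
#' @param traj an \code{xe_trajectory}.
#' @param atoms_csv,frames_csv output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_trajectory_csv <- function(traj, atoms_csv, frames_csv) {
  stopifnot(inherits(traj, "xe_trajectory"))
  utils::write.csv(traj$atoms, atoms_csv, row.names = FALSE)
  nf <- n_frames(traj)
  rows <- do.call(rbind, lapply(seq_len(nf), function(f) {
    xyz <- frame_coords(traj, f)
    data.frame(frame = f, time_ns = traj$times[f],
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  utils::write.csv(rows, frames_csv, row.names = FALSE)
  invisible(c(atoms_csv, frames_csv))
}
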