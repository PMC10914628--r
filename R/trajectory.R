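#' Trajectory container
#'
#' A trajectory couples a fixed topology (one row per atom) with an ordered
#' set of coordinate frames in Angstrom. The topology is a data.frame with
#' columns `serial`, `name`, `element`, `resname`, `resid`, `chain`,
#' `charge` (NA unless a sidecar charge table was applied) and `is_solvent`.
#' Coordinates are stored as an `n_frames x (3 * n_atoms)` matrix in
#' x1,y1,z1,x2,... order so whole-frame operations stay vectorized.
#'
#' @param atoms topology data.frame (see above; `serial` must be unique)
#' @param xyz numeric matrix, `n_frames` rows, `3 * nrow(atoms)` columns
#' @param times optional numeric vector of frame times in ns, strictly
#'   increasing
#' @return an object of class `md_traj`
#' @export
md_traj <- function(atoms, xyz, times = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L)
    stop("topology is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a topology")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$is_solvent))
    atoms$is_solvent <- atoms$resname %in% solvent_resnames()
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("each frame must supply exactly 3 coordinates per atom")
  if (!is.null(times)) {
    if (length(times) != nrow(xyz))
      stop("frame_times length must equal the number of frames")
    if (any(diff(times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  structure(list(atoms = atoms, xyz = xyz, times = times),
            class = "md_traj")
}

solvent_resnames <- function() c("HOH", "WAT", "TIP3", "SPC")

#' @export
n_frames <- function(traj) UseMethod("n_frames")
#' @export
n_frames.md_traj <- function(traj) nrow(traj$xyz)

#' @export
n_atoms <- function(traj) UseMethod("n_atoms")
#' @export
n_atoms.md_traj <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame
#'
#' @param traj an `md_traj`
#' @param i frame index (1-based)
#' @return an `n_atoms x 3` matrix
#' @export
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Replace coordinates of one frame
#' @param traj an `md_traj`
#' @param i frame index
#' @param coords `n_atoms x 3` matrix
#' @return the modified trajectory
#' @export
set_frame_coords <- function(traj, i, coords) {
  stopifnot(nrow(coords) == n_atoms(traj), ncol(coords) == 3L)
  traj$xyz[i, ] <- as.numeric(t(coords))
  traj
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("<md_traj> %d atoms, %d frame(s), %d chain(s)\n",
              n_atoms(x), n_frames(x), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Subset a trajectory to a set of atoms
#'
#' Keeps topology rows and the matching coordinate columns for every frame.
#'
#' @param traj an `md_traj`
#' @param idx integer atom indices (1-based, in topology order)
#' @return an `md_traj` with `length(idx)` atoms
#' @export
subset_atoms <- function(traj, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("cannot subset a trajectory to zero atoms")
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  md_traj(traj$atoms[idx, , drop = FALSE],
          traj$xyz[, cols, drop = FALSE], traj$times)
}

#' Look up atom indices by residue and atom name
#'
#' @param traj an `md_traj`
#' @param chain chain id
#' @param resid residue number
#' @param name optional atom name (vector allowed); if omitted, all atoms of
#'   the residue are returned
#' @return integer vector of atom indices (possibly empty)
#' @export
atom_index <- function(traj, chain, resid, name = NULL) {
  a <- traj$atoms
  sel <- a$chain == chain & a$resid == resid
  if (!is.null(name)) sel <- sel & a$name %in% name
  which(sel)
}
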