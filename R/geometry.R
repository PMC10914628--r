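#' Geometric kernels
#'
#' Distances, angles, torsions, hydrogen bonds, rigid superposition and
#' coordination shells. All inputs are coordinate matrices (rows = atoms,
#' columns = x/y/z, Angstrom); every scalar descriptor is invariant under
#' global rigid motion.
#'
#' @name geometry
NULL

vnorm <- function(v) sqrt(sum(v * v))

#' Euclidean distance between two atoms of a frame
#' @param coords n x 3 coordinate matrix
#' @param i,j atom indices
#' @return distance in Angstrom
#' @export
atom_distance <- function(coords, i, j) {
  if (i < 1L || j < 1L || i > nrow(coords) || j > nrow(coords))
    stop("atom index out of bounds")
  vnorm(coords[i, ] - coords[j, ])
}

#' Minimum distance between two atom sets
#' @param coords n x 3 coordinate matrix
#' @param set_a,set_b integer index vectors
#' @return smallest pairwise distance; `Inf` if either set is empty
#' @export
min_distance <- function(coords, set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) return(Inf)
  a <- coords[set_a, , drop = FALSE]
  b <- coords[set_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Bond angle at atom j (i-j-k), degrees
#' @param coords n x 3 matrix
#' @param i,j,k atom indices
#' @export
bond_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Torsion angle i-j-k-l, degrees in (-180, 180]
#'
#' IUPAC sign convention: cis = 0, trans = 180, sign by the right-hand rule
#' about the j->k axis. Errors out when three of the four points are
#' (numerically) collinear, i.e. a cross-product norm below 1e-8.
#'
#' @param coords n x 3 matrix
#' @param i,j,k,l atom indices
#' @export
dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8)
    stop("undefined torsion: collinear atoms")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# gamma reference atom for chi1, per residue type
chi1_gamma_atom <- function(resname) {
  switch(resname,
         ILE = "CG1", VAL = "CG1", SER = "OG", THR = "OG1", CYS = "SG",
         ALA = NA_character_, GLY = NA_character_,
         "CG")
}

#' Side-chain chi1 torsion (N-CA-CB-gamma), degrees
#'
#' The gamma reference atom is CG except for Ile/Val (CG1), Ser (OG),
#' Thr (OG1) and Cys (SG). Ala/Gly have no chi1.
#'
#' @param traj an `md_traj`
#' @param frame_idx frame index
#' @param chain,resid residue address
#' @return chi1 in degrees, range (-180, 180]
#' @export
chi1 <- function(traj, frame_idx, chain, resid) {
  res <- atom_index(traj, chain, resid)
  if (length(res) == 0L)
    stop(sprintf("no residue %s:%d in topology", chain, resid))
  resname <- traj$atoms$resname[res[1]]
  gatom <- chi1_gamma_atom(resname)
  if (is.na(gatom))
    stop(sprintf("residue %s has no chi1 torsion", resname))
  need <- c("N", "CA", "CB", gatom)
  idx <- vapply(need, function(nm) {
    hit <- atom_index(traj, chain, resid, nm)
    if (length(hit) == 0L)
      stop(sprintf("incomplete residue %s:%d %s: missing atom %s",
                   chain, resid, resname, nm))
    hit[1]
  }, integer(1))
  coords <- frame_coords(traj, frame_idx)
  dihedral(coords, idx[1], idx[2], idx[3], idx[4])
}

#' Detect hydrogen bonds by geometry
#'
#' A donor/acceptor heavy-atom pair is a hydrogen bond when the
#' donor-acceptor distance is at most `d_max` and, if explicit hydrogens are
#' bonded to the donor (within 1.25 A, element H), some D-H...A angle is at
#' least `angle_min`. Without hydrogens the distance criterion alone
#' decides. One record per (donor, acceptor) pair.
#'
#' @param coords n x 3 coordinate matrix
#' @param donors,acceptors integer index vectors of heavy atoms
#' @param d_max heavy-atom distance cutoff in Angstrom (default 3.5)
#' @param angle_min minimum D-H...A angle in degrees (default 120)
#' @param elements optional character vector of element symbols (length n);
#'   needed to locate explicit hydrogens
#' @return data.frame with columns donor, hydrogen (NA when absent),
#'   acceptor, d_DA, angle (NA when no hydrogen)
#' @export
detect_hbonds <- function(coords, donors, acceptors, d_max = 3.5,
                          angle_min = 120, elements = NULL) {
  out <- list()
  hydrogens <- if (!is.null(elements)) which(elements == "H") else integer(0)
  for (d in donors) {
    dh <- hydrogens[apply(coords[hydrogens, , drop = FALSE], 1L, function(h)
      vnorm(h - coords[d, ])) < 1.25]
    for (a in acceptors) {
      if (a == d) next
      dda <- vnorm(coords[d, ] - coords[a, ])
      if (dda > d_max) next
      if (length(dh) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = NA_integer_, acceptor = a,
          d_DA = dda, angle = NA_real_)
      } else {
        angs <- vapply(dh, function(h) bond_angle(coords, d, h, a), numeric(1))
        best <- which.max(angs)
        if (angs[best] >= angle_min)
          out[[length(out) + 1L]] <- data.frame(
            donor = d, hydrogen = dh[best], acceptor = a,
            d_DA = dda, angle = angs[best])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), d_DA = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `ref` over a common atom selection,
#' solved by singular value decomposition with the determinant correction
#' that guarantees a proper rotation.
#'
#' @param ref,mobile n x 3 coordinate matrices
#' @param selection integer indices used for the fit (default: all rows);
#'   at least 3 non-collinear atoms
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% rotation + translation`), and `rmsd` over the
#'   selection after fitting
#' @export
kabsch_superpose <- function(ref, mobile, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  if (length(selection) < 3L)
    stop("degenerate fit: need at least 3 atoms")
  p <- mobile[selection, , drop = FALSE]
  q <- ref[selection, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2L, pc); q0 <- sweep(q, 2L, qc)
  sv <- svd(crossprod(p0, q0))
  if (sv$d[2] < 1e-10)
    stop("degenerate fit: collinear or coincident selection")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- qc - pc %*% rot
  fitted <- p %*% rot + matrix(trans, nrow(p), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix
#' @param fit result of [kabsch_superpose()]
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(coords, fit) {
  coords %*% fit$rotation +
    matrix(fit$translation, nrow(coords), 3L, byrow = TRUE)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' @param traj an `md_traj`
#' @param selection atom indices used for the fit
#' @param ref_frame frame index of the reference (default 1) or an
#'   `n_atoms x 3` matrix of reference coordinates
#' @return the trajectory with all frames rigidly fitted
#' @export
superpose_trajectory <- function(traj, selection, ref_frame = 1L) {
  ref <- if (is.matrix(ref_frame)) ref_frame else frame_coords(traj, ref_frame)
  for (f in seq_len(n_frames(traj))) {
    coords <- frame_coords(traj, f)
    fit <- kabsch_superpose(ref, coords, selection)
    traj <- set_frame_coords(traj, f, apply_transform(coords, fit))
  }
  traj
}

#' First coordination shell of an ion
#'
#' Candidates within `cutoff` of the center, sorted by distance.
#' Octahedricity (RMS deviation of the 15 ligand-center-ligand angles from
#' the nearest ideal octahedral value, 90 or 180 degrees) is reported only
#' when exactly 6 ligands are found, otherwise NA.
#'
#' @param coords n x 3 coordinate matrix
#' @param center atom index of the ion
#' @param candidates integer indices of candidate ligand atoms
#' @param cutoff shell radius in Angstrom (> 0)
#' @return list with `center`, `ligands` (data.frame atom/distance) and
#'   `octahedricity`
#' @export
coordination_shell <- function(coords, center, candidates, cutoff) {
  stopifnot(cutoff > 0)
  candidates <- setdiff(candidates, center)
  d <- vapply(candidates, function(i) vnorm(coords[i, ] - coords[center, ]),
              numeric(1))
  keep <- d <= cutoff
  lig <- data.frame(atom = candidates[keep], distance = d[keep])
  lig <- lig[order(lig$distance), , drop = FALSE]
  rownames(lig) <- NULL
  oct <- NA_real_
  if (nrow(lig) == 6L) {
    pairs <- utils::combn(lig$atom, 2L)
    devs <- apply(pairs, 2L, function(p) {
      ang <- bond_angle(coords, p[1], center, p[2])
      min(abs(ang - 90), abs(ang - 180))
    })
    oct <- sqrt(mean(devs^2))
  }
  list(center = center, ligands = lig, octahedricity = oct)
}
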