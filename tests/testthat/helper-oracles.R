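# Independent oracles and small generators used across the test files.

random_rotation <- function() {
  q <- qr(matrix(rnorm(9L), 3L))
  rot <- qr.Q(q)
  if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
  rot
}

rigid_move <- function(coords, rot = random_rotation(),
                       shift = runif(3, -10, 10)) {
  coords %*% rot + matrix(shift, nrow(coords), 3L, byrow = TRUE)
}

# Horn's quaternion method for optimal superposition RMSD, independent of
# the SVD route in the package
quaternion_rmsd <- function(ref, mobile) {
  p <- sweep(mobile, 2L, colMeans(mobile))
  q <- sweep(ref, 2L, colMeans(ref))
  m <- crossprod(p, q)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- rbind(
    c(sxx + syy + szz, syz - szy, szx - sxz, sxy - syx),
    c(syz - szy, sxx - syy - szz, sxy + syx, szx + sxz),
    c(szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy),
    c(sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz))
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)
  sqrt(max(0, msd))
}

# torsion via the independent "two plane normals + atan2" construction
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2) * sqrt(sum(b2^2))
  y <- sum(cr(n1, n2) * b2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# exhaustive O(n^2) hydrogen-bond search (distance-only, no hydrogens)
hbond_oracle <- function(coords, donors, acceptors, d_max) {
  out <- list()
  for (d in donors) for (a in acceptors) {
    if (a == d) next
    dd <- sqrt(sum((coords[d, ] - coords[a, ])^2))
    if (dd <= d_max)
      out[[length(out) + 1L]] <- data.frame(donor = d, acceptor = a,
                                            d_DA = dd)
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      d_DA = numeric(0)))
  do.call(rbind, out)
}

# exhaustive per-frame, per-residue ion-contact counter
contact_oracle <- function(traj, ion_sel, residues, cutoff) {
  counts <- integer(nrow(residues))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    for (r in seq_len(nrow(residues))) {
      idx <- atom_index(traj, residues$chain[r], residues$resid[r])
      hit <- FALSE
      for (i in ion_sel) for (j in idx) {
        if (sqrt(sum((co[i, ] - co[j, ])^2)) < cutoff) hit <- TRUE
      }
      if (hit) counts[r] <- counts[r] + 1L
    }
  }
  counts
}

# brute-force evaluation of a simple conjunctive selection
filter_oracle <- function(atoms, chain = NULL, resid = NULL, name = NULL,
                          resname = NULL, elem = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  if (!is.null(resname)) keep <- keep & atoms$resname %in% resname
  if (!is.null(elem)) keep <- keep & atoms$element %in% elem
  which(keep)
}

# octahedricity recomputed by direct angle enumeration
octahedricity_oracle <- function(coords, center, ligands) {
  devs <- c()
  for (i in seq_along(ligands)) {
    for (j in seq_along(ligands)) {
      if (j <= i) next
      u <- coords[ligands[i], ] - coords[center, ]
      v <- coords[ligands[j], ] - coords[center, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      devs <- c(devs, min(abs(ang - 90), abs(ang - 180)))
    }
  }
  sqrt(mean(devs^2))
}

# tiny two-atom trajectory for closed-form energy checks
two_point_traj <- function(r) {
  md_traj(data.frame(serial = 1:2, name = c("X1", "X2"),
                     element = c("N", "O"), resname = c("LIG", "REC"),
                     resid = 1:2, chain = c("A", "B")),
          matrix(c(0, 0, 0, r, 0, 0), nrow = 1L))
}
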