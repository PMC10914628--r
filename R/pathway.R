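#' Phosphate-dissociation pathway analysis
#'
#' Contact counting, residue ranking, way-station tracing and channel
#' charge lining for a dissociating inorganic phosphate.
#'
#' @name phosphate_pathway
NULL

#' Count per-residue ion contacts over a trajectory
#'
#' A residue scores one contact in a frame iff the minimum distance over
#' all (ion atom, residue atom) pairs is strictly below `cutoff` ("below
#' 3 A in a single frame"); at most one contact per residue per frame.
#'
#' @param traj an [md_traj()]
#' @param ion_sel integer atom indices of the ion (non-empty)
#' @param residues data.frame with columns chain, resid (one row per
#'   residue to profile), or NULL for every non-solvent, non-ion residue
#' @param cutoff contact distance in Angstrom (default 3.0, strict `<`)
#' @return data.frame (chain, resid, resname, contact_frames, total_frames)
#' @export
count_contacts <- function(traj, ion_sel, residues = NULL, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  if (length(ion_sel) == 0L) stop("empty ion selection")
  a <- traj$atoms
  if (is.null(residues)) {
    pool <- !a$is_solvent & !(seq_len(nrow(a)) %in% ion_sel)
    residues <- unique(a[pool, c("chain", "resid")])
  }
  res_idx <- lapply(seq_len(nrow(residues)), function(r)
    atom_index(traj, residues$chain[r], residues$resid[r]))
  resname <- vapply(res_idx, function(idx)
    if (length(idx) > 0L) a$resname[idx[1]] else NA_character_, character(1))
  nf <- n_frames(traj)
  counts <- integer(nrow(residues))
  for (f in seq_len(nf)) {
    coords <- frame_coords(traj, f)
    ion_xyz <- coords[ion_sel, , drop = FALSE]
    present <- !anyNA(ion_xyz)
    if (!present) next
    for (r in seq_along(res_idx)) {
      if (length(res_idx[[r]]) == 0L) next
      if (min_distance(coords, ion_sel, res_idx[[r]]) < cutoff)
        counts[r] <- counts[r] + 1L
    }
  }
  data.frame(chain = residues$chain, resid = residues$resid,
             resname = resname, contact_frames = counts,
             total_frames = nf, row.names = NULL)
}

#' Rank residues by contact count
#'
#' Descending by `contact_frames`; ties broken by (chain, resid) ascending,
#' so the ranking is deterministic and independent of input order.
#'
#' @param profile result of [count_contacts()]
#' @param top_k how many residues to keep (>= 1; capped at the table size)
#' @return the top rows of the profile, ranked
#' @export
rank_residues <- function(profile, top_k = nrow(profile)) {
  stopifnot(top_k >= 1L)
  ord <- order(-profile$contact_frames, profile$chain, profile$resid)
  out <- profile[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

# side-chain tip atom per residue type, for waypoints and charge lining
sidechain_tip <- function(resname) {
  switch(resname, ARG = "CZ", LYS = "NZ", ASP = "CG", GLU = "CD",
         HIS = "CE1", "CA")
}

#' Trace the dissociation path of the phosphate
#'
#' Frames are superposed onto the first frame via the cis-subunit C-alpha
#' atoms. Per frame the Pi centroid, the nearest lining residue and its
#' minimum distance are recorded; the waypoint sequence is the
#' deduplicated first-visit order of residues approached within
#' `waypoint_cutoff`.
#'
#' @param traj an [md_traj()]
#' @param pocket a `pocket_spec` (provides the cis chain and the Pi address)
#' @param lining data.frame (chain, resid) of lining residues; default: all
#'   mapped pocket residues
#' @param waypoint_cutoff distance for a way-station visit (default 3.0 A)
#' @return list with `trace` (frame, x, y, z, nearest_chain, nearest_resid,
#'   min_distance) and `waypoints` (chain, resid, resname, first_frame)
#' @export
trace_dissociation <- function(traj, pocket, lining = NULL,
                               waypoint_cutoff = 3.0) {
  a <- traj$atoms
  if (is.null(lining)) {
    lining <- unique(do.call(rbind, lapply(pocket$roles, function(r)
      data.frame(chain = r$chain, resid = r$resid))))
  }
  addr <- pocket$pi
  if (!is.null(addr) && length(addr$resid) > 1L)
    addr <- list(chain = addr$chain, resid = addr$resid[1])
  ion <- if (!is.null(addr)) atom_index(traj, addr$chain, addr$resid)
         else integer(0)
  if (length(ion) == 0L) stop("pocket has no Pi ion to trace")

  cis_ca <- which(a$chain == pocket$cis_chain & a$name == "CA")
  local <- superpose_trajectory(traj, cis_ca, 1L)
  res_idx <- lapply(seq_len(nrow(lining)), function(r)
    atom_index(local, lining$chain[r], lining$resid[r]))

  nf <- n_frames(local)
  rows <- vector("list", nf)
  visited <- character(0)
  waypoints <- list()
  for (f in seq_len(nf)) {
    coords <- frame_coords(local, f)
    ion_xyz <- coords[ion, , drop = FALSE]
    if (anyNA(ion_xyz)) {  # gap: ion absent in this frame
      rows[[f]] <- data.frame(frame = f, x = NA_real_, y = NA_real_,
                              z = NA_real_, nearest_chain = NA_character_,
                              nearest_resid = NA_integer_,
                              min_distance = NA_real_)
      next
    }
    cen <- colMeans(ion_xyz)
    d <- vapply(res_idx, function(idx) min_distance(coords, ion, idx),
                numeric(1))
    nearest <- which.min(d)
    rows[[f]] <- data.frame(frame = f, x = cen[1], y = cen[2], z = cen[3],
                            nearest_chain = lining$chain[nearest],
                            nearest_resid = lining$resid[nearest],
                            min_distance = d[nearest])
    if (d[nearest] <= waypoint_cutoff) {
      key <- paste(lining$chain[nearest], lining$resid[nearest])
      if (!(key %in% visited)) {
        visited <- c(visited, key)
        idx1 <- res_idx[[nearest]][1]
        waypoints[[length(waypoints) + 1L]] <- data.frame(
          chain = lining$chain[nearest], resid = lining$resid[nearest],
          resname = a$resname[idx1], first_frame = f)
      }
    }
  }
  waypoints <- if (length(waypoints) > 0L) do.call(rbind, waypoints)
    else data.frame(chain = character(0), resid = integer(0),
                    resname = character(0), first_frame = integer(0))
  list(trace = do.call(rbind, rows), waypoints = waypoints)
}

#' Net formal charge lining a path
#'
#' For each path point, sums the formal side-chain charges (Arg/Lys +1,
#' Asp/Glu -1, His 0) of residues whose side-chain tip atom (Arg CZ, Lys
#' NZ, Asp CG, Glu CD, His CE1) lies within `radius` of the point. A
#' formal-charge proxy for an electrostatic potential map.
#'
#' @param traj an [md_traj()]
#' @param frame_idx frame to evaluate
#' @param path_points numeric matrix (k x 3) of probe positions
#' @param radius inclusion radius in Angstrom (default 6)
#' @return data.frame (point, x, y, z, net_charge, n_pos, n_neg)
#' @export
channel_charge_profile <- function(traj, frame_idx, path_points,
                                   radius = 6.0) {
  if (is.vector(path_points)) path_points <- matrix(path_points, ncol = 3L)
  coords <- frame_coords(traj, frame_idx)
  a <- traj$atoms
  charged <- a$resname %in% c("ARG", "LYS", "ASP", "GLU")
  res <- unique(a[charged, c("chain", "resid", "resname")])
  tips <- vapply(seq_len(nrow(res)), function(r) {
    idx <- atom_index(traj, res$chain[r], res$resid[r],
                      sidechain_tip(res$resname[r]))
    if (length(idx) == 0L) NA_integer_ else idx[1]
  }, integer(1))
  keep <- !is.na(tips)
  res <- res[keep, , drop = FALSE]
  tips <- tips[keep]
  q <- ifelse(res$resname %in% c("ARG", "LYS"), 1L, -1L)

  out <- lapply(seq_len(nrow(path_points)), function(p) {
    d <- sqrt(rowSums((coords[tips, , drop = FALSE] -
                       matrix(path_points[p, ], length(tips), 3L,
                              byrow = TRUE))^2))
    inside <- d <= radius
    data.frame(point = p, x = path_points[p, 1], y = path_points[p, 2],
               z = path_points[p, 3], net_charge = sum(q[inside]),
               n_pos = sum(inside & q > 0), n_neg = sum(inside & q < 0))
  })
  do.call(rbind, out)
}
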