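#' Per-residue RMSF profile
#'
#' Two-pass procedure: (1) superpose every frame onto frame 1 using the
#' alignment selection and compute the mean structure; (2) re-superpose
#' onto that mean; RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2) per analysis
#' atom, reported per residue (mean over the residue's analysis atoms;
#' C-alpha only by default). Aligning on a selection that excludes a mobile
#' segment keeps that segment's mobility from being absorbed by the fit.
#'
#' @param traj an [md_traj()] with at least 2 frames
#' @param analysis_sel atom indices to report (default: all C-alpha)
#' @param align_sel atom indices for the rigid fit (default: same as
#'   `analysis_sel`); at least 3 non-collinear atoms
#' @return data.frame (chain, resid, resname, rmsf, n_frames) of class
#'   `rmsf_profile`
#' @export
compute_rmsf <- function(traj, analysis_sel = NULL, align_sel = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  a <- traj$atoms
  if (is.null(analysis_sel)) analysis_sel <- which(a$name == "CA")
  if (is.null(align_sel)) align_sel <- analysis_sel
  if (length(align_sel) < 3L) stop("degenerate fit: need >= 3 align atoms")

  pass1 <- superpose_trajectory(traj, align_sel, 1L)
  mean_xyz <- matrix(colMeans(pass1$xyz), ncol = 3L, byrow = TRUE)
  pass2 <- superpose_trajectory(pass1, align_sel, mean_xyz)
  mean_xyz <- matrix(colMeans(pass2$xyz), ncol = 3L, byrow = TRUE)

  nf <- n_frames(pass2)
  dev2 <- matrix(0, nf, length(analysis_sel))
  for (f in seq_len(nf)) {
    d <- frame_coords(pass2, f)[analysis_sel, , drop = FALSE] -
      mean_xyz[analysis_sel, , drop = FALSE]
    dev2[f, ] <- rowSums(d^2)
  }
  atom_rmsf <- sqrt(colMeans(dev2))

  key <- paste(a$chain[analysis_sel], a$resid[analysis_sel])
  agg <- tapply(atom_rmsf, key, mean)
  first <- analysis_sel[!duplicated(key)]
  ord_key <- paste(a$chain[first], a$resid[first])
  out <- data.frame(chain = a$chain[first], resid = a$resid[first],
                    resname = a$resname[first],
                    rmsf = as.numeric(agg[ord_key]), n_frames = nf)
  out <- out[order(out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Per-residue ratio of two RMSF profiles
#'
#' Ratio on the intersection of residue sets; residues whose denominator
#' RMSF is at or below `floor` are flagged (`ratio` NA, `flagged` TRUE)
#' instead of divided.
#'
#' @param numerator,denominator `rmsf_profile`s
#' @param floor smallest denominator allowed (default 1e-6 A)
#' @return data.frame (chain, resid, rmsf_num, rmsf_den, ratio, flagged)
#' @export
rmsf_ratio <- function(numerator, denominator, floor = 1e-6) {
  key_n <- paste(numerator$chain, numerator$resid)
  key_d <- paste(denominator$chain, denominator$resid)
  common <- intersect(key_n, key_d)
  if (length(common) == 0L) stop("RMSF profiles share no residues")
  i_n <- match(common, key_n)
  i_d <- match(common, key_d)
  den <- denominator$rmsf[i_d]
  flagged <- den <= floor
  ratio <- ifelse(flagged, NA_real_, numerator$rmsf[i_n] / den)
  data.frame(chain = numerator$chain[i_n], resid = numerator$resid[i_n],
             rmsf_num = numerator$rmsf[i_n], rmsf_den = den,
             ratio = ratio, flagged = flagged)
}

backbone_atom_indices <- function(traj, chain, resid, name) {
  idx <- atom_index(traj, chain, resid, name)
  if (length(idx) == 0L) NA_integer_ else idx[1]
}

# phi/psi for a span of residues in one frame; rows with a missing
# neighbour are NA
phi_psi_frame <- function(traj, coords, chain, resids) {
  out <- data.frame(resid = resids, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(resids)) {
    r <- resids[k]
    c_prev <- backbone_atom_indices(traj, chain, r - 1L, "C")
    n <- backbone_atom_indices(traj, chain, r, "N")
    ca <- backbone_atom_indices(traj, chain, r, "CA")
    cc <- backbone_atom_indices(traj, chain, r, "C")
    n_next <- backbone_atom_indices(traj, chain, r + 1L, "N")
    if (anyNA(c(n, ca, cc)))
      stop(sprintf("incomplete residue %s:%d: missing backbone atom",
                   chain, r))
    if (!is.na(c_prev)) out$phi[k] <- dihedral(coords, c_prev, n, ca, cc)
    if (!is.na(n_next)) out$psi[k] <- dihedral(coords, n, ca, cc, n_next)
  }
  out
}

#' Ramachandran table for a residue span in one frame
#'
#' One row per residue with both torsions defined; terminal residues
#' lacking a neighbour are omitted with a message.
#'
#' @param traj an [md_traj()]
#' @param frame_idx frame index
#' @param chain chain id
#' @param span inclusive residue range, `c(first, last)`
#' @return data.frame (resid, phi, psi)
#' @export
ramachandran_table <- function(traj, frame_idx, chain, span) {
  coords <- frame_coords(traj, frame_idx)
  tab <- phi_psi_frame(traj, coords, chain, seq(span[1], span[2]))
  drop <- is.na(tab$phi) | is.na(tab$psi)
  if (any(drop))
    message(sprintf("omitting %d terminal residue(s) without phi/psi: %s",
                    sum(drop), paste(tab$resid[drop], collapse = ", ")))
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sensor-loop conformation: 3-10-helix assignment from backbone torsions
#'
#' A residue is assigned 3-10 when its (phi, psi) lie within
#' (`tol_phi`, `tol_psi`) of the canonical 3-10 torsions (-49, -26); the
#' psi tolerance default separates 3-10 from ideal alpha-helix (psi -47).
#' `helix_fraction` is the fraction of frames containing at least 3
#' consecutive 3-10 residues in the span.
#'
#' @param traj an [md_traj()]
#' @param chain chain id
#' @param span inclusive residue range (default the sensor loop 348-360)
#' @param tol_phi,tol_psi tolerances in degrees (defaults 20 and 15)
#' @return list with `per_frame` (frame, resid, phi, psi, is_310),
#'   `helix_fraction`, and the parameters used
#' @export
loop_conformation <- function(traj, chain, span = c(348L, 360L),
                              tol_phi = 20, tol_psi = 15) {
  resids <- seq(span[1], span[2])
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  helix_frames <- 0L
  for (f in seq_len(nf)) {
    coords <- frame_coords(traj, f)
    tab <- phi_psi_frame(traj, coords, chain, resids)
    tab$is_310 <- !is.na(tab$phi) & !is.na(tab$psi) &
      abs(tab$phi - (-49)) <= tol_phi & abs(tab$psi - (-26)) <= tol_psi
    runs <- rle(tab$is_310)
    if (any(runs$values & runs$lengths >= 3L)) helix_frames <- helix_frames + 1L
    tab$frame <- f
    rows[[f]] <- tab
  }
  list(per_frame = do.call(rbind, rows),
       helix_fraction = helix_frames / nf,
       span = span, tol_phi = tol_phi, tol_psi = tol_psi)
}
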