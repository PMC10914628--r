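#' Default geometric thresholds for pocket-state classification
#'
#' All cutoffs are exposed parameters; the defaults are field-standard
#' values for the geometric definitions (the source structures define the
#' geometry, not numeric cutoffs):
#' \describe{
#'   \item{r_arg}{arginine-finger Nh-to-phosphate-O contact, 3.5 A}
#'   \item{r_K}{Walker-A lysine Nz-to-Pi-O engagement, 4.0 A}
#'   \item{r_lytic}{lytic-water O to Pgamma, 3.8 A}
#'   \item{r_polar}{R359 guanidinium N to gamma-phosphate O, 4.0 A}
#'   \item{bond_PgPb}{Pgamma-Pbeta "bond intact" cutoff, 2.0 A (raise to
#'     ~3.5 A for experimentally derived triphosphates, whose P-P distance
#'     is near 2.9 A)}
#'   \item{rotamer_w}{half-width of the chi1 rotamer bins, 40 degrees}
#'   \item{r_mg_shell}{Mg2+ coordination-shell radius, 2.6 A}
#'   \item{hbond_d_max, hbond_angle_min}{hydrogen-bond geometry, 3.5 A / 120}
#'   \item{persistence}{frames a new label must persist to count as a
#'     transition, 10}
#' }
#' @return named list of thresholds
#' @export
default_thresholds <- function() {
  list(r_arg = 3.5, r_K = 4.0, r_lytic = 3.8, r_polar = 4.0,
       bond_PgPb = 2.0, rotamer_w = 40, r_mg_shell = 2.6,
       hbond_d_max = 3.5, hbond_angle_min = 120, persistence = 10L)
}

state_labels <- function() {
  c("ATP_LIKE", "ADP_PI_A", "ADP_PI_B", "ADP_LIKE", "APO_2PI_MIMIC",
    "UNASSIGNED")
}

# atoms of the inorganic-phosphate oxygens of one Pi residue
pi_oxygens <- function(traj, pi_addr) {
  idx <- atom_index(traj, pi_addr$chain, pi_addr$resid)
  idx[traj$atoms$element[idx] == "O"]
}

role_atoms <- function(traj, pocket, role, names) {
  r <- pocket$roles[[role]]
  idx <- atom_index(traj, r$chain, r$resid, names)
  if (length(idx) == 0L)
    stop(sprintf("incomplete site: pocket %s role %s (%s:%d) lacks atom(s) %s",
                 pocket$pocket_id, role, r$chain, r$resid,
                 paste(names, collapse = "/")))
  idx
}

# gamma-phosphate atoms of an intact triphosphate (Pgamma + its oxygens)
gamma_phosphate_oxygens <- function(traj, nuc_addr) {
  idx <- atom_index(traj, nuc_addr$chain, nuc_addr$resid)
  idx[grepl("^O[0-9]G$", traj$atoms$name[idx])]
}

#' Featurize one pocket in one frame
#'
#' Computes the per-frame geometric feature vector of a nucleotide-binding
#' pocket: the arginine-finger binding distances d1 <= d2 (R359 Nh1/Nh2 to
#' the nearest Pi oxygen, sorted), the F360 chi1 torsion, engagement
#' distances of K251/N348/R362 to the Pi ion, Mg2+ distances to T252 Og1
#' and D304 carboxylate, the Pgamma-Pbeta distance (cleaved or not) and the
#' Mg2+ coordination shell. Features whose partners are absent (no Pi, no
#' Mg, no nucleotide) are NA.
#'
#' @param traj an [md_traj()]
#' @param frame_idx frame index
#' @param pocket a `pocket_spec`
#' @param thresholds see [default_thresholds()] (shell radius is used here)
#' @return list of class `site_features`
#' @export
featurize_site <- function(traj, frame_idx, pocket,
                           thresholds = default_thresholds()) {
  coords <- frame_coords(traj, frame_idx)
  a <- traj$atoms

  pis <- pocket$pi
  if (!is.null(pis) && !is.null(pis$resid) && length(pis$resid) > 1L) {
    pis <- lapply(pis$resid, function(r) list(chain = pis$chain, resid = r))
  } else if (!is.null(pis)) {
    pis <- list(pis)
  } else pis <- list()
  pis <- Filter(function(p) length(atom_index(traj, p$chain, p$resid)) > 0L,
                pis)
  n_pi <- length(pis)
  pi_o <- if (n_pi > 0L) pi_oxygens(traj, pis[[1]]) else integer(0)

  nuc <- pocket$nucleotide
  nucleotide <- NA_character_
  d_PgPb <- NA_real_
  if (!is.null(nuc)) {
    nuc_idx <- atom_index(traj, nuc$chain, nuc$resid)
    if (length(nuc_idx) > 0L) {
      nucleotide <- a$resname[nuc_idx[1]]
      pg <- nuc_idx[a$name[nuc_idx] == "PG"]
      pb <- nuc_idx[a$name[nuc_idx] == "PB"]
      if (length(pg) == 1L && length(pb) == 1L)
        d_PgPb <- atom_distance(coords, pg, pb)
    }
  }

  nh <- c(role_atoms(traj, pocket, "arg_finger_R", "NH1"),
          role_atoms(traj, pocket, "arg_finger_R", "NH2"))
  d_pair <- if (length(pi_o) > 0L)
    sort(c(min_distance(coords, nh[1], pi_o),
           min_distance(coords, nh[2], pi_o)))
  else c(NA_real_, NA_real_)

  dist_or_na <- function(set_a) {
    if (length(pi_o) == 0L) return(NA_real_)
    min_distance(coords, set_a, pi_o)
  }
  d_K251 <- dist_or_na(role_atoms(traj, pocket, "walkerA_K", "NZ"))
  d_N348 <- dist_or_na(role_atoms(traj, pocket, "sensor_N",
                                  c("ND2", "OD1")))
  d_R362 <- dist_or_na(role_atoms(traj, pocket, "arg_finger_R2",
                                  c("NH1", "NH2", "NE")))

  chi1_F360 <- tryCatch(
    chi1(traj, frame_idx, pocket$roles$finger_F$chain,
         pocket$roles$finger_F$resid),
    error = function(e) NA_real_)

  mg_idx <- if (!is.null(pocket$mg))
    atom_index(traj, pocket$mg$chain, pocket$mg$resid) else integer(0)
  d_Mg_T252 <- d_Mg_D304 <- NA_real_
  mg_shell <- NULL
  if (length(mg_idx) == 1L) {
    d_Mg_T252 <- min_distance(
      coords, mg_idx, role_atoms(traj, pocket, "walkerA_T", "OG1"))
    d_Mg_D304 <- min_distance(
      coords, mg_idx, role_atoms(traj, pocket, "walkerB_D", c("OD1", "OD2")))
    candidates <- which(a$element %in% c("O", "N"))
    mg_shell <- coordination_shell(coords, mg_idx, candidates,
                                   thresholds$r_mg_shell)
  }

  structure(list(d1 = d_pair[1], d2 = d_pair[2], chi1_F360 = chi1_F360,
                 d_K251_Pi = d_K251, d_N348_Pi = d_N348, d_R362_Pi = d_R362,
                 d_Mg_T252 = d_Mg_T252, d_Mg_D304 = d_Mg_D304,
                 d_Pgamma_Pbeta = d_PgPb, mg_shell = mg_shell,
                 n_pi = n_pi, nucleotide = nucleotide),
            class = "site_features")
}

#' Bin a chi1 torsion into canonical rotamers
#'
#' gauche(-) within `w` of -60, trans within `w` of 180 (wrapping through
#' -180), gauche(+) within `w` of +60; anything else is an outlier.
#'
#' @param chi1 torsion in degrees, (-180, 180]
#' @param w half-width of the bins in degrees (default 40)
#' @return one of "gauche_minus", "trans", "gauche_plus", "outlier"
#' @export
rotamer_bin <- function(chi1, w = 40) {
  if (is.na(chi1)) return("outlier")
  wrap <- function(x) {
    x <- (x + 180) %% 360 - 180
    x
  }
  if (abs(wrap(chi1 + 60)) <= w) return("gauche_minus")
  if (abs(wrap(chi1 - 180)) <= w) return("trans")
  if (abs(wrap(chi1 - 60)) <= w) return("gauche_plus")
  "outlier"
}

#' Classify a pocket state from its features
#'
#' Pure rule tree over the feature vector:
#' intact Pgamma-Pbeta bond -> `ATP_LIKE`; with a cleaved Pi present and a
#' nucleotide bound, a bidentate arginine finger (d1, d2 <= r_arg) with
#' engaged K251 and gauche(-) chi1 gives `ADP_PI_A`, a monodentate finger
#' (d1 <= r_arg < d2) with disengaged K251 and trans chi1 gives `ADP_PI_B`,
#' and conflicting evidence `UNASSIGNED`; ADP without Pi -> `ADP_LIKE`; two
#' Pi ions without nucleotide -> `APO_2PI_MIMIC`.
#'
#' @param features a `site_features`
#' @param thresholds see [default_thresholds()]
#' @return a state label (character)
#' @export
classify_state <- function(features, thresholds = default_thresholds()) {
  f <- features
  t <- thresholds
  if (!is.na(f$d_Pgamma_Pbeta) && f$d_Pgamma_Pbeta <= t$bond_PgPb)
    return("ATP_LIKE")
  has_nuc <- !is.na(f$nucleotide)
  if (f$n_pi >= 2L && !has_nuc) return("APO_2PI_MIMIC")
  if (f$n_pi == 0L)
    return(if (has_nuc && f$nucleotide == "ADP") "ADP_LIKE" else "UNASSIGNED")
  if (!has_nuc) return("UNASSIGNED")
  rot <- rotamer_bin(f$chi1_F360, t$rotamer_w)
  bidentate <- !is.na(f$d2) && f$d2 <= t$r_arg
  monodentate <- !is.na(f$d1) && f$d1 <= t$r_arg &&
    !is.na(f$d2) && f$d2 > t$r_arg
  k_engaged <- !is.na(f$d_K251_Pi) && f$d_K251_Pi <= t$r_K
  if (bidentate && k_engaged && rot == "gauche_minus") return("ADP_PI_A")
  if (monodentate && !k_engaged && rot == "trans") return("ADP_PI_B")
  "UNASSIGNED"
}

#' Score geometric hydrolysis competence of an ATP-bound pocket
#'
#' Three criteria on an intact triphosphate: (i) a water oxygen within
#' `r_lytic` of Pgamma that is simultaneously hydrogen-bonded to the E305
#' carboxylate (the positioned, polarized lytic water); (ii) an R359
#' guanidinium nitrogen (Nh1/Nh2/Ne) within `r_polar` of a gamma-phosphate
#' oxygen (the finger polarizes the scissile phosphate); (iii) a hydrogen
#' bond between the N348 side-chain amide and a gamma-phosphate oxygen (the
#' sensor holds the phosphate in place). `reactive` is their conjunction.
#'
#' @param traj an [md_traj()]
#' @param frame_idx frame index
#' @param pocket a `pocket_spec`
#' @param thresholds see [default_thresholds()]
#' @return list of class `competence_flags`
#' @export
score_competence <- function(traj, frame_idx, pocket,
                             thresholds = default_thresholds()) {
  t <- thresholds
  coords <- frame_coords(traj, frame_idx)
  a <- traj$atoms
  nuc <- pocket$nucleotide
  nuc_idx <- if (!is.null(nuc)) atom_index(traj, nuc$chain, nuc$resid)
             else integer(0)
  pg <- nuc_idx[a$name[nuc_idx] == "PG"]
  pb <- nuc_idx[a$name[nuc_idx] == "PB"]
  if (length(pg) != 1L || length(pb) != 1L ||
      atom_distance(coords, pg, pb) > t$bond_PgPb)
    stop("state mismatch: competence scoring needs an intact triphosphate")
  gamma_o <- gamma_phosphate_oxygens(traj, nuc)

  waters <- which(a$is_solvent & a$element == "O")
  e305_o <- role_atoms(traj, pocket, "walkerB_E", c("OE1", "OE2"))
  crit_water <- FALSE
  if (length(waters) > 0L) {
    d_w_pg <- vapply(waters, function(w) atom_distance(coords, w, pg),
                     numeric(1))
    near <- waters[d_w_pg <= t$r_lytic]
    for (w in near) {
      hb <- detect_hbonds(coords, donors = w, acceptors = e305_o,
                          d_max = t$hbond_d_max,
                          angle_min = t$hbond_angle_min,
                          elements = a$element)
      if (nrow(hb) > 0L) { crit_water <- TRUE; break }
    }
  }

  r359_n <- role_atoms(traj, pocket, "arg_finger_R", c("NH1", "NH2", "NE"))
  crit_r359 <- min_distance(coords, r359_n, gamma_o) <= t$r_polar

  n348_amide <- role_atoms(traj, pocket, "sensor_N", c("ND2", "OD1"))
  hb_n348 <- detect_hbonds(coords, donors = n348_amide, acceptors = gamma_o,
                           d_max = t$hbond_d_max,
                           angle_min = t$hbond_angle_min,
                           elements = a$element)
  crit_n348 <- nrow(hb_n348) > 0L

  structure(list(crit_water_E305 = crit_water,
                 crit_R359_polarizes = crit_r359,
                 crit_N348_holds = crit_n348,
                 reactive = crit_water && crit_r359 && crit_n348),
            class = "competence_flags")
}

#' Per-frame state labels and persistence-filtered transitions
#'
#' Labels every frame of the pocket, then scans for transitions: a
#' transition is reported at the first frame of a run of at least
#' `persistence` identical labels that differ from the previously accepted
#' label. Label flicker shorter than `persistence` is suppressed.
#'
#' @param traj an [md_traj()]
#' @param pocket a `pocket_spec`
#' @param thresholds see [default_thresholds()]
#' @param persistence minimum run length in frames (>= 1)
#' @return list with `records` (data.frame: frame, label and the scalar
#'   features) and `transitions` (data.frame: frame, from, to)
#' @export
state_timeseries <- function(traj, pocket, thresholds = default_thresholds(),
                             persistence = thresholds$persistence) {
  stopifnot(persistence >= 1L)
  nf <- n_frames(traj)
  labels <- character(nf)
  feat_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    ft <- featurize_site(traj, f, pocket, thresholds)
    labels[f] <- classify_state(ft, thresholds)
    feat_rows[[f]] <- data.frame(
      frame = f, d1 = ft$d1, d2 = ft$d2, chi1_F360 = ft$chi1_F360,
      d_K251_Pi = ft$d_K251_Pi, d_N348_Pi = ft$d_N348_Pi,
      d_R362_Pi = ft$d_R362_Pi, d_Mg_T252 = ft$d_Mg_T252,
      d_Mg_D304 = ft$d_Mg_D304, d_Pgamma_Pbeta = ft$d_Pgamma_Pbeta,
      label = labels[f])
  }
  records <- do.call(rbind, feat_rows)
  records$pocket_id <- pocket$pocket_id

  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  accepted <- labels[1]
  transitions <- list()
  for (r in seq_along(runs$lengths)) {
    if (runs$lengths[r] >= persistence && runs$values[r] != accepted) {
      transitions[[length(transitions) + 1L]] <- data.frame(
        frame = starts[r], from = accepted, to = runs$values[r])
      accepted <- runs$values[r]
    }
  }
  transitions <- if (length(transitions) > 0L) do.call(rbind, transitions)
    else data.frame(frame = integer(0), from = character(0),
                    to = character(0))
  list(records = records, transitions = transitions)
}

#' Cluster ion positions in the pocket-local frame
#'
#' Frames are first superposed onto the first frame using the cis-subunit
#' C-alpha atoms, so the clustering is invariant to global rigid motion.
#' Leader clustering: each frame's ion position joins the first existing
#' cluster whose (running) centroid lies within `radius`, otherwise it
#' seeds a new cluster; centroids are recomputed once after assignment, and
#' clusters are sorted by occupancy.
#'
#' @param traj an [md_traj()]
#' @param pocket a `pocket_spec`
#' @param species `"MG"` or `"PI"`
#' @param radius cluster radius in Angstrom
#' @return data.frame with columns x, y, z (centroid), occupancy, n_frames,
#'   plus a `members` list-column of frame indices; empty if the ion is
#'   never present
#' @export
cluster_ion_positions <- function(traj, pocket, species = c("PI", "MG"),
                                  radius = 2.0) {
  species <- match.arg(species)
  addr <- if (species == "MG") pocket$mg else pocket$pi
  if (!is.null(addr) && !is.null(addr$resid) && length(addr$resid) > 1L)
    addr <- list(chain = addr$chain, resid = addr$resid[1])
  ion <- if (!is.null(addr)) atom_index(traj, addr$chain, addr$resid)
         else integer(0)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0), n_frames = integer(0))
  if (length(ion) == 0L) return(empty)

  cis_ca <- which(traj$atoms$chain == pocket$cis_chain &
                  traj$atoms$name == "CA")
  local <- superpose_trajectory(traj, cis_ca, 1L)
  nf <- n_frames(local)
  pos <- t(vapply(seq_len(nf), function(f)
    colMeans(frame_coords(local, f)[ion, , drop = FALSE]), numeric(3)))

  centroids <- list()
  members <- list()
  for (f in seq_len(nf)) {
    assigned <- FALSE
    for (k in seq_along(centroids)) {
      if (vnorm(pos[f, ] - centroids[[k]]) <= radius) {
        members[[k]] <- c(members[[k]], f)
        centroids[[k]] <- colMeans(pos[members[[k]], , drop = FALSE])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids[[length(centroids) + 1L]] <- pos[f, ]
      members[[length(members) + 1L]] <- f
    }
  }
  cent <- t(vapply(members, function(m)
    colMeans(pos[m, , drop = FALSE]), numeric(3)))
  occ <- lengths(members) / nf
  ord <- order(-occ)
  out <- data.frame(x = cent[ord, 1], y = cent[ord, 2], z = cent[ord, 3],
                    occupancy = occ[ord], n_frames = lengths(members)[ord])
  out$members <- members[ord]
  out
}
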