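#' Synthetic active-site fixtures with planted ground truth
#'
#' Generates minimal, idealized nucleotide-binding-pocket models (a cis
#' chain A carrying the Walker motifs, sensor asparagine, sensor-loop
#' backbone 347-361 and relay residues; a trans chain B carrying the
#' arginine fingers R359/R362 and F360; ligands ATP/ADP, Mg2+, inorganic
#' phosphate, waters) whose internal coordinates are set analytically so
#' that, at zero noise, each planted state satisfies its classification
#' rule with at least 0.5 A margin on every threshold. Side-chain tips are
#' placed directly at their target positions (the connecting bonds are
#' approximate): the fixtures are geometric ground truth, not energetic or
#' stereochemical models.
#'
#' @name synthetic_data
NULL

deg2rad <- function(x) x * pi / 180

unit <- function(v) v / vnorm(v)

# NeRF internal-coordinate placement: position d with |cd| = bond,
# angle(b,c,d) = ang and dihedral(a,b,c,d) = tor (degrees)
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- deg2rad(ang); tor <- deg2rad(tor)
  bc_u <- unit(c - b)
  n_u <- unit(cross3(b - a, bc_u))
  m_u <- cross3(n_u, bc_u)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  as.numeric(cbind(bc_u, m_u, n_u) %*% d_local + c)
}

# tetrahedral unit directions
tetra_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# tetrahedron around a phosphorus: one vertex along `apex_dir`, the other
# three at 109.47 degrees from it
phosphate_oxygens <- function(p, apex_dir, bond = 1.52) {
  a <- unit(apex_dir)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- unit(cross3(a, ref))
  w <- cross3(a, v)
  dirs <- rbind(a, t(vapply(c(0, 120, 240), function(th) {
    -a / 3 + sqrt(8) / 9 * 3 * (cos(deg2rad(th)) * v + sin(deg2rad(th)) * w)
  }, numeric(3))))
  sweep(dirs * bond, 2L, p, "+")
}

atom_row <- function(chain, resid, resname, name, element, xyz) {
  data.frame(chain = chain, resid = as.integer(resid), resname = resname,
             name = name, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3],
             stringsAsFactors = FALSE)
}

res_block <- function(chain, resid, resname, coords) {
  do.call(rbind, lapply(names(coords), function(nm) {
    el <- substr(gsub("[0-9'].*$", "", nm), 1L, 1L)
    atom_row(chain, resid, resname, nm, el, coords[[nm]])
  }))
}

# planar guanidinium: NE/NH1/NH2 at 1.33 A from CZ, 120 degrees apart in
# the plane with normal `normal`; NE along `ne_dir` (projected)
guanidinium <- function(cz, ne_dir, normal) {
  n <- unit(normal)
  e1 <- unit(ne_dir - sum(ne_dir * n) * n)
  e2 <- cross3(n, e1)
  ang <- function(th) cz + 1.33 * (cos(deg2rad(th)) * e1 +
                                     sin(deg2rad(th)) * e2)
  list(NE = ang(180), NH1 = ang(60), NH2 = ang(-60))
}

# --- fixed pocket geometry -------------------------------------------------

MG_POS <- c(0.878, -0.878, -2.928)
SHELL_SITE <- function(dir) MG_POS + 2.05 * dir

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- vnorm(v); cth <- sum(a * b)
  if (s < 1e-12) return(diag(3) * sign(cth))
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# sensor-loop backbone 347-361 by NeRF from planted (phi, psi), then
# rigidly parked in free space: CA348 anchored, helix axis pointing away
# from the pocket
build_loop <- function(phi_psi, anchor = c(-9.5, -7.5, 5.5),
                       axis_dir = c(-0.55, -0.55, 0.63)) {
  resids <- 347:361
  stopifnot(nrow(phi_psi) == length(resids))
  n1 <- c(0, 0, 0)
  ca1 <- c(1.458, 0, 0)
  c1 <- ca1 + 1.525 * c(cos(deg2rad(180 - 111)), sin(deg2rad(180 - 111)), 0)
  res <- list()
  n <- n1; ca <- ca1; cc <- c1
  for (k in seq_along(resids)) {
    psi <- phi_psi$psi[k]
    n_next <- place_atom(n, ca, cc, 1.329, 116.6, psi)
    o <- place_atom(n, ca, cc, 1.231, 120.5, psi - 180)
    res[[as.character(resids[k])]] <- list(N = n, CA = ca, C = cc, O = o)
    if (k == length(resids)) break
    ca_next <- place_atom(ca, cc, n_next, 1.458, 121.7, 180)
    c_next <- place_atom(cc, n_next, ca_next, 1.525, 111.0,
                         phi_psi$phi[k + 1L])
    n <- n_next; ca <- ca_next; cc <- c_next
  }
  axis <- res[["361"]]$CA - res[["347"]]$CA
  rot <- rotation_between(axis, axis_dir)
  pivot <- res[["348"]]$CA
  lapply(res, function(bb) lapply(bb, function(p)
    as.numeric(rot %*% (p - pivot)) + anchor))
}

# default loop torsions: compact helical turn (-75, -50), outside the
# 3-10 window; the ADP state converts R349-I353 to a 3-10 helix (-49, -26)
loop_torsions <- function(state) {
  resids <- 347:361
  tab <- data.frame(resid = resids, phi = -75, psi = -50)
  if (state == "ADP_LIKE") {
    hel <- tab$resid >= 349 & tab$resid <= 353
    tab$phi[hel] <- -49
    tab$psi[hel] <- -26
  }
  tab
}

# attach an Asn/Arg side chain whose tip is planted at `target`
asn_sidechain <- function(bb, target) {
  cb <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, -122)
  cg <- cb + 0.55 * (target - cb)
  od1 <- cg + 1.23 * unit(cross3(target - cg, cb - cg))
  list(CB = cb, CG = cg, OD1 = od1, ND2 = target)
}

arg_sidechain <- function(bb, cz_target, pocket_center = c(0, 0, 0)) {
  cb <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, -122)
  cg <- cb + 0.33 * (cz_target - cb)
  cd <- cb + 0.66 * (cz_target - cb)
  g <- guanidinium(cz_target, ne_dir = cd - cz_target,
                   normal = cross3(cd - cz_target,
                                   pocket_center - cz_target))
  c(list(CB = cb, CG = cg, CD = cd, CZ = cz_target), g)
}

# Phe side chain with exact chi1 built from ideal internal coordinates
phe_sidechain <- function(n, ca, c, chi1) {
  cb <- place_atom(c, n, ca, 1.53, 110.5, -122)
  cg <- place_atom(n, ca, cb, 1.50, 113.8, chi1)
  cd1 <- place_atom(ca, cb, cg, 1.39, 120.8, 90)
  cd2 <- place_atom(ca, cb, cg, 1.39, 120.8, -90)
  list(CB = cb, CG = cg, CD1 = cd1, CD2 = cd2)
}

fixture_states <- function() {
  c("ATP_LIKE", "REACTIVE_ATP", "ADP_PI_A", "ADP_PI_B", "ADP_LIKE",
    "APO_2PI_MIMIC")
}

# state-dependent single-structure coordinates of the whole pocket
pocket_atoms <- function(state) {
  stopifnot(state %in% fixture_states())
  td <- tetra_dirs() * 1.52
  atp <- state %in% c("ATP_LIKE", "REACTIVE_ATP")
  adp <- state %in% c("ADP_PI_A", "ADP_PI_B", "ADP_LIKE")
  has_mg <- state != "APO_2PI_MIMIC"
  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  # --- chain A: Walker motifs and relay residues
  add(res_block("A", 251, "LYS", list(
    N = c(-9.9, 2.1, 1.5), CA = c(-9.1, 2.7, 0.6), C = c(-9.9, 3.2, -0.6),
    O = c(-9.5, 3.3, -1.8), CB = c(-7.9, 1.9, 0.2), CG = c(-6.7, 2.5, -0.3),
    CD = c(-5.5, 1.7, -0.7), CE = c(-4.2, 2.2, -1.1),
    NZ = c(-3.0, 1.5, -1.5))))
  og1 <- if (atp) SHELL_SITE(c(1, 0, 0)) else c(5.3, -0.5, -3.3)
  cb252 <- og1 + c(1.0, -0.7, -0.7)
  add(res_block("A", 252, "THR", list(
    N = c(8.4, 0.3, -3.8), CA = c(7.5, -0.6, -4.6), C = c(8.2, -1.5, -5.4),
    O = c(7.8, -2.6, -5.7), CB = cb252, OG1 = og1,
    CG2 = cb252 + c(0.4, -1.2, 0.8))))
  add(res_block("A", 304, "ASP", list(
    N = c(1.221, -7.533, -4.903), CA = c(2.110, -6.643, -4.162),
    C = c(3.494, -7.104, -4.623), O = c(4.115, -8.098, -4.250),
    CB = c(1.646, -5.407, -3.389), CG = c(0.878, -4.178, -2.928),
    OD1 = SHELL_SITE(c(0, -1, 0)), OD2 = c(0.012, -4.921, -2.433))))
  if (atp) {
    add(res_block("A", 305, "GLU", list(
      N = c(-7.0, -6.4, 3.8), CA = c(-6.1, -6.8, 3.0),
      C = c(-6.5, -8.1, 2.6), O = c(-6.0, -9.0, 3.3),
      CB = c(-5.17, -5.85, 2.18), CG = c(-4.24, -4.92, 1.41),
      CD = c(-3.32, -4.0, 0.64), OE1 = c(-2.53, -3.05, 0.49),
      OE2 = c(-3.32, -4.75, 1.64))))
  } else {
    add(res_block("A", 305, "GLU", list(
      N = c(-2.4, -7.5, 9.3), CA = c(-1.4, -7.9, 8.6),
      C = c(-0.6, -8.9, 9.4), O = c(0.3, -9.4, 8.8),
      CB = c(-0.964, -6.885, 7.652), CG = c(-0.5, -6.112, 6.416),
      CD = c(-0.5, -5.2, 5.2), OE1 = c(-0.121, -4.190, 4.569),
      OE2 = c(-1.4, -4.6, 4.9))))
  }
  add(res_block("A", 312, "LYS", list(
    N = c(4.3, 16.2, 3.7), CA = c(3.6, 15.6, 4.6), C = c(4.5, 15.2, 5.7),
    O = c(5.2, 14.3, 5.5), CB = c(2.8, 14.5, 4.0), CG = c(2.0, 13.4, 4.6),
    CD = c(1.2, 12.3, 4.0), CE = c(0.5, 11.2, 4.6), NZ = c(0, 10, 4))))
  r313_bb <- list(N = c(-12.2, 14.0, 10.4), CA = c(-11.3, 14.6, 9.6),
                  C = c(-11.9, 15.2, 8.4), O = c(-11.5, 16.2, 7.8))
  add(res_block("A", 313, "ARG", c(r313_bb, arg_sidechain(
    r313_bb, cz_target = c(-6, 12, 8)))))
  k315_bb <- list(N = c(-15.2, 13.1, 13.8), CA = c(-14.3, 13.7, 13.0),
                  C = c(-14.9, 14.4, 11.8), O = c(-14.4, 15.0, 10.8))
  add(res_block("A", 315, "LYS", c(k315_bb, list(
    CB = c(-13.2, 12.9, 12.5), CG = c(-12.1, 12.1, 12.0),
    CD = c(-11.0, 11.3, 11.5), CE = c(-9.9, 10.5, 11.0),
    NZ = c(-9, 10, 10)))))

  # --- chain A: sensor loop 347-361 with planted torsions
  loop <- build_loop(loop_torsions(state))
  loop_resnames <- c(`347` = "GLY", `348` = "ASN", `349` = "ARG",
                     `350` = "GLY", `351` = "ALA", `352` = "ALA",
                     `353` = "ILE", `354` = "GLY", `355` = "ALA",
                     `356` = "SER", `357` = "ALA", `358` = "GLY",
                     `359` = "ARG", `360` = "PHE", `361` = "ALA")
  nd2_target <- if (atp) c(-2.2, 2.2, -2.2) else c(-1.5, -2.8, 1.5)
  for (rid in names(loop)) {
    bb <- loop[[rid]]
    extra <- list()
    if (rid == "348") extra <- asn_sidechain(bb, nd2_target)
    if (rid == "349") extra <- arg_sidechain(bb, cz_target = c(-2, 6, 4))
    add(res_block("A", as.integer(rid), loop_resnames[[rid]],
                  c(bb, extra)))
  }

  # --- chain B (trans): arginine fingers and F360
  r359_bb <- list(N = c(10.1, 1.5, -0.8), CA = c(9.35, 2.1, 0.2),
                  C = c(10.0, 2.4, 1.4), O = c(9.6, 3.3, 2.1))
  add(res_block("B", 359, "ARG", c(r359_bb, list(
    CB = c(8.0, 1.6, 0.7), CG = c(7.6, 0.3, 0.8), CD = c(6.33, 0.85, 0.35),
    NE = c(5.38, 0, 0), CZ = c(4.05, 0, 0),
    NH1 = c(3.378, 0.878, 0.878), NH2 = c(3.378, -0.878, -0.878)))))
  chi1_f360 <- if (state %in% c("ADP_PI_A", "APO_2PI_MIMIC")) -60 else 180
  f_n <- c(11.667, -0.084, 4.157)
  f_ca <- c(10.5, 0.5, 3.5)
  f_c <- c(9.76, 1.758, 3.944)
  add(res_block("B", 360, "PHE", c(
    list(N = f_n, CA = f_ca, C = f_c, O = f_c + c(-0.6, 0.6, 0.9)),
    phe_sidechain(f_n, f_ca, f_c, chi1_f360))))
  add(res_block("B", 362, "ARG", list(
    N = c(15.0, -7.2, -4.5), CA = c(14.3, -7.7, -3.5), C = c(15.1, -7.8, -2.3),
    O = c(15.0, -8.9, -1.9), CB = c(13.1, -6.9, -3.1),
    CG = c(11.9, -7.5, -2.6), CD = c(10.8, -6.6, -2.2),
    NE = c(9.5, -7.0, -1.9), CZ = c(8.6, -6.2, -1.2),
    NH1 = c(7.6, -6.6, -0.6), NH2 = c(9.0, -5.1, -0.7))))

  # --- ligands (chain L)
  if (atp) {
    pg <- c(0, 0, 0)
    pb <- 1.4 * unit(td[4, ])
    add(res_block("L", 401, "ATP", list(
      PG = pg, O1G = td[1, ], O2G = td[2, ], O3G = td[3, ],
      PB = pb, O1B = c(-2.2, -1.2, 1.2), O2B = c(-1.2, -2.2, 1.0),
      O3B = c(-1.0, -0.6, 2.3), O3A = c(-2.0, -1.8, 2.5),
      PA = c(-2.8, -2.8, 3.4), O1A = c(-4.1, -2.5, 3.6),
      O2A = c(-2.3, -3.9, 4.3))))
  } else if (adp) {
    add(res_block("L", 401, "ADP", list(
      PA = c(0.9, 1.4, -8.5), O1A = c(-0.3, 2.0, -8.9),
      O2A = c(2.1, 2.1, -8.3), O3A = c(0.9, 0.5, -7.2),
      PB = c(0.878, -0.878, -6.498), O1B = c(-0.5, -1.3, -7.0),
      O2B = SHELL_SITE(c(0, 0, -1)), O3B = c(2.1, -1.6, -6.9))))
  }
  if (state %in% c("ADP_PI_A", "APO_2PI_MIMIC")) {
    o <- sweep(td, 2L, c(0, 0, 0), "+")
    add(res_block("L", 402, "PO4", list(
      P = c(0, 0, 0), O1 = o[1, ], O2 = o[2, ], O3 = o[3, ], O4 = o[4, ])))
  }
  if (state == "ADP_PI_B") {
    u <- unit(c(0.3, -0.9, -0.3))
    nh2 <- c(3.378, -0.878, -0.878)
    p_b <- nh2 + (2.6 + 1.52) * u
    o <- phosphate_oxygens(p_b, apex_dir = -u)
    add(res_block("L", 402, "PO4", list(
      P = p_b, O1 = o[1, ], O2 = o[2, ], O3 = o[3, ], O4 = o[4, ])))
  }
  if (state == "APO_2PI_MIMIC") {
    p2 <- c(0.878, -0.878, -6.498)
    o <- phosphate_oxygens(p2, apex_dir = c(0, 0, 1))
    add(res_block("L", 403, "PO4", list(
      P = p2, O1 = o[1, ], O2 = o[2, ], O3 = o[3, ], O4 = o[4, ])))
    add(res_block("L", 405, "NA", list(NA1 = MG_POS)))
  }
  if (has_mg) add(atom_row("L", 404, "MG", "MG", "MG", MG_POS))

  # --- waters (chain S): Mg shell completion + bulk
  w <- list()
  w$`502` <- SHELL_SITE(c(0, 1, 0))
  w$`503` <- SHELL_SITE(c(-1, 0, 0))
  w$`501` <- if (atp) SHELL_SITE(c(0, 0, -1)) else SHELL_SITE(c(1, 0, 0))
  w$`504` <- if (state %in% c("ADP_PI_B", "ADP_LIKE"))
    SHELL_SITE(c(0, 0, 1)) else c(6.5, 6.5, 6.5)
  w$`500` <- if (state == "REACTIVE_ATP") c(-1.67, -1.67, -1.67)
    else c(8, 8, -6)
  for (rid in names(w))
    add(atom_row("S", as.integer(rid), "HOH", "O", "O", w[[rid]]))

  out <- do.call(rbind, rows)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

coords_matrix <- function(tab) as.matrix(tab[, c("x", "y", "z")])

atoms_table <- function(tab) {
  data.frame(serial = tab$serial, name = tab$name, element = tab$element,
             resname = tab$resname, resid = tab$resid, chain = tab$chain,
             stringsAsFactors = FALSE)
}

#' Pocket specification matching the synthetic fixtures
#'
#' @param state fixture state (see [build_fixture()]); controls which
#'   ligand addresses are present
#' @return a `pocket_spec` (cis chain A, trans chain B)
#' @export
fixture_pocket <- function(state = "ADP_PI_A") {
  stopifnot(state %in% c(fixture_states(), "ESCAPE"))
  atp <- state %in% c("ATP_LIKE", "REACTIVE_ATP")
  nucleotide <- if (atp) list(chain = "L", resid = 401L, resname = "ATP")
    else if (state %in% c("ADP_PI_A", "ADP_PI_B", "ADP_LIKE", "ESCAPE"))
      list(chain = "L", resid = 401L, resname = "ADP")
    else NULL
  pi <- if (state %in% c("ADP_PI_A", "ADP_PI_B", "ESCAPE"))
    list(chain = "L", resid = 402L)
    else if (state == "APO_2PI_MIMIC") list(chain = "L", resid = c(402L, 403L))
    else NULL
  mg <- if (state %in% c("APO_2PI_MIMIC", "ESCAPE")) NULL
    else list(chain = "L", resid = 404L)
  new_pocket_spec("D1:A-B", "A", "B", nucleotide = nucleotide,
                  mg = mg, pi = pi)
}

# thermal noise as per-residue rigid Gaussian displacements: every atom's
# marginal displacement is N(0, sigma^2) per coordinate while covalent
# geometry (bond lengths, torsions) within a residue is preserved
residue_noise <- function(tab, sigma) {
  key <- paste(tab$chain, tab$resid)
  groups <- match(key, unique(key))
  shift <- matrix(stats::rnorm(3L * max(groups), sd = sigma),
                  max(groups), 3L)
  shift[groups, , drop = FALSE]
}

#' Build a synthetic pocket fixture
#'
#' States: `ATP_LIKE` (intact triphosphate), `REACTIVE_ATP` (ATP plus the
#' three hydrolysis-competence features: positioned lytic water
#' hydrogen-bonded to E305, polarizing R359, sensor N348 holding the
#' gamma-phosphate), `ADP_PI_A` (cleaved Pi held by K251/N348, bidentate
#' R359, F360 chi1 -60), `ADP_PI_B` (Pi detached from K251, monodentate
#' R359, chi1 180), `ADP_LIKE` (no Pi; sensor loop 349-353 as 3-10 helix),
#' `APO_2PI_MIMIC` (two Pi ions bridged by Na+, no nucleotide, no Mg).
#' Mg2+ carries exactly 6 octahedral shell partners in the ADP.Pi states.
#'
#' @param state one of the above
#' @param n_frames number of frames (>= 1)
#' @param noise_sigma per-coordinate Gaussian noise amplitude in Angstrom
#' @param switch optional `list(to_state =, frame =)`: frames from `frame`
#'   on are built from `to_state` (topology must match, i.e. A <-> B)
#' @param seed RNG seed (fixtures are bit-identical for identical spec+seed)
#' @return list with `traj` ([md_traj()]), `truth` (planted labels, chi1,
#'   switch frame, sigma, seed) and `pocket` (a `pocket_spec`)
#' @export
build_fixture <- function(state = "ADP_PI_A", n_frames = 1L,
                          noise_sigma = 0, switch = NULL, seed = 1L) {
  stopifnot(state %in% fixture_states(), n_frames >= 1L, noise_sigma >= 0)
  if (!is.null(switch)) {
    if (n_frames < 2L || is.null(switch$frame) || is.null(switch$to_state))
      stop("fixture spec error: switch needs a trajectory and a target state")
    if (switch$frame < 1L || switch$frame > n_frames)
      stop("fixture spec error: switch frame outside trajectory")
  }
  base <- pocket_atoms(state)
  labels <- rep(state, n_frames)
  coords <- list(coords_matrix(base))
  if (!is.null(switch)) {
    target <- pocket_atoms(switch$to_state)
    if (!identical(atoms_table(target)[, -1L], atoms_table(base)[, -1L]))
      stop("fixture spec error: switch states have different topologies")
    coords[[2L]] <- coords_matrix(target)
    labels[seq(switch$frame, n_frames)] <- switch$to_state
  }
  set.seed(seed)
  nat <- nrow(base)
  xyz <- matrix(NA_real_, n_frames, 3L * nat)
  for (f in seq_len(n_frames)) {
    cc <- if (!is.null(switch) && f >= switch$frame) coords[[2L]]
          else coords[[1L]]
    if (noise_sigma > 0) cc <- cc + residue_noise(base, noise_sigma)
    xyz[f, ] <- as.numeric(t(cc))
  }
  planted_chi1 <- ifelse(labels %in% c("ADP_PI_A", "APO_2PI_MIMIC"),
                         -60, 180)
  list(traj = md_traj(atoms_table(base), xyz),
       truth = list(state = labels, chi1_F360 = planted_chi1,
                    switch_frame = if (is.null(switch)) NA_integer_
                                   else as.integer(switch$frame),
                    noise_sigma = noise_sigma, seed = seed,
                    loop_is_310 = state == "ADP_LIKE"),
       pocket = fixture_pocket(state))
}

#' Build a phosphate-escape trajectory
#'
#' State-A pocket with the Mg2+ ion removed (expediting dissociation); the
#' Pi centroid follows a piecewise-linear path that dwells within 2.5 A of
#' each waypoint's side-chain tip in order -- by default the arginine
#' finger R359 (trans), then relay residues R349 and R313 (cis) -- and then
#' exits beyond 8 A of all of them.
#'
#' @param n_frames trajectory length (default 200)
#' @param noise_sigma per-coordinate Gaussian noise in Angstrom
#' @param seed RNG seed
#' @param waypoints character vector of waypoint keys among
#'   `c("B:359", "A:349", "A:313")` (subset, in order); the default is the
#'   full hand-over sequence
#' @return list with `traj`, `truth` (waypoint order, per-leg frame
#'   fractions, channel probe points, seed) and `pocket`
#' @export
build_escape_trajectory <- function(n_frames = 200L, noise_sigma = 0,
                                    seed = 1L,
                                    waypoints = c("B:359", "A:349", "A:313")) {
  stopifnot(n_frames >= length(waypoints) * 2L)
  base <- pocket_atoms("ADP_PI_A")
  base <- base[!(base$resname == "MG"), , drop = FALSE]
  base$serial <- seq_len(nrow(base))
  stations <- list(`B:359` = c(4.05, -1.0, 1.6),
                   `A:349` = c(-1.3, 5.3, 5.0),
                   `A:313` = c(-5.3, 11.3, 8.8))
  unknown <- setdiff(waypoints, names(stations))
  if (length(unknown) > 0L)
    stop("fixture spec error: unknown waypoint(s): ",
         paste(unknown, collapse = ", "))
  pts <- lapply(waypoints, function(w) stations[[w]])
  exit <- c(-11, 21, 15)

  # centroid schedule: dwell at each station, linear legs between, exit leg
  dwell_frac <- c(0.32, 0.23, 0.16)[seq_along(pts)]
  dwell_frac <- dwell_frac / sum(dwell_frac) * 0.75
  leg_frac <- rep(0.25 / length(pts), length(pts))
  centers <- matrix(NA_real_, n_frames, 3L)
  f <- 1L
  alloc <- function(frac) max(1L, as.integer(round(frac * n_frames)))
  for (k in seq_along(pts)) {
    nd <- alloc(dwell_frac[k])
    for (i in seq_len(nd)) {
      if (f <= n_frames) { centers[f, ] <- pts[[k]]; f <- f + 1L }
    }
    to <- if (k < length(pts)) pts[[k + 1L]] else exit
    nl <- alloc(leg_frac[k])
    for (i in seq_len(nl)) {
      if (f <= n_frames) {
        centers[f, ] <- pts[[k]] + (i / (nl + 1L)) * (to - pts[[k]])
        f <- f + 1L
      }
    }
  }
  while (f <= n_frames) { centers[f, ] <- exit; f <- f + 1L }

  pi_rows <- which(base$resname == "PO4")
  pi_offsets <- sweep(coords_matrix(base[pi_rows, , drop = FALSE]), 2L,
                      colMeans(coords_matrix(base[pi_rows, , drop = FALSE])))
  set.seed(seed)
  nat <- nrow(base)
  xyz <- matrix(NA_real_, n_frames, 3L * nat)
  base_xyz <- coords_matrix(base)
  for (fr in seq_len(n_frames)) {
    cc <- base_xyz
    cc[pi_rows, ] <- sweep(pi_offsets, 2L, centers[fr, ], "+")
    if (noise_sigma > 0) cc <- cc + residue_noise(base, noise_sigma)
    xyz[fr, ] <- as.numeric(t(cc))
  }
  # channel probe points: stations interleaved with leg midpoints
  channel <- list(pts[[1L]])
  if (length(pts) > 1L) {
    for (k in seq_len(length(pts) - 1L)) {
      channel <- c(channel, list((pts[[k]] + pts[[k + 1L]]) / 2),
                   list(pts[[k + 1L]]))
    }
  }
  channel <- do.call(rbind, channel)
  list(traj = md_traj(atoms_table(base), xyz),
       truth = list(waypoints = waypoints,
                    dwell_frames = vapply(dwell_frac, alloc, integer(1)),
                    channel_points = channel,
                    centers = centers, noise_sigma = noise_sigma,
                    seed = seed),
       pocket = fixture_pocket("ESCAPE"))
}

#' Build a mobility fixture: rigid scaffold plus planted per-residue noise
#'
#' C-alpha trace on a helix (radius 8 A, rise 1.5 A/residue) with isotropic
#' per-atom Gaussian displacements of per-residue amplitude `sigma`;
#' optional random global rigid motion per frame to exercise the alignment
#' step of RMSF. The expected RMSF of residue i is `sigma_i * sqrt(3)`.
#'
#' @param sigma scalar or per-residue vector of noise amplitudes (A per
#'   coordinate)
#' @param n_residues number of residues (default 60; ignored when `sigma`
#'   is a vector)
#' @param n_frames number of frames (default 2000)
#' @param seed RNG seed
#' @param global_motion apply a random rotation + translation per frame
#' @return list with `traj` and `truth` (`sigma` per residue, seed)
#' @export
build_mobility_fixture <- function(sigma = 0.2, n_residues = 60L,
                                   n_frames = 2000L, seed = 1L,
                                   global_motion = FALSE) {
  if (length(sigma) > 1L) n_residues <- length(sigma)
  sigma <- rep_len(sigma, n_residues)
  stopifnot(all(sigma >= 0), n_frames >= 2L)
  i <- seq_len(n_residues)
  scaffold <- cbind(8 * cos(0.6 * i), 8 * sin(0.6 * i), 1.5 * i)
  atoms <- data.frame(serial = i, name = "CA", element = "C",
                      resname = "ALA", resid = i, chain = "A",
                      stringsAsFactors = FALSE)
  set.seed(seed)
  # noise is drawn first so that, for one seed, the displacements are
  # identical with and without the global-motion overlay
  noise <- lapply(seq_len(n_frames), function(f)
    matrix(stats::rnorm(3L * n_residues, sd = sigma), n_residues, 3L))
  xyz <- matrix(NA_real_, n_frames, 3L * n_residues)
  for (f in seq_len(n_frames)) {
    cc <- scaffold + noise[[f]]
    if (global_motion) {
      qr_d <- qr(matrix(stats::rnorm(9L), 3L))
      rot <- qr.Q(qr_d)
      if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
      cc <- cc %*% rot +
        matrix(stats::runif(3L, -5, 5), n_residues, 3L, byrow = TRUE)
    }
    xyz[f, ] <- as.numeric(t(cc))
  }
  list(traj = md_traj(atoms, xyz),
       truth = list(sigma = sigma, expected_rmsf = sigma * sqrt(3),
                    seed = seed, global_motion = global_motion))
}

#' Assemble a ring of pockets for topology-level tests
#'
#' Replicates the pocket fixture with 6-fold rotational symmetry. Chain k
#' carries the cis residues of pocket k and the trans-role side chains
#' (R359, F360, R362) serving pocket k-1; backbone-only loop copies of
#' residues 359-361 are dropped in favour of the full trans versions.
#' Ligands keep the cis chain's letter. With `two_domain = TRUE` a second
#' ring (residue numbers offset by `domain_offset`, shifted along z)
#' models the second ATPase domain, giving 12 pockets in total. Intended
#' for chain/pocket/selection accounting, not for geometric analyses.
#'
#' @param state pocket state to replicate
#' @param n_chains number of subunits (default 6)
#' @param two_domain add the second domain ring
#' @param domain_offset residue-number offset of the second domain
#' @return an [md_traj()] with one frame
#' @export
assemble_ring <- function(state = "ADP_PI_A", n_chains = 6L,
                          two_domain = FALSE, domain_offset = 250L) {
  base <- pocket_atoms(state)
  chains <- LETTERS[seq_len(n_chains)]
  ring_radius <- 40
  one_domain <- function(offset, z_shift) {
    rows <- list()
    for (k in seq_len(n_chains)) {
      th <- 2 * pi * (k - 1L) / n_chains
      rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                   c(0, 0, 1))
      placed <- base
      m <- coords_matrix(base)
      m <- sweep(m, 2L, c(ring_radius, 0, 0), "+") %*% t(rot)
      m[, 3L] <- m[, 3L] + z_shift
      placed[, c("x", "y", "z")] <- m
      cis <- placed$chain == "A" & !(placed$resid %in% 359:361)
      trans <- placed$chain == "B"
      lig <- placed$chain %in% c("L", "S")
      ck <- chains[k]
      ck_next <- chains[if (k == n_chains) 1L else k + 1L]
      placed$chain[cis] <- ck
      placed$chain[trans] <- ck_next
      placed$chain[lig] <- ck
      placed$resid <- placed$resid + offset
      rows[[k]] <- placed[cis | trans | lig, , drop = FALSE]
    }
    do.call(rbind, rows)
  }
  tab <- one_domain(0L, 0)
  if (two_domain) tab <- rbind(tab, one_domain(domain_offset, -50))
  tab$serial <- seq_len(nrow(tab))
  md_traj(atoms_table(tab), matrix(as.numeric(t(coords_matrix(tab))),
                                   nrow = 1L))
}

#' Self-check: do the packaged fixtures classify as planted, with margin?
#'
#' Builds every state at zero noise, featurizes and classifies it, and
#' reports the planted label, the recovered label and the tightest margin
#' (in Angstrom) among the distance criteria that define the state.
#'
#' @return data.frame (state, label, ok, min_margin)
#' @export
fixture_selfcheck <- function() {
  t <- default_thresholds()
  rows <- lapply(fixture_states(), function(st) {
    fx <- build_fixture(st, n_frames = 1L, noise_sigma = 0)
    ft <- featurize_site(fx$traj, 1L, fx$pocket)
    label <- classify_state(ft)
    expected <- if (st == "REACTIVE_ATP") "ATP_LIKE" else st
    margins <- switch(st,
      ADP_PI_A = c(t$r_arg - ft$d2, t$r_K - ft$d_K251_Pi),
      ADP_PI_B = c(t$r_arg - ft$d1, ft$d2 - t$r_arg,
                   ft$d_K251_Pi - t$r_K),
      ATP_LIKE = ,
      REACTIVE_ATP = t$bond_PgPb - ft$d_Pgamma_Pbeta,
      numeric(0))
    data.frame(state = st, label = label, ok = label == expected,
               min_margin = if (length(margins) > 0L) min(margins)
                            else NA_real_)
  })
  do.call(rbind, rows)
}
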