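#' Simplified interaction-energy decomposition
#'
#' Single-trajectory Coulomb (optionally Debye-screened, optionally with a
#' small built-in 12-6 Lennard-Jones term) cross-interaction energies
#' between a ligand (the leaving inorganic phosphate) and a receptor
#' (protein + ADP + Mg2+), decomposed per receptor entity. Identical
#' coordinates are used for complex, receptor and ligand (no relaxation),
#' so every term is purely a cross term. Negative = stabilizing. This is a
#' deliberately transparent stand-in for end-state PB methods: relative
#' orderings are its contract, never absolute binding free energies.
#'
#' @name energetics
NULL

# Coulomb constant in kcal*A/(mol*e^2)
COULOMB_K <- 332.0636

#' Assign formal charges to a topology
#'
#' `mode = "formal"` places net formal charges on declared atoms:
#' Arg +1 (CZ), Lys +1 (NZ), Asp -1 (CG), Glu -1 (CD), Mg +2, Na/K +1,
#' inorganic phosphate (HPO4 2-) -2 spread over its P and O atoms, ADP -3
#' and ATP -4 spread over their phosphate oxygens. `mode = "sidecar"` keeps
#' charges already present in the topology (see [apply_charge_sidecar()]);
#' atoms with sidecar values override the formal assignment.
#'
#' @param traj an [md_traj()]
#' @param mode `"formal"` or `"sidecar"`
#' @return numeric vector of per-atom charges (e)
#' @export
assign_charges <- function(traj, mode = c("formal", "sidecar")) {
  mode <- match.arg(mode)
  a <- traj$atoms
  q <- numeric(nrow(a))
  put <- function(sel, charge) {
    if (any(sel)) q[sel] <<- charge
  }
  put(a$resname == "ARG" & a$name == "CZ", 1)
  put(a$resname == "LYS" & a$name == "NZ", 1)
  put(a$resname == "ASP" & a$name == "CG", -1)
  put(a$resname == "GLU" & a$name == "CD", -1)
  put(a$resname == "MG", 2)
  put(a$resname %in% c("NA", "K"), 1)
  for (rn in c("PO4", "PI")) {
    sel <- a$resname == rn
    if (any(sel)) {
      for (res in unique(paste(a$chain[sel], a$resid[sel]))) {
        here <- sel & paste(a$chain, a$resid) == res
        q[here] <- -2 / sum(here)
      }
    }
  }
  for (nuc in c("ADP", "ATP")) {
    sel <- a$resname == nuc & grepl("^O[0-9][ABG]$", a$name)
    if (any(sel)) q[sel] <- (if (nuc == "ADP") -3 else -4) / sum(sel)
  }
  if (mode == "sidecar") {
    side <- !is.na(a$charge)
    q[side] <- a$charge[side]
  }
  q
}

# minimal 12-6 LJ parameters by element (epsilon kcal/mol, rmin/2 A)
lj_table <- function() {
  data.frame(element = c("C", "N", "O", "P", "S", "H", "MG", "NA", "K"),
             eps = c(0.086, 0.17, 0.21, 0.20, 0.25, 0.015,
                     0.015, 0.087, 0.17),
             rmin2 = c(1.908, 1.824, 1.661, 2.10, 2.00, 0.60,
                       0.787, 1.369, 1.705))
}

lj_params <- function(elements) {
  tab <- lj_table()
  m <- match(toupper(elements), tab$element)
  m[is.na(m)] <- match("C", tab$element)  # generic fallback
  list(eps = tab$eps[m], rmin2 = tab$rmin2[m])
}

entity_of <- function(atoms) {
  ifelse(atoms$resname %in% c("MG", "NA", "K", "ADP", "ATP", "PO4", "PI"),
         atoms$resname,
         paste0(atoms$chain, ":", atoms$resname, atoms$resid))
}

#' Ligand-receptor interaction energy of one frame, per receptor entity
#'
#' Coulomb term per (ligand atom a, receptor atom b) pair:
#' `332.0636 * qa * qb / (eps * r) * exp(-r / lambda_D)`; screening is off
#' at `lambda_D = Inf`. The optional 12-6 LJ term uses a small built-in
#' element table with Lorentz-Berthelot mixing. Terms are aggregated by
#' receptor entity (protein residue, MG, ADP, ...).
#'
#' @param traj an [md_traj()]
#' @param frame_idx frame index
#' @param ligand,receptor disjoint integer atom index sets
#' @param charges per-atom charge vector (see [assign_charges()])
#' @param eps relative dielectric constant (default 1)
#' @param lambda_D Debye screening length in Angstrom (default `Inf`; see
#'   [debye_length()])
#' @param lj logical, add the Lennard-Jones term (default FALSE)
#' @return data.frame (entity, e_coulomb, e_lj, e_total) with one row per
#'   receptor entity; the column sums give the frame's total
#' @export
interaction_energy <- function(traj, frame_idx, ligand, receptor, charges,
                               eps = 1, lambda_D = Inf, lj = FALSE) {
  if (length(intersect(ligand, receptor)) > 0L)
    stop("ligand and receptor atom sets overlap")
  a <- traj$atoms
  formally_charged <- a$resname %in%
    c("ARG", "LYS", "ASP", "GLU", "MG", "NA", "K", "ADP", "ATP", "PO4", "PI")
  bad <- union(ligand, receptor)
  bad <- bad[formally_charged[bad] & is.na(charges[bad])]
  if (length(bad) > 0L)
    stop("charge model error: unassigned charge on formally charged entity: ",
         paste(unique(entity_of(a[bad, , drop = FALSE])), collapse = ", "))
  charges[is.na(charges)] <- 0
  coords <- frame_coords(traj, frame_idx)
  la <- coords[ligand, , drop = FALSE]
  ra <- coords[receptor, , drop = FALSE]
  d2 <- outer(rowSums(la^2), rowSums(ra^2), "+") - 2 * tcrossprod(la, ra)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.1))
    stop("atomic clash: ligand-receptor distance below 0.1 A")
  qq <- outer(charges[ligand], charges[receptor])
  screen <- if (is.finite(lambda_D)) exp(-r / lambda_D) else 1
  e_cou_pair <- COULOMB_K * qq / (eps * r) * screen
  e_lj_pair <- matrix(0, nrow(r), ncol(r))
  if (lj) {
    pl <- lj_params(a$element[ligand])
    pr <- lj_params(a$element[receptor])
    epsm <- sqrt(outer(pl$eps, pr$eps))
    rmin <- outer(pl$rmin2, pr$rmin2, "+")
    sr6 <- (rmin / r)^6
    e_lj_pair <- epsm * (sr6^2 - 2 * sr6)
  }
  ent <- entity_of(a[receptor, , drop = FALSE])
  e_cou <- tapply(colSums(e_cou_pair), ent, sum)
  e_ljv <- tapply(colSums(e_lj_pair), ent, sum)
  out <- data.frame(entity = names(e_cou),
                    e_coulomb = as.numeric(e_cou),
                    e_lj = as.numeric(e_ljv[names(e_cou)]),
                    e_total = as.numeric(e_cou) +
                      as.numeric(e_ljv[names(e_cou)]))
  rownames(out) <- NULL
  out
}

#' Debye screening length from ionic strength
#'
#' `lambda_D = 3.04 / sqrt(I)` Angstrom for a 1:1 electrolyte in water at
#' 298 K, with I in mol/L (150 mM gives ~7.8 A).
#'
#' @param ionic_strength mol/L (default 0.150)
#' @return screening length in Angstrom
#' @export
debye_length <- function(ionic_strength = 0.150) {
  stopifnot(ionic_strength > 0)
  3.04 / sqrt(ionic_strength)
}

#' Decompose ligand-receptor energies over a trajectory
#'
#' Per-entity mean energies with standard errors
#' (`se = sd / sqrt(n_frames)`) over sampled frames; per-entity totals sum
#' to the global total in every frame and in the mean (additivity).
#'
#' @param traj an [md_traj()]
#' @param ligand,receptor disjoint atom index sets
#' @param charges per-atom charge vector
#' @param stride sample every `stride`-th frame (default 1)
#' @param eps,lambda_D,lj as in [interaction_energy()]
#' @return list of class `energy_table`: `per_entity` (entity, mean
#'   e_coulomb, mean e_lj, mean e_total, se_total, n_frames; sorted by mean
#'   total, most stabilizing first), `global_total`, `global_se`, `n_frames`
#' @export
decompose_trajectory <- function(traj, ligand, receptor, charges,
                                 stride = 1L, eps = 1, lambda_D = Inf,
                                 lj = FALSE) {
  frames <- seq(1L, n_frames(traj), by = stride)
  if (length(frames) < 2L)
    stop("energy decomposition needs at least 2 sampled frames")
  per_frame <- lapply(frames, function(f)
    interaction_energy(traj, f, ligand, receptor, charges, eps, lambda_D, lj))
  entities <- per_frame[[1]]$entity
  tot <- vapply(per_frame, function(tab)
    tab$e_total[match(entities, tab$entity)], numeric(length(entities)))
  tot <- matrix(tot, nrow = length(entities))
  cou <- vapply(per_frame, function(tab)
    tab$e_coulomb[match(entities, tab$entity)], numeric(length(entities)))
  cou <- matrix(cou, nrow = length(entities))
  ljm <- vapply(per_frame, function(tab)
    tab$e_lj[match(entities, tab$entity)], numeric(length(entities)))
  ljm <- matrix(ljm, nrow = length(entities))
  n <- length(frames)
  per_entity <- data.frame(
    entity = entities,
    e_coulomb = rowMeans(cou),
    e_lj = rowMeans(ljm),
    e_total = rowMeans(tot),
    se_total = apply(tot, 1L, stats::sd) / sqrt(n),
    n_frames = n)
  per_entity <- per_entity[order(per_entity$e_total), , drop = FALSE]
  rownames(per_entity) <- NULL
  global_frames <- colSums(tot)
  structure(list(per_entity = per_entity,
                 global_total = mean(global_frames),
                 global_se = stats::sd(global_frames) / sqrt(n),
                 n_frames = n),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("<energy_table> %d entities over %d frames; total %.2f +/- %.2f kcal/mol\n",
              nrow(x$per_entity), x$n_frames, x$global_total, x$global_se))
  print(utils::head(x$per_entity, 5L))
  invisible(x)
}
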