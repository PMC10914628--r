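#' Read a (multi-MODEL) PDB file into a trajectory
#'
#' Fixed-column ATOM/HETATM parsing; MODEL/ENDMDL records delimit frames and
#' every MODEL must repeat the same topology (names, residues, chains) in
#' the same order. A file without MODEL records yields a single frame.
#' Inorganic phosphate is accepted as residue name `PO4` or `PI`, water as
#' HOH/WAT/TIP3/SPC.
#'
#' @param path PDB file path
#' @param model_policy `"all"` (default) to keep every MODEL as a frame, or
#'   `"first"` to keep only the first
#' @return an [md_traj()]
#' @export
read_pdb <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")

  frames <- list()
  cur <- integer(0)
  any_model <- any(is_model)
  for (i in seq_along(lines)) {
    if (is_model[i]) {
      cur <- integer(0)
    } else if (is_atom[i]) {
      cur <- c(cur, i)
    } else if (is_end[i]) {
      frames[[length(frames) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (!any_model) {
    frames <- list(which(is_atom))
  } else if (length(cur) > 0L) {
    frames[[length(frames) + 1L]] <- cur  # unterminated final MODEL
  }
  frames <- Filter(length, frames)
  if (length(frames) == 0L) stop("no ATOM/HETATM records in ", path)
  if (model_policy == "first") frames <- frames[1]

  nat <- lengths(frames)
  if (length(unique(nat)) != 1L)
    stop(sprintf("topology mismatch: MODELs contain %s atoms",
                 paste(unique(nat), collapse = " vs ")))

  parse_block <- function(idx) {
    ln <- lines[idx]
    serial <- suppressWarnings(as.integer(substr(ln, 7L, 11L)))
    name <- trimws(substr(ln, 13L, 16L))
    resname <- trimws(substr(ln, 18L, 20L))
    chain <- substr(ln, 22L, 22L)
    resid <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
    x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
    element <- trimws(substr(ln, 77L, 78L))
    bad <- which(is.na(serial) | is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad) > 0L)
      stop(sprintf("malformed PDB record at line %d: %s",
                   idx[bad[1]], ln[bad[1]]))
    # fall back to the first letter of the atom name if element is blank
    element <- ifelse(nzchar(element), element,
                      substr(gsub("[^A-Za-z].*$", "", name), 1L, 1L))
    list(atoms = data.frame(serial = serial, name = name, element = element,
                            resname = resname, resid = resid, chain = chain,
                            stringsAsFactors = FALSE),
         coords = cbind(x, y, z))
  }

  first <- parse_block(frames[[1]])
  xyz <- matrix(NA_real_, length(frames), 3L * nrow(first$atoms))
  xyz[1L, ] <- as.numeric(t(first$coords))
  if (length(frames) > 1L) {
    key <- function(a) paste(a$name, a$resname, a$resid, a$chain)
    ref_key <- key(first$atoms)
    for (f in seq_along(frames)[-1L]) {
      blk <- parse_block(frames[[f]])
      if (!identical(key(blk$atoms), ref_key))
        stop(sprintf("topology mismatch between MODEL 1 and MODEL %d", f))
      xyz[f, ] <- as.numeric(t(blk$coords))
    }
  }
  md_traj(first$atoms, xyz)
}

#' Write a trajectory as a (multi-MODEL) PDB file
#'
#' Single-frame trajectories are written without MODEL records; multi-frame
#' ones as MODEL/ENDMDL blocks. Nucleotides, phosphate (written as PO4),
#' Mg (MG) and waters (HOH) are emitted as HETATM, everything else as ATOM.
#' Coordinates carry the format's 3 decimal places.
#'
#' @param traj an [md_traj()]
#' @param path output file path
#' @export
write_pdb <- function(traj, path) {
  if (!inherits(traj, "md_traj") || n_atoms(traj) == 0L)
    stop("cannot write an empty trajectory")
  a <- traj$atoms
  if (any(a$resid > 9999L) || any(a$resid < -999L))
    stop("residue number not encodable in PDB fixed columns")
  if (any(nchar(a$chain) != 1L))
    stop("chain id must be a single character")
  resname <- ifelse(a$resname == "PI", "PO4", a$resname)
  het <- a$is_solvent | resname %in%
    c("PO4", "MG", "NA", "K", "ADP", "ATP", "HOH")
  record <- ifelse(het, "HETATM", "ATOM  ")
  # atom-name column convention: 1-2 char element names start in column 14
  name_fmt <- ifelse(nchar(a$name) < 4L & nchar(a$element) < 2L,
                     sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  fmt_frame <- function(coords) {
    sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, a$serial, name_fmt, resname, a$chain, a$resid,
            coords[, 1], coords[, 2], coords[, 3], 1, 0, a$element)
  }
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL %8d", f), con)
    writeLines(fmt_frame(frame_coords(traj, f)), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Attach partial charges from a sidecar table
#'
#' The sidecar is a TSV with header columns `res_name`, `atom_name`,
#' `charge` (elementary charges); every matching (residue name, atom name)
#' pair in the topology receives the charge.
#'
#' @param traj an [md_traj()]
#' @param path sidecar TSV path
#' @return trajectory with the `charge` column filled where matched
#' @export
apply_charge_sidecar <- function(traj, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("res_name", "atom_name", "charge")
  if (!all(need %in% names(tab)))
    stop("charge sidecar needs columns: ", paste(need, collapse = ", "))
  key <- paste(traj$atoms$resname, traj$atoms$name)
  m <- match(key, paste(tab$res_name, tab$atom_name))
  hit <- !is.na(m)
  traj$atoms$charge[hit] <- tab$charge[m[hit]]
  traj
}
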