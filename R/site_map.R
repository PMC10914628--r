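#' Active-site maps
#'
#' An active-site map assigns functional-residue roles to (chain, residue)
#' addresses per nucleotide-binding pocket. Pockets sit at subunit
#' interfaces: the cis subunit contributes the Walker motifs (K251, T252,
#' D304, E305), the sensor asparagine N348, the sensor-loop span 348-360
#' and the relay residues (K312, R313, K315, R349); the counterclockwise
#' neighbour (trans subunit) contributes the arginine fingers R359/R362 and
#' F360. Residue numbers default to p97 D1 numbering and can be overridden
#' per config.
#'
#' @name site_map
NULL

default_site_residues <- function() {
  list(walkerA_K = 251L, walkerA_T = 252L, walkerB_D = 304L,
       walkerB_E = 305L, sensor_N = 348L, arg_finger_R = 359L,
       arg_finger_R2 = 362L, finger_F = 360L,
       relay_K312 = 312L, relay_R313 = 313L, relay_K315 = 315L,
       relay_R349 = 349L)
}

trans_roles <- function() c("arg_finger_R", "arg_finger_R2", "finger_F")

new_pocket_spec <- function(pocket_id, cis_chain, trans_chain,
                            residues = default_site_residues(),
                            sensor_loop_span = c(348L, 360L),
                            nucleotide = NULL, mg = NULL, pi = NULL) {
  if (cis_chain == trans_chain)
    stop("cis and trans chain of a pocket must differ")
  roles <- lapply(names(residues), function(role) {
    chain <- if (role %in% trans_roles()) trans_chain else cis_chain
    list(chain = chain, resid = as.integer(residues[[role]]))
  })
  names(roles) <- names(residues)
  structure(list(pocket_id = pocket_id, cis_chain = cis_chain,
                 trans_chain = trans_chain, roles = roles,
                 sensor_loop_span = as.integer(sensor_loop_span),
                 nucleotide = nucleotide, mg = mg, pi = pi),
            class = "pocket_spec")
}

#' Load an active-site map from a JSON config
#'
#' The config declares the ring order of chains (which defines the
#' counterclockwise direction: the trans subunit of pocket i is the next
#' chain in declared order), one or more ATPase domains with residue-number
#' offsets, and optional residue-number overrides. Omitted residue numbers
#' default to p97 numbering (K251, T252, D304, E305, N348, R359, F360,
#' R362). With `"ring": false` only the single pocket (chains[1] cis,
#' chains[2] trans) is produced.
#'
#' Config keys: `chains` (array, ring order), `domains` (array of
#' `{id, residue_offset}`, default one domain at offset 0), `residues`
#' (role -> number overrides), `sensor_loop_span`, `ring` (default true),
#' `nucleotide`/`mg`/`pi` (ligand addresses, optional; resolved per pocket
#' on the cis chain).
#'
#' @param path JSON config path
#' @return object of class `site_map`: list of `pocket_spec`s
#' @export
load_site_map <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  chains <- as.character(cfg$chains)
  if (length(chains) < 2L) stop("site-map config needs at least 2 chains")
  residues <- default_site_residues()
  if (!is.null(cfg$residues)) {
    unknown <- setdiff(names(cfg$residues), names(residues))
    if (length(unknown) > 0L)
      stop("unknown role key(s) in site-map config: ",
           paste(unknown, collapse = ", "))
    residues[names(cfg$residues)] <- lapply(cfg$residues, as.integer)
  }
  span <- if (!is.null(cfg$sensor_loop_span))
    as.integer(cfg$sensor_loop_span) else c(348L, 360L)
  domains <- cfg$domains
  if (is.null(domains)) domains <- list(list(id = "D1", residue_offset = 0L))
  ring <- if (is.null(cfg$ring)) TRUE else isTRUE(cfg$ring)

  pockets <- list()
  for (dom in domains) {
    off <- as.integer(dom$residue_offset)
    res_dom <- lapply(residues, function(r) r + off)
    n <- if (ring) length(chains) else 1L
    for (i in seq_len(n)) {
      cis <- chains[i]
      trans <- chains[if (i == length(chains)) 1L else i + 1L]
      pid <- paste0(dom$id, ":", cis, "-", trans)
      lig <- function(key, default_resid) {
        if (!is.null(cfg[[key]]))
          list(chain = cis, resid = as.integer(cfg[[key]]$resid) + off,
               resname = cfg[[key]]$resname)
        else NULL
      }
      pockets[[length(pockets) + 1L]] <- new_pocket_spec(
        pid, cis, trans, res_dom, span + off,
        nucleotide = lig("nucleotide"), mg = lig("mg"), pi = lig("pi"))
    }
  }
  ids <- vapply(pockets, `[[`, character(1), "pocket_id")
  if (anyDuplicated(ids)) stop("duplicate pocket ids in site-map config")
  structure(pockets, class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("<site_map> %d pocket(s): %s\n", length(x),
              paste(vapply(x, `[[`, character(1), "pocket_id"),
                    collapse = ", ")))
  invisible(x)
}

#' Check that every residue a site map references exists in a topology
#'
#' @param map a `site_map`
#' @param traj an [md_traj()]
#' @return invisibly TRUE; errors naming the first missing residue
#' @export
validate_site_map <- function(map, traj) {
  for (p in map) {
    for (role in names(p$roles)) {
      r <- p$roles[[role]]
      if (length(atom_index(traj, r$chain, r$resid)) == 0L)
        stop(sprintf("site map references missing residue %s:%d (role %s, pocket %s)",
                     r$chain, r$resid, role, p$pocket_id))
    }
  }
  invisible(TRUE)
}
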