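#' Atom selection expressions
#'
#' A deliberately small selection grammar over the topology:
#' `chain A`, `resid 348-360` (single numbers and comma lists allowed),
#' `resname HOH`, `name CA`, `elem O`, combined with `and`, `or`, `not`
#' and parentheses. Keywords take one or more values
#' (`name CA CB` matches either). Evaluation is deterministic and may
#' return an empty set.
#'
#' @param traj an [md_traj()]
#' @param expr selection expression string
#' @return sorted integer vector of matching atom indices
#' @export
select_atoms <- function(traj, expr) {
  tokens <- tokenize_selection(expr)
  env <- new.env()
  env$tokens <- tokens
  env$pos <- 1L
  mask <- parse_or(env, traj$atoms)
  if (env$pos <= length(tokens))
    stop("selection syntax error near '", tokens[env$pos], "'")
  which(mask)
}

tokenize_selection <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  tokens <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(tokens) == 0L || !nzchar(tokens[1]))
    stop("selection syntax error: empty expression")
  tokens
}

peek <- function(env) {
  if (env$pos > length(env$tokens)) NA_character_ else env$tokens[env$pos]
}
advance <- function(env) {
  tok <- peek(env)
  env$pos <- env$pos + 1L
  tok
}

parse_or <- function(env, atoms) {
  left <- parse_and(env, atoms)
  while (!is.na(peek(env)) && peek(env) == "or") {
    advance(env)
    left <- left | parse_and(env, atoms)
  }
  left
}

parse_and <- function(env, atoms) {
  left <- parse_unary(env, atoms)
  while (!is.na(peek(env)) && peek(env) == "and") {
    advance(env)
    left <- left & parse_unary(env, atoms)
  }
  left
}

parse_unary <- function(env, atoms) {
  tok <- peek(env)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  if (tok == "not") {
    advance(env)
    return(!parse_unary(env, atoms))
  }
  if (tok == "(") {
    advance(env)
    inner <- parse_or(env, atoms)
    if (is.na(peek(env)) || peek(env) != ")")
      stop("selection syntax error: unbalanced parenthesis")
    advance(env)
    return(inner)
  }
  parse_term(env, atoms)
}

selection_keywords <- c("chain", "resid", "resname", "name", "elem")

parse_term <- function(env, atoms) {
  kw <- advance(env)
  if (!(kw %in% selection_keywords))
    stop("selection syntax error: unknown keyword '", kw, "'")
  vals <- character(0)
  while (!is.na(peek(env)) &&
         !(peek(env) %in% c(selection_keywords, "and", "or", "not", "(", ")"))) {
    vals <- c(vals, advance(env))
  }
  if (length(vals) == 0L)
    stop("selection syntax error: '", kw, "' needs a value")
  if (kw == "resid") {
    ids <- integer(0)
    for (v in unlist(strsplit(vals, ","))) {
      if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
        m <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
        ids <- c(ids, seq(as.integer(m[2]), as.integer(m[3])))
      } else if (grepl("^-?[0-9]+$", v)) {
        ids <- c(ids, as.integer(v))
      } else {
        stop("selection syntax error: bad resid token '", v, "'")
      }
    }
    return(atoms$resid %in% ids)
  }
  col <- switch(kw, chain = atoms$chain, resname = atoms$resname,
                name = atoms$name, elem = atoms$element)
  col %in% vals
}
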