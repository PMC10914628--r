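# Shared setup for the analysis scripts: output locations, seed handling
# and a provenance record written next to each script's outputs.

suppressMessages(library(adppi))

args <- commandArgs(trailingOnly = TRUE)
arg_or <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
SEED <- as.integer(arg_or("--seed", "1"))
OUT <- arg_or("--out", "results")
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

write_tsv <- function(df, name) {
  path <- file.path(OUT, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_provenance <- function(script, params = list()) {
  rec <- c(list(script = script, seed = SEED,
                package_version = as.character(utils::packageVersion("adppi")),
                thresholds = default_thresholds()),
           params)
  jsonlite::write_json(rec, file.path(OUT, paste0(script, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
}
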