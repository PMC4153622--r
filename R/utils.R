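#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All stochastic operations in the package go through this, so a
# SimulationConfig (including its seed) maps to byte-identical output.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Hash a configuration object
#'
#' MD5 hash of the canonical (deparsed) representation of an R object, used to
#' stamp every output file so that results can be traced back to the exact
#' configuration that produced them.
#'
#' @param x any R object (typically a [sim_config()] or run configuration list)
#' @return a length-1 character MD5 hex digest
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")), tf)
  unname(tools::md5sum(tf))
}

# Write a data.frame as TSV with a leading '#' comment carrying the config
# hash (and optional extra key=value metadata).
write_tsv_stamped <- function(df, path, hash = NULL, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
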