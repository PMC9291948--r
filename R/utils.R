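# Internal helpers: error formatting, deterministic RNG sub-streams.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library internals never perturb a user's stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed derived from a master seed and a small
# offset; kept below 2^31 - 1 so set.seed() always accepts it.
substream_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 2147483647) * 48271 + 1009 * offset) %% 2147483647L
}

# Atomic file write: write to a sibling temp file, then rename.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not write '%s'", path)
  invisible(path)
}

write_tsv <- function(df, path, col.names = TRUE) {
  write_atomic(function(p)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names),
    path)
}
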