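#' Derive a deterministic per-stage child seed
#'
#' A single user-facing integer seed drives every stochastic stage of the
#' pipeline. Each stage draws its own random state from a child seed derived
#' from the global seed and the stage name, so rerunning one stage in
#' isolation reproduces exactly what the full pipeline did, without manual
#' seed bookkeeping.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"genome"`, `"library:mp3k"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # simple polynomial rolling hash of the stage name, mixed with the seed;
  # all arithmetic kept in double-safe range, result reduced mod 2^31 - 1
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's random state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with a consistent prefix-free message and no call
abort <- function(...) stop(..., call. = FALSE)

# write a data.frame as plain TSV (no quotes, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, col_classes = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = col_classes, comment.char = "",
                    stringsAsFactors = FALSE)
}
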