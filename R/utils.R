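# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Printed percentages throughout the package use round-half-away-from-zero
#' at the printed precision; all threshold logic uses unrounded values.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(2.25, 1)  # 2.3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stable 31-bit string hash (independent of R internals) used to derive
# per-library RNG streams from the master seed.
stable_hash <- function(s) {
  h <- 0
  for (i in utf8ToInt(s)) h <- (h * 131 + i) %% 2147483587
  as.integer(h)
}

derive_seed <- function(master, id) {
  as.integer((as.numeric(master) %% 2147483587 * 48271 + stable_hash(id)) %% 2147483587)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Plain TSV writers/readers: all tabular interchange in this package is
# tab-separated, unquoted, with a header line.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

cot_label <- function(cot) sprintf("COT-%03d", as.integer(cot))
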