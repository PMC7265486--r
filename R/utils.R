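# Internal helpers: argument checks, seed derivation, TSV matrix I/O.

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

#' Derive independent chain seeds from a master seed
#'
#' Uses R's RNG (seeded with the master seed) to draw distinct sub-seeds,
#' all below 2^31, so independent Gibbs chains or simulation replicates are
#' reproducible yet never share a stream.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of `n` distinct seeds.
#' @export
derive_seeds <- function(master, n) {
  stop_if_not(is_count(n), "`n` must be a positive integer")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Read a labelled numeric matrix from TSV
#'
#' Expects a header row and row labels in the first column (the layout of
#' all matrices exchanged by the command-line interface).
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' Write a labelled numeric matrix to TSV
#'
#' @param x matrix with dimnames.
#' @param path destination; row labels go in the first column under an
#'   `id` header.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pearson correlation + two-sided t-distribution p-value; returns c(r, p).
pearson_with_p <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(cor(x, y))
  if (is.na(r) || n < 3L) return(c(r = if (is.na(r)) NaN else r, p = NaN))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(c(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

canonical_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
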