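`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}

# Evaluate `code` under a fixed RNG seed when one is given, restoring the
# caller's RNG state afterwards.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Row-wise min/max without matrixStats; columns of a data.frame recycle through
# pmin/pmax.
row_min <- function(m) do.call(pmin, as.data.frame(m))
row_max <- function(m) do.call(pmax, as.data.frame(m))
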