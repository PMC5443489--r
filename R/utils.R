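#' Derive a reproducible sub-stream seed
#'
#' All generators in the package consume a single integer seed and split it
#' into independent sub-streams, one per labelled draw, so that adding a new
#' draw to a generator never perturbs the existing ones. The split is a
#' small multiplicative hash of the master seed and a stream label, reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param key character label of the sub-stream (e.g. "coverage", donor id).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(key) == 1L)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# clip to [lo, hi]; used to keep simulated beta values in range
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# stop() with sprintf-style formatting, no call in the condition
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Read a tab-separated table with a header line
#'
#' Thin wrapper around [utils::read.delim()] with the defaults the package's
#' own writers use (no factors, no name munging).
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a tab-separated table with a header line
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
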