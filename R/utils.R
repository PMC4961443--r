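#' Derive a reproducible stream seed from a master seed and a label
#'
#' Deterministic integer hash used so that every pipeline stage and every
#' simulation replicate draws from its own reproducible stream while being
#' fully determined by a single top-level seed.
#'
#' @param seed master integer seed.
#' @param label character or integer stream label (e.g. replicate number or
#'   stage name).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483629
  h <- as.numeric(seed) %% m
  chars <- utf8ToInt(paste0(label, collapse = ":"))
  for (ch in chars) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 1) + 1)
}

# log(sum(exp(x))) without overflow; all-(-Inf) input gives -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
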