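#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every stochastic generator so that runs are reproducible.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Hierarchical substream scheme: every module derives its own seed from the
# root seed and a small stream index, so any stage can be regenerated alone.
# The multiplier/offset pair keeps results inside the 32-bit integer range.
child_seed <- function(root_seed, stream) {
  root_seed <- as.double(root_seed)
  as.integer((root_seed * 1009 + stream * 9973) %% 2147483629)
}

# Stops with a message naming the offending argument; all configuration
# validation funnels through here so error text is uniform.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

is_proportion <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
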