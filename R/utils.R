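# Internal helpers: validation, deterministic seed substreams.

fp_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "fnirspipe_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

fp_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) fp_stop(class, msg, ...)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a deterministic seed substream
#'
#' Maps a base seed plus a sequence of string/integer labels to a new seed in
#' `[1, 2^31 - 2]` via a rolling polynomial hash.  Used throughout the
#' simulator so that, e.g., subject 7's noise stream does not change when
#' subject counts or unrelated parameters change.
#'
#' @param seed integer base seed.
#' @param ... labels (characters or integers) naming the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483629  # prime < 2^31
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

with_substream <- function(seed, ..., expr) {
  set.seed(substream_seed(seed, ...))
  expr
}

# Evaluate `expr` with a local RNG state seeded from substream labels,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, ...) {
  s <- substream_seed(seed, ...)
  set.seed(s)
  invisible(s)
}
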