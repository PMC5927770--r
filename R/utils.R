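# Internal helpers: seeded RNG scoping and named substreams.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed
#'
#' Deterministically derives a 31-bit seed from a master seed plus any
#' number of string labels.  The scenario generator splits one master seed
#' into named substreams (per muscle, per cell, per calcium level, per sweep
#' kind), so adding a condition never perturbs the draws of another.
#'
#' @param seed Master integer seed.
#' @param ... Labels (coerced to character) naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "m6", 3, "train")
substream_seed <- function(seed, ...) {
  labels <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1, exact in doubles
  h <- 17
  for (b in utf8ToInt(labels)) {
    h <- (h * 1159 + b) %% 2147483647
  }
  as.integer(h)
}

stop_if_not <- function(cond, msg, class = "quantalr_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

is_pos <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
}

is_nonneg <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0
}
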