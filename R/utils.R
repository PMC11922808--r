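#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from user-supplied integer seeds
#' through named sub-streams (atlas placement, per-participant amplitudes,
#' voxel noise, weight initialization, per-fold training, ...). Each
#' sub-stream seed is a deterministic 31-bit hash of the parent seed and a
#' sequence of labels, so any stage can be re-run in isolation and
#' cross-validation folds are reproducible independently of execution order.
#'
#' @param seed parent integer seed.
#' @param ... labels (strings or numbers) naming the sub-stream.
#' @return an integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "atlas")
#' derive_seed(1, "fold", "sub-007")
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Cheap deterministic checksum over a named list of numeric arrays; used to
# record per-fold weight provenance (not cryptographic, just an audit tag).
weight_checksum <- function(weights) {
  acc <- 0
  for (nm in sort(names(weights))) {
    w <- as.numeric(weights[[nm]])
    if (!length(w)) next
    idx <- seq_along(w) %% 97 + 1
    acc <- acc + sum(w * idx) + length(w) * sum(utf8ToInt(nm))
  }
  signif(acc, 12)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
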