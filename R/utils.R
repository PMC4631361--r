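#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministically expands one master seed into independent sub-seeds for
#' per-run, per-voxel and per-noise random streams, so each component of a
#' simulation is reproducible on its own. The result always lies in
#' `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param ... One or more integer stream indices (e.g. run number, stage id).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1L)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed) %% m
  for (k in as.double(idx)) {
    # LCG-style mixing; constants from Numerical Recipes ranqd1
    s <- (s * 1664525 + (k + 1) * 1013904223 + 12345) %% m
  }
  as.integer(s)
}

## Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Stop with a formatted message.
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

## Short stable hash of a configuration list (hex string). Used to stamp
## outputs so artifacts from different configs are detectable. FNV-1a over
## the serialized JSON; not cryptographic.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
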