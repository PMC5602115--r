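# Counter-based derivation of per-module RNG streams from one user seed.
# Each generator draws from its own stream, so invoking one module never
# perturbs the draws of another and pipelines stay reproducible end to end.

.stream_ids <- c(
  sequence     = 101,
  object_table = 211,
  image_stack  = 307,
  spectro      = 401,
  scene        = 503,
  mixture      = 607,
  misc         = 701
)

#' Derive a substream seed from a user seed
#'
#' Maps a (seed, stream) pair to an integer in `[0, 2^31)` by one step of a
#' multiplicative congruential recurrence. Streams are identified by name
#' (one per generator) or by an arbitrary integer counter, so consumers can
#' derive as many independent substreams as they need from a single seed.
#'
#' @param seed Single non-negative integer-valued seed.
#' @param stream Stream name (one of `names(probefish:::.stream_ids)`) or an
#'   integer counter.
#' @return An integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream = "misc") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  id <- if (is.character(stream)) {
    if (!stream %in% names(.stream_ids)) stop("unknown stream: ", stream)
    .stream_ids[[stream]]
  } else {
    abs(as.numeric(stream)) %% 2147483647
  }
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 48271 + id) %% 2147483647)
}

# Evaluate `code` under the derived stream seed, restoring the caller's RNG
# state afterwards so generators are side-effect free.
with_stream <- function(seed, stream, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

# round() halves away from zero (round() in R rounds half to even)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))
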