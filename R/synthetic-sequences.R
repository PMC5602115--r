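#' Generate a random target nucleotide sequence
#'
#' Draws an i.i.d. sequence over \{A, C, G, T\} with a prescribed expected
#' GC fraction, used as a stand-in transcript for probe-design runs.
#'
#' @param length Number of nucleotides (non-negative integer).
#' @param gc_target Expected GC fraction in `[0, 1]`; G and C (and A and T)
#'   are drawn with equal probability within their class.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A single character string of `length` nucleotides (possibly `""`).
#' @examples
#' gen_target_sequence(30, gc_target = 0.5, seed = 1)
#' @export
gen_target_sequence <- function(length, gc_target = 0.5, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 0 || length != round(length)) {
    stop("`length` must be a single non-negative integer")
  }
  if (!is.numeric(gc_target) || gc_target < 0 || gc_target > 1) {
    stop("`gc_target` must lie in [0, 1]")
  }
  if (length == 0) return("")
  with_stream(seed, "sequence", {
    bases <- sample(
      c("A", "C", "G", "T"), size = length, replace = TRUE,
      prob = c((1 - gc_target) / 2, gc_target / 2,
               gc_target / 2, (1 - gc_target) / 2)
    )
    paste(bases, collapse = "")
  })
}
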