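#' Specification of a synthetic smFISH object population
#'
#' Describes the generative model for a table of detected smFISH objects in
#' an expressing compartment (nurse cells) plus a sparse false-positive
#' population in a non-expressing compartment (follicle cells):
#'
#' * an object carries `k` mRNA copies with probability `weights[k]`;
#' * its reference-channel intensity is Normal(`k * mu1`, `sqrt(k) * sigma1`),
#'   clamped at zero (photon counts cannot be negative);
#' * its target-channel intensity is `beta * reference` when a per-object
#'   Bernoulli(`p_codetect`) detection event fires, plus additive
#'   measurement noise of standard deviation `tgt_noise_sd`, clamped at
#'   zero;
#' * the non-expressing compartment holds `round(n_expressing / fp_fold)`
#'   objects (half away from zero) drawn from the single-copy component.
#'
#' @param n_expressing Number of objects in the expressing compartment.
#' @param weights Copy-number class probabilities `w_k`, `k = 1..K`;
#'   non-negative, summing to 1 within 1e-9. Default `c(0.7, 0.3)`: mostly
#'   single-mRNA particles with a minority of two-copy particles, the
#'   regime described for *oskar* RNPs in nurse cells.
#' @param mu1 Mean single-copy reference intensity (photons), > 0.
#' @param sigma1 SD of the single-copy reference intensity (photons), > 0.
#' @param beta Target/reference brightness ratio (> 0).
#' @param p_codetect Per-object probability that the target channel detects
#'   the object, in `[0, 1]`.
#' @param fp_fold Ratio of expressing to non-expressing object density
#'   (>= 1); the reciprocal is the simulated false-positive rate.
#' @param tgt_noise_sd SD of additive target-channel measurement noise
#'   (photons). Defaults to `0.05 * mu1`, small relative to a single-copy
#'   signal; set to 0 for a noise-free limit.
#' @param seed Integer seed.
#' @return An object of class `object_table_spec`.
#' @seealso [gen_object_table()]
#' @export
object_table_spec <- function(n_expressing, weights = c(0.7, 0.3),
                              mu1 = 100, sigma1 = 15, beta = 0.8,
                              p_codetect = 0.91, fp_fold = 20,
                              tgt_noise_sd = 0.05 * mu1, seed = 1L) {
  stopifnot(is.numeric(n_expressing), length(n_expressing) == 1L,
            n_expressing >= 0, n_expressing == round(n_expressing))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be non-negative and sum to 1 within 1e-9")
  }
  if (mu1 <= 0) stop("`mu1` must be > 0")
  if (sigma1 <= 0) stop("`sigma1` must be > 0")
  if (beta <= 0) stop("`beta` must be > 0")
  if (p_codetect < 0 || p_codetect > 1) stop("`p_codetect` must lie in [0, 1]")
  if (fp_fold < 1) stop("`fp_fold` must be >= 1")
  if (tgt_noise_sd < 0) stop("`tgt_noise_sd` must be >= 0")
  structure(
    list(n_expressing = as.integer(n_expressing), weights = weights,
         mu1 = mu1, sigma1 = sigma1, beta = beta, p_codetect = p_codetect,
         fp_fold = fp_fold, tgt_noise_sd = tgt_noise_sd,
         seed = as.integer(seed)),
    class = "object_table_spec"
  )
}

#' Generate a synthetic smFISH object table with ground truth
#'
#' Draws a table of smFISH objects under the generative model described in
#' [object_table_spec()]. Per-object ground truth (`copy_number`, the
#' Bernoulli target-channel `detected` event) is recorded alongside the
#' measured quantities, so downstream estimators (mixture fits, codetection
#' rates, FPDR) can be validated against truth.
#'
#' Object centroids are placed uniformly in a nominal `64 x 64 x 32` voxel
#' volume and slice depths drawn from 3..6; these are plumbing for the TSV
#' schema shared with the image-based detector and carry no signal.
#'
#' @param spec An [object_table_spec()].
#' @return A `data.frame` of class `smfish_objects` with columns
#'   `object_id`, `region` (`expressing` / `nonexpressing`), `x`, `y`, `z`,
#'   `n_slices`, `ref_intensity`, `tgt_intensity`, and truth columns
#'   `copy_number`, `detected`. The generating seed is kept in
#'   `attr(, "seed")`.
#' @examples
#' tab <- gen_object_table(object_table_spec(500, seed = 7))
#' table(tab$region)
#' @export
gen_object_table <- function(spec) {
  stopifnot(inherits(spec, "object_table_spec"))
  with_stream(spec$seed, "object_table", {
    n <- spec$n_expressing
    k <- sample.int(length(spec$weights), n, replace = TRUE,
                    prob = spec$weights)
    ref <- pmax(0, rnorm(n, k * spec$mu1, sqrt(k) * spec$sigma1))
    det <- runif(n) < spec$p_codetect
    tgt <- pmax(0, spec$beta * ref * det +
                     rnorm(n, 0, spec$tgt_noise_sd))

    n_fp <- round_half_away(n / spec$fp_fold)
    ref_fp <- pmax(0, rnorm(n_fp, spec$mu1, spec$sigma1))
    det_fp <- runif(n_fp) < spec$p_codetect
    tgt_fp <- pmax(0, spec$beta * ref_fp * det_fp +
                        rnorm(n_fp, 0, spec$tgt_noise_sd))

    n_all <- n + n_fp
    out <- data.frame(
      object_id = seq_len(n_all),
      region = rep(c("expressing", "nonexpressing"), c(n, n_fp)),
      x = runif(n_all, 0, 64),
      y = runif(n_all, 0, 64),
      z = runif(n_all, 0, 32),
      n_slices = sample(3:6, n_all, replace = TRUE),
      ref_intensity = c(ref, ref_fp),
      tgt_intensity = c(tgt, tgt_fp),
      copy_number = c(k, rep(1L, n_fp)),
      detected = c(det, det_fp),
      stringsAsFactors = FALSE
    )
    attr(out, "seed") <- spec$seed
    class(out) <- c("smfish_objects", "data.frame")
    out
  })
}
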