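# Two-channel codetection statistics: reference detection threshold,
# target/reference regression slope on the non-single population, derived
# target threshold, and the fraction of single-mRNA objects codetected in
# the target channel.

#' Two-channel single-molecule codetection rate
#'
#' Quantifies how reliably a second probe set (target channel) detects the
#' mRNAs found by a reference probe set:
#'
#' 1. The reference detection threshold is the `ref_percentile`-th
#'    percentile (default 0.1th) of all objects' reference intensities,
#'    computed by linear interpolation of order statistics.
#' 2. Objects below the single-molecule gate (`mu_1 + 2 sigma_1` of the
#'    fitted mixture, see [single_gate()]) are the single-mRNA population;
#'    the rest are the non-single fraction.
#' 3. A zero-intercept least-squares line of target on reference intensity
#'    is fitted to the non-single fraction; its slope times the reference
#'    threshold gives the target-channel detection threshold. The fit
#'    quality is reported as the squared Pearson correlation between the
#'    two channels over the fitted objects.
#' 4. The codetection rate is the percentage of single-mRNA objects whose
#'    target intensity reaches the target threshold; its complement is
#'    the fraction of single mRNAs that would be missed in the target
#'    channel.
#'
#' @param objects An `smfish_objects` `data.frame` with `ref_intensity`
#'   and `tgt_intensity` columns.
#' @param model A [fit_mixture()] result for the reference intensities.
#' @param ref_percentile Percentile (in percent) of the reference
#'   intensity distribution defining the reference detection threshold;
#'   default 0.1.
#' @return An object of class `codetection_result`: `n_objects`,
#'   `n_single`, `single_gate`, `ref_threshold`, `slope`, `r_squared`,
#'   `tgt_threshold`, `codetect_rate_pct`, `fail_rate_pct`.
#' @examples
#' tab <- gen_object_table(object_table_spec(2000, seed = 13))
#' fit <- fit_mixture(tab$ref_intensity, k_max = 3, constrained = TRUE)
#' codetect(tab, fit)
#' @export
codetect <- function(objects, model, ref_percentile = 0.1) {
  stopifnot(is.data.frame(objects),
            all(c("ref_intensity", "tgt_intensity") %in% names(objects)),
            inherits(model, "mixture_model"),
            ref_percentile > 0, ref_percentile < 100)
  ref <- objects$ref_intensity
  tgt <- objects$tgt_intensity
  gate <- single_gate(model)
  is_single <- ref < gate
  n_single <- sum(is_single)
  if (n_single < 10) {
    stop("fewer than 10 objects below the single-molecule gate")
  }
  if (sum(!is_single) < 2) {
    stop("fewer than 2 objects above the single-molecule gate; ",
         "cannot fit the target/reference slope")
  }
  ref_threshold <- quantile(ref, ref_percentile / 100, names = FALSE,
                            type = 7)
  xs <- ref[!is_single]
  ys <- tgt[!is_single]
  slope <- sum(xs * ys) / sum(xs^2)
  if (slope <= 0) {
    stop("target/reference slope is non-positive; the channels are ",
         "uncorrelated or anti-correlated and no detection threshold ",
         "can be derived")
  }
  r_squared <- if (sd(xs) == 0 || sd(ys) == 0) NA_real_ else cor(xs, ys)^2
  tgt_threshold <- slope * ref_threshold
  codetect_rate_pct <- 100 * mean(tgt[is_single] >= tgt_threshold)
  structure(list(n_objects = length(ref), n_single = n_single,
                 single_gate = gate, ref_threshold = ref_threshold,
                 slope = slope, r_squared = r_squared,
                 tgt_threshold = tgt_threshold,
                 codetect_rate_pct = codetect_rate_pct,
                 fail_rate_pct = 100 - codetect_rate_pct),
            class = "codetection_result")
}

#' @export
print.codetection_result <- function(x, ...) {
  cat(sprintf("Codetection: %d objects, %d single-mRNA (gate %.1f)\n",
              x$n_objects, x$n_single, x$single_gate))
  cat(sprintf("  ref threshold %.2f, slope %.3f (r^2 = %.3f) => %s %.2f\n",
              x$ref_threshold, x$slope, x$r_squared,
              "target threshold", x$tgt_threshold))
  cat(sprintf("  codetection rate: %.1f%% (%.1f%% of single mRNAs %s)\n",
              x$codetect_rate_pct, x$fail_rate_pct,
              "would be missed in the target channel"))
  invisible(x)
}

#' Expected target-channel signal and per-object fold difference
#'
#' The expected target signal of an object is the regression slope times
#' its reference intensity; the fold difference `observed / expected`
#' summarizes, per object, how far the target channel deviates from the
#' two-channel proportionality (the quantity usually driving the color
#' scale of codetection scatter plots).
#'
#' @param objects An `smfish_objects` `data.frame`.
#' @param slope Target/reference regression slope (> 0), typically
#'   `codetect(...)$slope`.
#' @return `objects` with added columns `expected_tgt` and `fold`
#'   (`NA` where the expected signal is 0).
#' @export
expected_target <- function(objects, slope) {
  stopifnot(is.data.frame(objects), is.numeric(slope), slope > 0)
  expected <- slope * objects$ref_intensity
  fold <- ifelse(expected > 0, objects$tgt_intensity / expected, NA_real_)
  objects$expected_tgt <- expected
  objects$fold <- fold
  objects
}

#' Write a JSON + TSV codetection report
#'
#' Writes a JSON summary (mixture parameters, gate, thresholds, slope,
#' codetection rate) and a per-object TSV with `expected_tgt` and `fold`
#' columns.
#'
#' @param objects An `smfish_objects` `data.frame`.
#' @param model A [fit_mixture()] result.
#' @param result A [codetect()] result.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return The JSON summary, invisibly.
#' @export
codetect_report <- function(objects, model, result, json_path = NULL,
                            tsv_path = NULL) {
  summary <- list(
    K = model$K, weights = model$weights, means = model$means,
    sds = model$sds, single_gate = result$single_gate,
    ref_threshold = result$ref_threshold, slope = result$slope,
    r_squared = result$r_squared, tgt_threshold = result$tgt_threshold,
    codetect_rate_pct = result$codetect_rate_pct,
    n_single = result$n_single, n_objects = result$n_objects
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    annotated <- expected_target(objects, result$slope)
    write.table(annotated, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(summary)
}
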