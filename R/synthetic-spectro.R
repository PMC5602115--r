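#' Simulate a UV-Vis absorbance reading of a labeled oligo pool
#'
#' Inverts the spectroscopic degree-of-labeling arithmetic: given a true
#' molar concentration and DOL, produces the absorbances a 1-cm path
#' spectrophotometer would report,
#' \deqn{OD_{dye} = DOL \cdot c \cdot \varepsilon_{dye}, \qquad
#'       OD_{260} = c \cdot \varepsilon_{oligo} + cf_{260} \cdot OD_{dye},}
#' where \eqn{\varepsilon_{oligo}} is the pool extinction coefficient
#' (mean per-oligo value plus the ddU increment, see [pool_epsilon()]) and
#' \eqn{cf_{260}} the dye's relative absorbance at 260 nm. With
#' `noise_sd = 0` the reading is exact and [estimate_dol()] recovers
#' `(c_true, dol_true)` to machine precision.
#'
#' @param c_true True oligo concentration (mol/L, > 0).
#' @param dol_true True degree of labeling (>= 0; may exceed 1).
#' @param pool An [oligo_pool_spec()].
#' @param dye A [dye_spec()].
#' @param noise_sd SD of additive Gaussian noise applied to both
#'   absorbances (default 0); readings are clamped at 0.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A [spectro_read()].
#' @export
gen_spectro_read <- function(c_true, dol_true, pool, dye, noise_sd = 0,
                             seed = 1L) {
  stopifnot(c_true > 0, dol_true >= 0, noise_sd >= 0)
  od_dye <- dol_true * c_true * dye$eps_dye
  od260 <- c_true * pool_epsilon(pool) + dye$cf260 * od_dye
  if (noise_sd > 0) {
    with_stream(seed, "spectro", {
      od260 <- max(0, od260 + rnorm(1, 0, noise_sd))
      od_dye <- max(0, od_dye + rnorm(1, 0, noise_sd))
    })
  }
  spectro_read(od260, od_dye)
}
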