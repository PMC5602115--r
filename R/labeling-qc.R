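#' Dye spectral properties
#'
#' @param eps_dye Molar extinction coefficient at the dye absorption
#'   maximum (L mol^-1 cm^-1, > 0).
#' @param cf260 Relative absorbance of the dye at 260 nm (dimensionless,
#'   in `[0, 1)`); the dye's contribution to OD260 is `cf260 * OD_dye`.
#' @return An object of class `dye_spec`.
#' @examples
#' atto633 <- dye_spec(eps_dye = 130000, cf260 = 0.05)
#' @export
dye_spec <- function(eps_dye, cf260) {
  stopifnot(is.numeric(eps_dye), eps_dye > 0,
            is.numeric(cf260), cf260 >= 0, cf260 < 1)
  structure(list(eps_dye = eps_dye, cf260 = cf260), class = "dye_spec")
}

#' Labeled oligonucleotide pool
#'
#' @param epsilons Per-oligo extinction coefficients at 260 nm
#'   (L mol^-1 cm^-1, all > 0).
#' @param n_initial_pmol Starting amount of unlabeled oligo (pmol, >= 0).
#' @param volume_l Reconstituted volume after purification (L, > 0).
#' @return An object of class `oligo_pool_spec`.
#' @export
oligo_pool_spec <- function(epsilons, n_initial_pmol = 1000,
                            volume_l = 50e-6) {
  if (length(epsilons) < 1) stop("at least one oligo epsilon is required")
  stopifnot(all(epsilons > 0), n_initial_pmol >= 0, volume_l > 0)
  structure(list(epsilons = as.numeric(epsilons),
                 n_initial_pmol = n_initial_pmol, volume_l = volume_l),
            class = "oligo_pool_spec")
}

#' A UV-Vis absorbance reading (1-cm path)
#'
#' @param od260 Absorbance at 260 nm (>= 0).
#' @param od_dye Absorbance at the dye absorption maximum (>= 0).
#' @return An object of class `spectro_read`.
#' @export
spectro_read <- function(od260, od_dye) {
  stopifnot(od260 >= 0, od_dye >= 0)
  structure(list(od260 = od260, od_dye = od_dye), class = "spectro_read")
}

#' Extinction coefficient of a labeled oligo pool
#'
#' The pool coefficient is the arithmetic mean of the per-oligo extinction
#' coefficients at 260 nm plus 9000 L mol^-1 cm^-1 for the single
#' incorporated ddU terminator.
#'
#' @param pool An [oligo_pool_spec()].
#' @return Extinction coefficient in L mol^-1 cm^-1.
#' @examples
#' pool_epsilon(oligo_pool_spec(200000))          # 209000
#' pool_epsilon(oligo_pool_spec(c(1e5, 3e5)))     # 209000
#' @export
pool_epsilon <- function(pool) {
  stopifnot(inherits(pool, "oligo_pool_spec"))
  mean(pool$epsilons) + 9000
}

#' Concentration, DOL and recovery from a UV-Vis reading
#'
#' Implements the spectroscopic labeling arithmetic for a singly
#' end-labeled oligo pool:
#' \deqn{c = \frac{OD_{260} - cf_{260} \cdot OD_{dye}}{\varepsilon_{oligo}},
#'   \qquad DOL = \frac{OD_{dye}}{\varepsilon_{dye} \cdot c}, \qquad
#'   Recovery\% = 100 \cdot \frac{c \cdot V}{n_{initial}}.}
#'
#' DOL is not clamped: values slightly above 1 occur in practice
#' (spectroscopy tends to overestimate relative to gel densitometry), but
#' values above 1.2 trigger a warning as a plausibility check.
#'
#' @param read A [spectro_read()].
#' @param dye A [dye_spec()].
#' @param pool An [oligo_pool_spec()] (supplies the pool extinction
#'   coefficient, the starting amount and the reconstituted volume).
#' @return An object of class `dol_estimate`: a list with `c` (mol/L),
#'   `dol` (fraction) and `recovery_pct` (percent of starting material).
#' @examples
#' pool <- oligo_pool_spec(200000, n_initial_pmol = 1000, volume_l = 50e-6)
#' dye <- dye_spec(130000, 0.05)
#' estimate_dol(gen_spectro_read(2e-6, 0.93, pool, dye), dye, pool)
#' @export
estimate_dol <- function(read, dye, pool) {
  stopifnot(inherits(read, "spectro_read"), inherits(dye, "dye_spec"),
            inherits(pool, "oligo_pool_spec"))
  eps_oligo <- pool_epsilon(pool)
  c_molar <- (read$od260 - dye$cf260 * read$od_dye) / eps_oligo
  if (c_molar <= 0) {
    stop("degenerate reading: dye absorbance dominates OD260, ",
         "estimated concentration <= 0; DOL is undefined")
  }
  dol <- if (read$od_dye == 0) 0 else read$od_dye / (dye$eps_dye * c_molar)
  if (dol > 1.2) {
    warning(sprintf("DOL estimate %.3f exceeds 1.2; check extinction %s",
                    dol, "coefficients and the dye correction factor"))
  }
  n_pmol <- c_molar * pool$volume_l * 1e12
  recovery_pct <- if (pool$n_initial_pmol > 0) {
    100 * n_pmol / pool$n_initial_pmol
  } else {
    NA_real_
  }
  structure(list(c = c_molar, dol = dol, recovery_pct = recovery_pct),
            class = "dol_estimate")
}

#' @export
print.dol_estimate <- function(x, ...) {
  cat(sprintf("DOL estimate: c = %.4g mol/L, DOL = %.3f, recovery = %s\n",
              x$c, x$dol,
              if (is.na(x$recovery_pct)) "NA"
              else sprintf("%.1f%%", x$recovery_pct)))
  invisible(x)
}

#' Degree of labeling from denaturing PAGE densitometry
#'
#' The unlabeled oligo migrates faster than the labeled product; comparing
#' the unlabeled band to a standard series gives `n_unlabeled`, and
#' `DOL = 1 - n_unlabeled / n_loaded`.
#'
#' @param n_unlabeled Amount of unlabeled band (pmol, `0 <= n_unlabeled <=
#'   n_loaded`).
#' @param n_loaded Amount loaded on the lane (pmol, > 0).
#' @return DOL in `[0, 1]`.
#' @examples
#' gel_dol(4.8, 96)  # 0.95
#' @export
gel_dol <- function(n_unlabeled, n_loaded) {
  if (!is.numeric(n_loaded) || n_loaded <= 0) stop("`n_loaded` must be > 0")
  if (n_unlabeled < 0 || n_unlabeled > n_loaded) {
    stop("`n_unlabeled` must lie in [0, n_loaded]")
  }
  1 - n_unlabeled / n_loaded
}

#' Biotin degree of labeling from the HABA/avidin assay
#'
#' Biotin displaces the HABA dye from avidin, and the resulting absorbance
#' loss at 500 nm is proportional to the amount of biotin:
#' `n_biotin = delta_a500 * volume / eps_haba`. The returned DOL is the
#' biotin/oligonucleotide molar ratio.
#'
#' @param delta_a500 Absorbance decrease at 500 nm (>= 0, 1-cm path).
#' @param volume_l Assay volume (L, > 0).
#' @param n_oligo_mol Amount of oligonucleotide assayed (mol, > 0).
#' @param eps_haba Extinction coefficient of the HABA-avidin complex at
#'   500 nm; default 34000 L mol^-1 cm^-1, the standard assay value.
#' @return Biotin per oligo (dimensionless; ~1 for complete labeling).
#' @export
haba_dol <- function(delta_a500, volume_l, n_oligo_mol, eps_haba = 34000) {
  stopifnot(delta_a500 >= 0, volume_l > 0, eps_haba > 0)
  if (!is.numeric(n_oligo_mol) || n_oligo_mol <= 0) {
    stop("`n_oligo_mol` must be > 0")
  }
  (delta_a500 * volume_l / eps_haba) / n_oligo_mol
}

#' Zero-intercept regression of spectroscopic on densitometric DOL
#'
#' Compares the two DOL modalities over a panel of probe sets by least
#' squares through the origin (`y = slope * x` with `x` densitometric and
#' `y` spectroscopic DOL). The goodness of fit is the no-intercept
#' coefficient of determination `1 - RSS / sum(y^2)` (conventions for R^2
#' without an intercept differ; this is the definition used by `lm(y ~ 0 +
#' x)` summaries). The per-pair ratio `y / x` is summarized as mean and SD.
#'
#' @param densitometric DOL values from PAGE densitometry (all > 0).
#' @param spectroscopic DOL values from UV-Vis, same length.
#' @return A list with `slope`, `r_squared`, `ratio_mean`, `ratio_sd`, `n`.
#' @examples
#' dol_regression(c(0.9, 0.95, 1.0), 1.05 * c(0.9, 0.95, 1.0))$slope  # 1.05
#' @export
dol_regression <- function(densitometric, spectroscopic) {
  x <- as.numeric(densitometric)
  y <- as.numeric(spectroscopic)
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 2) stop("at least two pairs are required")
  if (all(x == 0)) stop("all densitometric values are zero")
  if (any(x <= 0)) stop("densitometric DOL values must be > 0")
  slope <- sum(x * y) / sum(x^2)
  rss <- sum((y - slope * x)^2)
  ratio <- y / x
  list(slope = slope,
       r_squared = 1 - rss / sum(y^2),
       ratio_mean = mean(ratio),
       ratio_sd = sd(ratio),
       n = length(x))
}

#' Number of smFISH experiments supported by one labeling reaction
#'
#' A hybridization uses `n_probes * conc_per_probe * volume` moles of
#' labeled oligo; after purification losses, a synthesis of `n_initial`
#' pmol supports
#' `floor(n_initial * (1 - loss_fraction) / per-experiment demand)`
#' experiments. At the standard scale (1000 pmol, 30 probes, 2.5 nM/probe,
#' 100 uL, 22% loss) this is ~100 experiments.
#'
#' @param n_initial_pmol Synthesis scale (pmol of pooled oligo, >= 0).
#' @param n_probes Number of distinct probes in the set (> 0).
#' @param conc_per_probe Final per-probe hybridization concentration
#'   (mol/L, > 0).
#' @param volume_l Hybridization volume (L, > 0).
#' @param loss_fraction Purification loss as a fraction in `[0, 1)`;
#'   default 0.22, a typical ethanol-precipitation loss.
#' @return Integer number of experiments.
#' @examples
#' plan_experiments(1000, 30, 2.5e-9, 100e-6, 0.22)  # 104
#' @export
plan_experiments <- function(n_initial_pmol, n_probes, conc_per_probe,
                             volume_l, loss_fraction = 0.22) {
  stopifnot(n_initial_pmol >= 0, loss_fraction >= 0, loss_fraction < 1)
  if (n_probes <= 0 || conc_per_probe <= 0 || volume_l <= 0) {
    stop("n_probes, conc_per_probe and volume_l must all be > 0")
  }
  per_exp_pmol <- n_probes * conc_per_probe * volume_l * 1e12
  as.integer(floor(n_initial_pmol * (1 - loss_fraction) / per_exp_pmol))
}
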