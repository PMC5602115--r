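# Unified nearest-neighbor thermodynamic parameters for DNA/DNA duplexes
# (SantaLucia 1998 unified set). dh in kcal/mol, ds in cal/(mol K),
# keyed by the 5'->3' dimer on one strand; a dimer and its reverse
# complement share parameters.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation per terminal base pair
.init_dh <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.init_ds <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

.gas_constant <- 1.9872  # cal/(mol K)

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_acgt <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, chars[bad[1]], bad[1]))
  }
  invisible(chars)
}

#' Nearest-neighbor DNA duplex melting temperature
#'
#' Tm of a perfectly matched DNA/DNA duplex under the unified
#' nearest-neighbor thermodynamic parameter set, with the entropic
#' monovalent-salt correction `dS + 0.368 * (L - 1) * ln([Na+])` and
#' `Tm = dH / (dS + R ln(Ct / x)) - 273.15`, where `x = 4` for
#' non-self-complementary duplexes (1 if self-complementary, with the
#' usual symmetry entropy correction). Defaults (50 mM monovalent salt,
#' 250 nM total strand) describe a typical probe working solution; the
#' absolute scale matters less for design than the relative ordering used
#' to pick probes of similar Tm.
#'
#' @param sequence One DNA strand, 5'->3', ACGT only, length >= 2.
#' @param na_molar Monovalent cation concentration (mol/L, > 0).
#' @param oligo_molar Total strand concentration (mol/L, > 0).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("GGGGGGGGGGGGGGGGGG") >
#'   melting_temperature("AAAAAAAAAAAAAAAAAA")
#' @export
melting_temperature <- function(sequence, na_molar = 0.05,
                                oligo_molar = 250e-9) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            na_molar > 0, oligo_molar > 0)
  chars <- check_acgt(sequence)
  n <- length(chars)
  if (n < 2) stop("sequence must be at least 2 nt for a duplex Tm")
  dimers <- paste0(chars[-n], chars[-1])
  dh <- sum(.nn_dh[dimers]) + .init_dh[[chars[1]]] + .init_dh[[chars[n]]]
  ds <- sum(.nn_ds[dimers]) + .init_ds[[chars[1]]] + .init_ds[[chars[n]]]
  selfcomp <- identical(sequence, revcomp(sequence))
  x <- 4
  if (selfcomp) {
    ds <- ds - 1.4
    x <- 1
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  tm_k <- dh * 1000 / (ds + .gas_constant * log(oligo_molar / x))
  tm_k - 273.15
}
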