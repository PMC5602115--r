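# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# --- nearest-neighbor Tm, second implementation -------------------------
# Loop-based, parameters encoded as a two-column matrix keyed by dimer,
# unified DNA/DNA values at 1 M Na+ with the entropic salt adjustment.
oracle_tm <- function(seq, na_molar = 0.05, ct = 250e-9) {
  tab <- rbind(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9)
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  b <- strsplit(seq, "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(b) - 1)) {
    dimer <- paste0(b[i], b[i + 1])
    if (!dimer %in% rownames(tab)) dimer <- rc(dimer)
    dh <- dh + tab[dimer, 1]
    ds <- ds + tab[dimer, 2]
  }
  for (end in c(b[1], b[length(b)])) {
    if (end %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  x <- 4
  if (identical(seq, rc(seq))) {
    ds <- ds - 1.4
    x <- 1
  }
  ds <- ds + 0.368 * (length(b) - 1) * log(na_molar)
  unname(dh * 1000 / (ds + 1.9872 * log(ct / x)) - 273.15)
}

# --- maximum-cardinality tiling by dynamic programming ------------------
# Counts the optimum number of non-overlapping candidates with gap >= g,
# recursing over candidates sorted by start (memoized on candidate index).
oracle_max_tiling <- function(starts, ends, gap) {
  n <- length(starts)
  if (n == 0) return(0L)
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  memo <- rep(NA_integer_, n + 1L)
  best_from <- function(i) {
    if (i > n) return(0L)
    if (!is.na(memo[i])) return(memo[i])
    # skip candidate i
    res <- best_from(i + 1L)
    # or take it: next compatible candidate has start >= ends[i] + gap
    j <- i + 1L
    while (j <= n && starts[j] < ends[i] + gap) j <- j + 1L
    res <- max(res, 1L + best_from(j))
    memo[i] <<- res
    res
  }
  best_from(1L)
}

# --- greedy one-to-one matching of detections to planted spots ----------
match_detections <- function(objects, truth, radius = 3) {
  used <- logical(nrow(objects))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    if (nrow(objects) == 0) break
    d <- sqrt((objects$x - truth$x[i])^2 + (objects$y - truth$y[i])^2 +
                (objects$z - truth$z[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= radius) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(objects) - tp
  fn <- nrow(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       recall = tp / nrow(truth), precision = tp / max(1L, nrow(objects)),
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# integrated amplitude giving a requested peak SNR s/sqrt(s + b) for the
# package PSF defaults (sigma_xy = 1.3, sigma_z = 1.5)
amp_for_peak_snr <- function(snr, background,
                             sigma_xy = 1.3, sigma_z = 1.5) {
  g0 <- (pnorm(0.5, 0, sigma_xy) - pnorm(-0.5, 0, sigma_xy))^2 *
    (pnorm(0.5, 0, sigma_z) - pnorm(-0.5, 0, sigma_z))
  peak <- uniroot(function(p) p / sqrt(p + background) - snr,
                  c(1e-6, 1e7))$root
  peak / g0
}

gc_frac <- function(s) {
  b <- strsplit(s, "")[[1]]
  mean(b %in% c("G", "C"))
}
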