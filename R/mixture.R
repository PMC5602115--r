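# Multiple-Gaussian decomposition of smFISH object intensity distributions.
# Component k corresponds to objects carrying k mRNA copies; the first
# (lowest-mean) component defines the single-molecule intensity gate
# mu_1 + 2 sigma_1.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# one EM run; returns NULL on failure to converge
em_gaussian <- function(x, k, means0, sds0, w0, constrained, tol, max_iter,
                        var_floor) {
  n <- length(x)
  w <- w0; means <- means0; sds <- pmax(sds0, sqrt(var_floor))
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j) {
      log(w[j]) + dnorm(x, means[j], sds[j], log = TRUE)
    }, numeric(n))
    logp <- matrix(logp, nrow = n)
    lse <- logsumexp_rows(logp)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(logp - lse)
    if (constrained) {
      # component k has mean k*mu1 and variance k*sigma1^2; closed-form
      # M-step: mu1 = sum(x) / sum_ik r_ik k (rows of r sum to 1)
      ks <- seq_len(k)
      mu1 <- sum(x) / sum(sweep(r, 2, ks, "*"))
      dev2 <- vapply(ks, function(j) (x - j * mu1)^2 / j, numeric(n))
      s2 <- sum(r * dev2) / n
      s2 <- max(s2, var_floor)
      w <- pmax(colMeans(r), 1e-12); w <- w / sum(w)
      means <- ks * mu1
      sds <- sqrt(ks * s2)
    } else {
      nk <- colSums(r)
      w <- pmax(nk / n, 1e-12); w <- w / sum(w)
      means <- colSums(r * x) / nk
      v <- colSums(r * outer(x, means, "-")^2) / nk
      sds <- sqrt(pmax(v, var_floor))
    }
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged && max_iter > 1) return(list(ok = FALSE, trace = ll_trace))
  ord <- order(means)
  list(ok = TRUE, weights = w[ord], means = means[ord], sds = sds[ord],
       log_likelihood = ll_trace[length(ll_trace)], trace = ll_trace,
       iters = length(ll_trace))
}

#' Fit a multiple-Gaussian model to smFISH intensities
#'
#' Fits Gaussian mixtures with `K = 1..k_max` components by
#' expectation-maximization and selects `K` by minimum BIC. In the
#' `constrained` mode the components encode the copy-number structure of
#' smFISH data directly: component `k` has mean `k * mu_1` and SD
#' `sqrt(k) * sigma_1`, leaving only `(mu_1, sigma_1)` and the weights
#' free — the model expected when each object sums the fluorescence of an
#' integer number of identically labeled mRNAs. The unconstrained mode
#' fits free means and SDs.
#'
#' EM is initialized from a K-quantile partition of the sorted data and
#' restarted `n_restarts` times with jittered initial means; component
#' variances are floored at `(1e-3 * sd(x))^2` to prevent collapse onto
#' single observations. Convergence is a relative log-likelihood change
#' below `tol`.
#'
#' @param intensities Numeric vector of object intensities (>= 50 values).
#' @param k_max Largest component count to consider (default 4).
#' @param constrained Use the copy-number-constrained parameterization?
#'   Default `FALSE`.
#' @param seed Integer seed governing the restart jitter.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per run (default 500).
#' @param n_restarts Number of jittered restarts per `K` (default 5).
#' @return An object of class `mixture_model`: `K`, `weights`, `means`
#'   (ascending), `sds`, `log_likelihood`, `bic`, `single_gate`
#'   (`mu_1 + 2 sigma_1`), `constrained`, and `bic_by_k`.
#' @examples
#' x <- c(rnorm(700, 100, 15), rnorm(300, 200, 21))
#' fit_mixture(x, k_max = 3, constrained = TRUE)
#' @export
fit_mixture <- function(intensities, k_max = 4, constrained = FALSE,
                        seed = 1L, tol = 1e-6, max_iter = 500,
                        n_restarts = 5) {
  x <- as.numeric(intensities)
  if (length(x) < 50) stop("at least 50 observations are required")
  if (any(!is.finite(x))) stop("intensities must be finite")
  if (k_max < 1) stop("`k_max` must be >= 1")
  sx <- sd(x)
  if (sx == 0) stop("degenerate input: all observations are identical")
  var_floor <- (1e-3 * sx)^2
  n <- length(x)

  fits <- with_stream(seed, "mixture", {
    lapply(seq_len(k_max), function(k) {
      # quantile-partition initialization
      grp <- ceiling(rank(x, ties.method = "first") * k / length(x))
      m0 <- vapply(seq_len(k), function(j) mean(x[grp == j]), 0)
      s0 <- vapply(seq_len(k), function(j) {
        s <- sd(x[grp == j]); if (is.na(s) || s == 0) sx / k else s
      }, 0)
      w0 <- rep(1 / k, k)
      best <- NULL
      last_trace <- NULL
      for (r in seq_len(n_restarts)) {
        mr <- if (r == 1) m0 else m0 + rnorm(k, 0, 0.2 * sx)
        if (constrained) {
          # initial mu1 from the jittered first mean
          mu1 <- max(mr[1], sx * 1e-3)
          mr <- seq_len(k) * mu1
          sr <- sqrt(seq_len(k)) * s0[1]
        } else {
          sr <- s0
        }
        fit <- em_gaussian(x, k, mr, sr, w0, constrained, tol, max_iter,
                           var_floor)
        if (!fit$ok) {
          last_trace <- fit$trace
          next
        }
        if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
          best <- fit
        }
      }
      if (is.null(best)) {
        stop("EM failed to converge for K = ", k,
             "; last log-likelihood trajectory: ",
             paste(signif(tail(last_trace, 5), 8), collapse = ", "))
      }
      best$k <- k
      best
    })
  })

  n_params <- vapply(fits, function(f) {
    if (constrained) (f$k - 1) + 2 else 3 * f$k - 1
  }, 0)
  bics <- vapply(fits, function(f) -2 * f$log_likelihood, 0) +
    n_params * log(n)
  best <- fits[[which.min(bics)]]
  structure(list(K = best$k, weights = best$weights, means = best$means,
                 sds = best$sds, log_likelihood = best$log_likelihood,
                 bic = min(bics), bic_by_k = bics,
                 constrained = constrained,
                 single_gate = best$means[1] + 2 * best$sds[1],
                 n = n),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%s), K = %d, BIC = %.1f\n",
              if (x$constrained) "copy-number constrained" else "free",
              x$K, x$bic))
  for (k in seq_len(x$K)) {
    cat(sprintf("  component %d: w = %.3f, mean = %.2f, sd = %.2f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  }
  cat(sprintf("  single-molecule gate (mu1 + 2 sigma1): %.2f\n",
              x$single_gate))
  invisible(x)
}

#' Single-molecule intensity gate
#'
#' Objects with reference intensity below `mu_1 + 2 sigma_1` of the
#' lowest-mean fitted Gaussian component are taken to contain a single
#' mRNA molecule.
#'
#' @param model A [fit_mixture()] result.
#' @return The gate threshold in photon units.
#' @examples
#' m <- structure(list(means = 100, sds = 15), class = "mixture_model")
#' single_gate(m)  # 130
#' @export
single_gate <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  model$means[1] + 2 * model$sds[1]
}
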