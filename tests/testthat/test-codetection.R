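sim_two_component <- function(n, seed) {
  # 0.7 N(100, 15) + 0.3 N(200, 21) reference intensity mixture
  set.seed(seed)
  k <- 1L + rbinom(n, 1, 0.3)
  rnorm(n, 100 * k, c(15, 21)[k])
}

test_that("BIC selects one component on single-Gaussian data", {
  set.seed(9)
  x <- rnorm(2000, 100, 15)
  fit <- fit_mixture(x, k_max = 3, seed = 9)
  expect_identical(fit$K, 1L)
  expect_equal(fit$means[1], 100, tolerance = 0.02)
})

test_that("mixture fits recover the two-component simulation", {
  x <- sim_two_component(5000, seed = 9)
  free <- fit_mixture(x, k_max = 3, seed = 9)
  expect_identical(free$K, 2L)
  expect_equal(free$means[1], 100, tolerance = 0.05)

  constr <- fit_mixture(x, k_max = 3, constrained = TRUE, seed = 9)
  expect_identical(constr$K, 2L)
  expect_equal(constr$means[1], 100, tolerance = 0.05)
  # constrained structure: means at integer multiples, sds sqrt(k)-scaled
  expect_equal(constr$means[2], 2 * constr$means[1])
  expect_equal(constr$sds[2], sqrt(2) * constr$sds[1])
  expect_equal(sum(constr$weights), 1, tolerance = 1e-9)
})

test_that("free mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  x <- sim_two_component(3000, seed = 15)
  ours <- fit_mixture(x, k_max = 2, seed = 15)
  theirs <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(theirs$parameters$mean)),
               tolerance = 0.02)
  expect_equal(ours$log_likelihood, theirs$loglik, tolerance = 1e-3)
})

test_that("degenerate intensity inputs are rejected", {
  expect_error(fit_mixture(rep(5, 100)), "identical")
  expect_error(fit_mixture(rnorm(10)), "at least 50")
})

test_that("the single-molecule gate is mu1 + 2 sigma1", {
  m <- structure(list(means = c(100, 200), sds = c(15, 21)),
                 class = "mixture_model")
  expect_equal(single_gate(m), 130)
  m0 <- structure(list(means = 100, sds = 0), class = "mixture_model")
  expect_equal(single_gate(m0), 100)

  # on the standard simulation the gate sits near mu1 + 2 sigma1 = 130
  # and captures >= 95% of true single-copy objects
  spec <- object_table_spec(5000, weights = c(0.7, 0.3), mu1 = 100,
                            sigma1 = 15, seed = 9)
  tab <- gen_object_table(spec)
  expr <- tab[tab$region == "expressing", ]
  fit <- fit_mixture(expr$ref_intensity, k_max = 3, constrained = TRUE,
                     seed = 9)
  gate <- single_gate(fit)
  expect_gt(gate, 120)
  expect_lt(gate, 140)
  singles <- expr[expr$copy_number == 1, ]
  expect_gte(mean(singles$ref_intensity < gate), 0.90)
})

test_that("codetect reproduces exact proportional limits", {
  # build a table with known structure around a fixed mixture model
  model <- structure(list(means = c(100, 200), sds = c(10, 14),
                          K = 2L, constrained = TRUE),
                     class = "mixture_model")
  set.seed(33)
  ref <- c(rnorm(500, 100, 10), rnorm(100, 200, 14))
  tab <- data.frame(ref_intensity = ref, tgt_intensity = 0.8 * ref)
  res <- codetect(tab, model)
  # every object on the fitted line: only objects whose reference value
  # falls below the interpolated 0.1th percentile (at most one of the
  # ~500 singles) can miss the derived target threshold
  expect_gte(res$codetect_rate_pct, 100 * (1 - 2 / res$n_single))
  expect_equal(res$slope, 0.8, tolerance = 1e-12)
  expect_equal(res$tgt_threshold, 0.8 * res$ref_threshold)

  # singles dark in the target channel -> zero codetection
  gate <- single_gate(model)
  tab0 <- tab
  tab0$tgt_intensity[tab0$ref_intensity < gate] <- 0
  res0 <- codetect(tab0, model)
  expect_equal(res0$codetect_rate_pct, 0)

  # a target channel with no signal gives a non-positive slope, which
  # is refused: no detection threshold can be derived from it
  tabneg <- tab
  tabneg$tgt_intensity <- 0
  expect_error(codetect(tabneg, model), "slope")
})

test_that("codetection rate recovers the simulated detection probability", {
  spec <- object_table_spec(3000, p_codetect = 0.90, beta = 0.8,
                            seed = 13)
  tab <- gen_object_table(spec)
  fit <- fit_mixture(tab$ref_intensity, k_max = 3, constrained = TRUE,
                     seed = 13)
  res <- codetect(tab, fit)
  expect_equal(res$codetect_rate_pct, 90, tolerance = 3 / 90)

  # invariant under joint positive rescaling of both channels
  tab2 <- tab
  tab2$ref_intensity <- 3.7 * tab2$ref_intensity
  tab2$tgt_intensity <- 3.7 * tab2$tgt_intensity
  fit2 <- fit_mixture(tab2$ref_intensity, k_max = 3, constrained = TRUE,
                      seed = 13)
  res2 <- codetect(tab2, fit2)
  expect_equal(res2$codetect_rate_pct, res$codetect_rate_pct,
               tolerance = 0.02)
})

test_that("shuffled channel pairing yields no linear relation", {
  spec <- object_table_spec(3000, p_codetect = 0.90, seed = 13)
  tab <- gen_object_table(spec)
  fit <- fit_mixture(tab$ref_intensity, k_max = 3, constrained = TRUE,
                     seed = 13)
  set.seed(99)
  tab$tgt_intensity <- sample(tab$tgt_intensity)
  res <- try(codetect(tab, fit), silent = TRUE)
  if (!inherits(res, "try-error")) {
    expect_lt(res$r_squared, 0.1)
  } else {
    # a non-positive slope is an equally valid null outcome
    expect_match(attr(res, "condition")$message, "slope")
  }
})

test_that("expected target signal and fold difference are proportional", {
  tab <- data.frame(ref_intensity = c(100, 200, 300),
                    tgt_intensity = c(80, 160, 240))
  ann <- expected_target(tab, slope = 0.8)
  expect_equal(ann$fold, c(1, 1, 1))
  ann2 <- expected_target(transform(tab, tgt_intensity = 2 * tgt_intensity),
                          slope = 0.8)
  expect_equal(ann2$fold, c(2, 2, 2))

  # with every object detected the slope equals beta exactly and
  # truth-detected singles sit at fold ~ 1
  spec1 <- object_table_spec(3000, p_codetect = 1, beta = 0.8, seed = 13)
  sim1 <- gen_object_table(spec1)
  fit1 <- fit_mixture(sim1$ref_intensity, k_max = 3, constrained = TRUE,
                      seed = 13)
  res1 <- codetect(sim1, fit1)
  ann1 <- expected_target(sim1, res1$slope)
  s1 <- ann1[ann1$copy_number == 1, ]
  expect_equal(median(s1$fold), 1.0, tolerance = 0.05)

  # at p_codetect = 0.9 the zero-intercept slope is shrunk toward
  # beta * p by the undetected non-singles, so detected singles sit at
  # fold ~ 1/p rather than 1
  spec <- object_table_spec(3000, p_codetect = 0.90, beta = 0.8,
                            seed = 13)
  sim <- gen_object_table(spec)
  fit <- fit_mixture(sim$ref_intensity, k_max = 3, constrained = TRUE,
                     seed = 13)
  res <- codetect(sim, fit)
  ann3 <- expected_target(sim, res$slope)
  singles <- ann3[ann3$copy_number == 1 & ann3$detected, ]
  expect_equal(median(singles$fold), 1 / 0.9, tolerance = 0.05)
})

test_that("codetection reports round-trip through JSON and TSV", {
  dir <- withr::local_tempdir()
  spec <- object_table_spec(1000, seed = 23)
  tab <- gen_object_table(spec)
  fit <- fit_mixture(tab$ref_intensity, k_max = 2, constrained = TRUE,
                     seed = 23)
  res <- codetect(tab, fit)
  jp <- file.path(dir, "report.json")
  tp <- file.path(dir, "objects.tsv")
  codetect_report(tab, fit, res, jp, tp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$codetect_rate_pct, res$codetect_rate_pct,
               tolerance = 1e-9)
  expect_equal(back$K, fit$K)
  objs <- read.delim(tp)
  expect_true(all(c("expected_tgt", "fold") %in% names(objs)))
  expect_identical(nrow(objs), nrow(tab))
})
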