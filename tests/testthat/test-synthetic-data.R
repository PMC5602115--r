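test_that("gen_target_sequence respects length, composition and seed", {
  expect_identical(gen_target_sequence(0, 0.5, seed = 1), "")
  expect_error(gen_target_sequence(-1, 0.5), "non-negative")

  s <- gen_target_sequence(10000, 0.5, seed = 1)
  expect_equal(nchar(s), 10000)
  expect_gt(gc_frac(s), 0.48)
  expect_lt(gc_frac(s), 0.52)

  gc_only <- gen_target_sequence(100, 1.0, seed = 7)
  expect_true(all(strsplit(gc_only, "")[[1]] %in% c("G", "C")))
  at_only <- gen_target_sequence(100, 0.0, seed = 7)
  expect_true(all(strsplit(at_only, "")[[1]] %in% c("A", "T")))

  expect_identical(gen_target_sequence(500, 0.5, seed = 42),
                   gen_target_sequence(500, 0.5, seed = 42))
})

test_that("gen_object_table follows its generative model", {
  # single-component reference intensities: mean within 100 +/- 0.6
  # (SE of the mean = 10 / sqrt(5000) ~ 0.14)
  spec <- object_table_spec(5000, weights = 1, mu1 = 100, sigma1 = 10,
                            seed = 11)
  tab <- gen_object_table(spec)
  expr <- tab[tab$region == "expressing", ]
  expect_equal(mean(expr$ref_intensity), 100, tolerance = 0.6 / 100)

  # noise-free, always-detected limit: target = beta * reference exactly
  spec0 <- object_table_spec(200, weights = 1, p_codetect = 1,
                             tgt_noise_sd = 0, beta = 0.8, seed = 3)
  tab0 <- gen_object_table(spec0)
  e0 <- tab0[tab0$region == "expressing", ]
  expect_equal(e0$tgt_intensity, 0.8 * e0$ref_intensity, tolerance = 1e-12)

  # nonexpressing count forced by the rounding rule
  spec_fp <- object_table_spec(2000, fp_fold = 20, seed = 5)
  tab_fp <- gen_object_table(spec_fp)
  expect_identical(sum(tab_fp$region == "nonexpressing"), 100L)

  # determinism
  expect_identical(gen_object_table(spec_fp), gen_object_table(spec_fp))
})

test_that("recorded detection events converge to p_codetect", {
  for (p in c(0.5, 0.91)) {
    spec <- object_table_spec(4000, p_codetect = p, seed = 21)
    tab <- gen_object_table(spec)
    expr <- tab[tab$region == "expressing", ]
    se <- sqrt(p * (1 - p) / nrow(expr))
    expect_lt(abs(mean(expr$detected) - p), 3 * se)
  }
})

test_that("object_table_spec validates its invariants", {
  expect_error(object_table_spec(100, weights = c(0.5, 0.4)), "sum to 1")
  expect_error(object_table_spec(100, mu1 = -1), "mu1")
  expect_error(object_table_spec(100, p_codetect = 1.2), "p_codetect")
  expect_error(object_table_spec(100, fp_fold = 0.5), "fp_fold")
})

test_that("gen_image_stack renders spots and noise as specified", {
  # zero spots, zero background -> all-zero stack
  empty <- scene_truth(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               copy_number = integer(0), amp_ref = numeric(0),
               amp_tgt = numeric(0), region = character(0)),
    dim = c(16, 16, 8), seed = 1)
  st0 <- gen_image_stack(empty, background = 0, poisson = FALSE)
  expect_true(all(st0$ref == 0) && all(st0$tgt == 0))

  # one spot, Poisson disabled: voxel sum recovers the integrated
  # amplitude within 1% (4-sigma truncation loss)
  one <- scene_truth(
    data.frame(x = 15.3, y = 16.7, z = 8.2, copy_number = 1L,
               amp_ref = 1000, amp_tgt = 800, region = "expressing"),
    dim = c(32, 32, 16), seed = 1)
  st1 <- gen_image_stack(one, background = 0, poisson = FALSE)
  expect_equal(sum(st1$ref), 1000, tolerance = 0.01)
  expect_equal(sum(st1$tgt), 800, tolerance = 0.01)

  # Poisson background statistics: mean within 5 +/- 0.01
  bg <- scene_truth(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               copy_number = integer(0), amp_ref = numeric(0),
               amp_tgt = numeric(0), region = character(0)),
    dim = c(64, 64, 64), seed = 3)
  stbg <- gen_image_stack(bg, background = 5, poisson = TRUE, seed = 3)
  expect_equal(mean(stbg$ref), 5, tolerance = 0.01 / 5)

  # fixed seed implies bit-identical stacks
  sc <- gen_scene_truth(5, dim = c(32, 32, 16), seed = 9)
  expect_identical(gen_image_stack(sc, background = 2),
                   gen_image_stack(sc, background = 2))
})

test_that("scene_truth enforces bounds and copy numbers", {
  bad <- data.frame(x = 100, y = 1, z = 1, copy_number = 1L,
                    amp_ref = 10, amp_tgt = 8, region = "expressing")
  expect_error(scene_truth(bad, dim = c(16, 16, 8), seed = 1),
               "inside the stack bounds")
  bad2 <- transform(bad, x = 5, copy_number = 0L)
  expect_error(scene_truth(bad2, dim = c(16, 16, 8), seed = 1),
               "copy_number")
  neg <- scene_truth(transform(bad, x = 5, amp_ref = -10),
                     dim = c(16, 16, 8), seed = 1)
  expect_error(gen_image_stack(neg), "amplitudes")
})

test_that("gen_spectro_read inverts the absorbance arithmetic", {
  pool <- oligo_pool_spec(200000, n_initial_pmol = 1000,
                          volume_l = 50e-6)
  dye <- dye_spec(130000, 0.05)

  # unlabeled sample: no dye absorbance
  r0 <- gen_spectro_read(1e-6, 0, pool, dye)
  expect_equal(r0$od_dye, 0)
  expect_equal(r0$od260, 1e-6 * pool_epsilon(pool))

  # cf260 = 0: OD260 independent of the dye
  dye0 <- dye_spec(130000, 0)
  r1 <- gen_spectro_read(1e-6, 1.0, pool, dye0)
  expect_equal(r1$od260, 1e-6 * pool_epsilon(pool))

  # exact round trip through estimate_dol
  r2 <- gen_spectro_read(2e-6, 0.93, pool, dye)
  est <- estimate_dol(r2, dye, pool)
  expect_equal(est$c, 2e-6, tolerance = 1e-9)
  expect_equal(est$dol, 0.93, tolerance = 1e-9)
})

test_that("generator RNG streams are independent of call order", {
  a1 <- gen_target_sequence(50, 0.5, seed = 17)
  t1 <- gen_object_table(object_table_spec(100, seed = 17))
  # interleave an unrelated draw; outputs must not change
  t2 <- gen_object_table(object_table_spec(100, seed = 17))
  a2 <- gen_target_sequence(50, 0.5, seed = 17)
  expect_identical(a1, a2)
  expect_identical(t1, t2)
})
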