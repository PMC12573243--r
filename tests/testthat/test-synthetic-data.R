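test_that("config validation rejects bad parameters", {
  expect_error(synthetic_modality_config("A", 1), "n_categories")
  expect_error(synthetic_modality_config("A", 2, noise_sd = -1), "noise_sd")
  expect_error(synthetic_modality_config(
    "A", 2, category_params = list(list(corr_len = 2, aniso_theta = 0,
                                        aniso_ratio = 1),
                                   list(corr_len = 2, aniso_theta = 0,
                                        aniso_ratio = 1))),
    "distinct")
  expect_error(synthetic_modality_config(
    "B", 2, category_params = list(list(f0 = 20, n_harmonics = 1, smooth = 0),
                                   list(f0 = 1, n_harmonics = 1, smooth = 0))),
    "f0")
})

test_that("generators are bit-deterministic and respect the value contract", {
  cfgA <- synthetic_modality_config("A", 3, seed = 7)
  cfgB <- synthetic_modality_config("B", 3, seed = 8)
  for (gen in list(function() gen_vision_like_patches(cfgA, 2, 50, seed = 4),
                   function() gen_audio_like_patches(cfgB, 2, 50, seed = 4))) {
    p1 <- gen(); p2 <- gen()
    expect_identical(unclass(p1), unclass(p2))
    expect_true(all(is.finite(p1)))
    expect_gte(min(p1), 0)
    expect_lte(max(p1), 1)
    expect_equal(dim(p1), c(50L, 256L))
  }
  expect_error(gen_vision_like_patches(cfgA, 9, 5), "out of range")
  expect_error(gen_vision_like_patches(cfgA, 1, 0), "`n`")
  expect_error(gen_audio_like_patches(cfgA, 1, 5), "modality-B")
})

test_that("infinite correlation length degenerates to constant patches", {
  cfg <- synthetic_modality_config(
    "A", 2, noise_sd = 0,
    category_params = list(list(corr_len = Inf, aniso_theta = 0, aniso_ratio = 1),
                           list(corr_len = 1, aniso_theta = 0, aniso_ratio = 1)),
    seed = 5)
  p <- gen_vision_like_patches(cfg, 1, 20, seed = 9)
  # constant within each patch -> the zero-range guard maps all to 0.5
  expect_true(all(p == 0.5))
})

test_that("longer correlation length raises lag-1 autocorrelation (oracle)", {
  cfg <- synthetic_modality_config(
    "A", 2, noise_sd = 0,
    category_params = list(list(corr_len = 4, aniso_theta = 0, aniso_ratio = 1),
                           list(corr_len = 1, aniso_theta = 0, aniso_ratio = 1)),
    seed = 13)
  ac4 <- oracle_lag1_autocorr(gen_vision_like_patches(cfg, 1, 60, seed = 1))
  ac1 <- oracle_lag1_autocorr(gen_vision_like_patches(cfg, 2, 60, seed = 1))
  expect_gt(ac4, ac1)
})

test_that("audio degenerate case: zero smoothness and noise", {
  cfg <- synthetic_modality_config(
    "B", 2, noise_sd = 0,
    category_params = list(list(f0 = 3, n_harmonics = 2, smooth = 0),
                           list(f0 = 2, n_harmonics = 1, smooth = 0)),
    seed = 3)
  p <- gen_audio_like_patches(cfg, 1, 40, seed = 6)
  # before normalization energy off the harmonic rows is exactly zero; the
  # per-patch min-max rescale maps that common minimum to exactly 0
  for (i in 1:5) {
    m <- matrix(p[i, ], 16, 16, byrow = TRUE)
    expect_true(all(m[-c(4, 7), ] == 0)) # 0-based rows 3 and 6
    expect_true(all(m[c(4, 7), ] > 0))
  }
  # envelope columns are independent draws: lag-1 correlation near zero
  env <- t(sapply(1:40, function(i) matrix(p[i, ], 16, 16, byrow = TRUE)[4, ]))
  r <- stats::cor(as.vector(env[, -16]), as.vector(env[, -1]))
  expect_lt(abs(r), 0.15)
})

test_that("row energy concentrates on the harmonic rows (oracle)", {
  cfg <- synthetic_modality_config(
    "B", 2,
    category_params = list(list(f0 = 3, n_harmonics = 2, smooth = 0.9),
                           list(f0 = 2, n_harmonics = 1, smooth = 0.9)),
    seed = 3)
  p <- gen_audio_like_patches(cfg, 1, 30, seed = 2)
  for (i in 1:10) {
    e <- oracle_row_energy(p[i, ])
    top2 <- order(e, decreasing = TRUE)[1:2]
    expect_setequal(top2, c(4, 7)) # 1-based rows for 0-based indices 3, 6
    expect_equal(which.max(e), 4L) # fundamental carries the most energy
  }
})

test_that("suite assembly counts, naming and labels", {
  suite <- tiny_suite()
  man <- attr(suite, "manifest")
  expect_length(suite, 4L)
  expect_equal(sum(man$modality == "A"), 2L)
  expect_equal(sum(man$modality == "B"), 2L)
  expect_setequal(names(suite), c("sv:1", "sv:2", "sa:1", "sa:2"))
  expect_true(all(vapply(suite, nrow, integer(1)) == 600L))
  cfgA <- synthetic_modality_config("A", 4)
  cfgB <- synthetic_modality_config("B", 4)
  s2 <- make_synthetic_suite(cfgA, cfgB, 100)
  expect_length(s2, 8L)
})

test_that("anisotropy statistic separates the modalities with no overlap", {
  cfgA <- synthetic_modality_config("A", 4, seed = 41)
  cfgB <- synthetic_modality_config("B", 4, seed = 42)
  suite <- make_synthetic_suite(cfgA, cfgB, 60)
  man <- attr(suite, "manifest")
  stat <- vapply(names(suite), function(id) oracle_anisotropy(suite[[id]], 20),
                 numeric(1))
  a <- stat[man$modality == "A"]
  b <- stat[man$modality == "B"]
  expect_gt(min(b), max(a))
})
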