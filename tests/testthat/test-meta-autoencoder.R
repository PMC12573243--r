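test_that("filters_of: shape, round-trip, column permutation", {
  W <- matrix(rnorm(4096), 256, 16)
  fl <- filters_of(W)
  expect_length(fl, 16L)
  for (j in 1:16) {
    expect_equal(dim(fl[[j]]), c(16L, 16L))
    expect_identical(as.vector(t(fl[[j]])), W[, j]) # row-major round-trip
  }
  perm <- c(5, 1, 16, 2:4, 6:15)
  expect_identical(filters_of(W[, perm]), fl[perm])
  expect_error(filters_of(matrix(0, 16, 16)), "256 x 16")
})

test_that("unitwise stage: bottleneck 3, loss decreases, deterministic", {
  zoo <- tiny_zoo()
  uw <- tiny_meta()$uw
  expect_s3_class(uw, "unitwise_params")
  expect_equal(uw$bottleneck, 3L)
  expect_lt(uw$final_mse, uw$initial_mse)
  z <- embed_filter(uw, filters_of(zoo$nets[[1]])[[4]])
  expect_length(z, 3L)
  expect_true(all(is.finite(z)))
  uw2 <- train_unitwise(zoo, epochs = 3, seed = 31)
  expect_identical(uw2$final_mse, uw$final_mse)
  expect_identical(embed_filter(uw2, filters_of(zoo$nets[[1]])[[4]]), z)
})

test_that("embed_filter accepts vector or image and is batch-independent", {
  uw <- tiny_meta()$uw
  W <- tiny_zoo()$nets[[2]]$W
  z_img <- embed_filter(uw, filters_of(W)[[7]])
  z_vec <- embed_filter(uw, W[, 7])
  expect_identical(z_img, z_vec)
  # two copies of one filter embedded alongside others give the same
  # latents as standalone embedding (inference-mode batch norm)
  lat <- metanet:::net_filter_latents(uw, W)
  expect_identical(lat[7, ], z_vec)
  Wdup <- W; Wdup[, 8] <- W[, 7]
  lat2 <- metanet:::net_filter_latents(uw, Wdup)
  expect_identical(lat2[7, ], z_vec)
  expect_identical(lat2[8, ], z_vec)
  expect_error(embed_filter(structure(list(), class = "junk"), W[, 1]),
               "not a trained")
})

test_that("sort_filters is a total order, permutation-independent", {
  set.seed(8)
  L <- matrix(rnorm(48), 16, 3)
  s <- sort_filters(L)
  expect_identical(sort_filters(s), s) # idempotent
  expect_identical(sort_filters(L[16:1, ]), s) # reversal
  # exhaustive: all 3! permutations of three distinguished rows
  base <- L
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    Lp <- base
    Lp[1:3, ] <- base[p, ]
    expect_identical(sort_filters(Lp), s)
  }
  for (rep in 1:10) { # random full permutations
    expect_identical(sort_filters(L[sample(16), ]), s)
  }
  # ties in the first coordinate fall through to the second and third
  Lt <- L; Lt[, 1] <- 1; Lt[1:2, 2] <- 2; Lt[1:2, 3] <- c(9, 1)
  st <- sort_filters(Lt)
  expect_identical(st, Lt[order(Lt[, 1], Lt[, 2], Lt[, 3]), ])
  expect_error(sort_filters(L[1:5, ]), "16 x 3")
})

test_that("interunit stage: dimensions, loss decrease, single-net capacity", {
  iu <- tiny_meta()$iu
  expect_equal(dim(iu$layers[[1]]$W), c(16L, 48L))
  expect_equal(dim(iu$layers[[2]]$W), c(48L, 16L))
  expect_lt(iu$final_mse, iu$initial_mse)
  # a linear AE with a 16-d bottleneck represents one 48-d point exactly;
  # long Adam training on a single-net zoo must drive the MSE toward zero
  zoo1 <- model_zoo(c(tiny_zoo()$nets[1], tiny_zoo()$nets[6]))
  zoo1$nets[[1]]$split <- "train"; zoo1$nets[[2]]$split <- "validation"
  zoo1 <- model_zoo(zoo1$nets)
  iu1 <- train_interunit(zoo1, tiny_meta()$uw, epochs = 3000, seed = 2)
  expect_lt(iu1$final_mse, 1e-6)
})

test_that("embed_network: dimension, provenance, permutation invariance", {
  zoo <- tiny_zoo(); mt <- tiny_meta()
  net <- zoo$nets[[3]]
  m <- embed_network(net, mt$uw, mt$iu)
  expect_length(m, 16L)
  expect_equal(attr(m, "dataset_id"), net$dataset_id)
  lat <- metanet:::net_filter_latents(mt$uw, net)
  expect_false(anyDuplicated(lat[, 1]) > 0) # tie-free first coordinates
  set.seed(14)
  for (i in 1:5) {
    perm <- sample(16)
    mp <- embed_network(net$W[, perm], mt$uw, mt$iu)
    expect_identical(as.numeric(mp), as.numeric(m))
  }
  expect_error(embed_network(net, mt$uw, structure(list(), class = "junk")),
               "interunit")
})

test_that("meta parameters serialize and reload to identical embeddings", {
  zoo <- tiny_zoo(); mt <- tiny_meta()
  td <- withr::local_tempdir()
  f <- file.path(td, "meta.json")
  save_meta_params(mt$uw, mt$iu, f)
  mp <- load_meta_params(f)
  for (net in zoo$nets[c(1, 9, 17)]) {
    expect_identical(as.numeric(embed_network(net, mp$unitwise, mp$interunit)),
                     as.numeric(embed_network(net, mt$uw, mt$iu)))
  }
  writeLines('{"container": "other"}', file.path(td, "bad.json"))
  expect_error(load_meta_params(file.path(td, "bad.json")), "container")
})

test_that("embeddings separate modalities more than within-dataset spread", {
  # needs a properly trained suite: reuse the shared default-scale run
  res <- acceptance_run()
  E <- res$embeddings$embeddings
  man <- res$embeddings$manifest
  set.seed(99)
  take <- sort(sample(nrow(E), 40)) # brute-force oracle over a 40-net sample
  E <- E[take, ]; man <- man[take, ]
  inter <- oracle_mean_cross_dist(E[man$modality == "A", , drop = FALSE],
                                  E[man$modality == "B", , drop = FALSE])
  intra <- mean(vapply(unique(man$dataset_id), function(id) {
    sub <- E[man$dataset_id == id, , drop = FALSE]
    if (nrow(sub) < 2) return(NA_real_)
    oracle_mean_within_dist(sub)
  }, numeric(1)), na.rm = TRUE)
  expect_gt(inter, intra)
})
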