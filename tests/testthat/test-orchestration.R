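micro_config <- function(seed = 5, out_dir = file.path(tempdir(), "micro_run")) {
  cfg <- default_config(seed = seed, out_dir = out_dir)
  cfg$suite$n_categories_A <- 2L
  cfg$suite$n_categories_B <- 2L
  cfg$suite$n_patches_per_dataset <- 400L
  cfg$zoo$n_models <- 4L
  cfg$zoo$n_train <- 3L
  cfg$meta$epochs <- 2L
  cfg$eval$k <- 3L
  cfg
}

test_that("validate_config fills defaults and enforces cross-field rules", {
  cfg <- validate_config(list(seed = 3))
  expect_equal(cfg$zoo$n_models, 60L)
  expect_equal(cfg$eval$k, 10L)
  expect_equal(cfg$seed, 3L) # explicit value survives defaulting
  cfg2 <- validate_config('{"suite": {"n_categories_A": 3}}')
  expect_equal(cfg2$suite$n_categories_A, 3L)
  expect_equal(cfg2$suite$n_categories_B, 4L)
  bad <- micro_config(); bad$zoo$n_train <- 9L
  expect_error(validate_config(bad), "n_train.*n_models")
  bad2 <- micro_config(); bad2$eval$k <- 10L; bad2$zoo$n_train <- 1L
  bad2$zoo$n_models <- 2L
  expect_error(validate_config(bad2), "reference count")
  bad3 <- micro_config(); bad3$eval$tsne <- TRUE; bad3$eval$tsne_perplexity <- 50
  expect_error(validate_config(bad3), "perplexity")
  # config files round-trip through JSON
  td <- withr::local_tempdir()
  f <- file.path(td, "cfg.json")
  jsonlite::write_json(unclass(micro_config()), f, auto_unbox = TRUE)
  expect_equal(validate_config(f)$zoo$n_models, 4L)
})

test_that("planner arithmetic on synthetic and paper-scale configs", {
  p <- plan_experiment(micro_config())
  expect_equal(p$n_meta_train_datasets, 4L)
  expect_equal(p$knn_reference_points, 12L)
  expect_equal(p$modality_eval_nets, 4L)
  expect_equal(p$embedding_dim, 16L)
})

test_that("micro experiment runs, caches, and is reproducible", {
  td <- withr::local_tempdir()
  cfg <- micro_config(out_dir = file.path(td, "run1"))
  r1 <- run_experiment(cfg, use_cache = FALSE, progress = FALSE)
  expect_s3_class(r1$report$category, "eval_report")
  expect_true(file.exists(file.path(td, "run1", "embeddings.csv")))
  expect_true(file.exists(file.path(td, "run1", "eval_meta.json")))
  expect_gte(r1$report$modality$accuracy, 0)
  expect_equal(nrow(r1$embeddings$embeddings), 16L)

  # cached rerun reuses artifacts and reproduces identical embeddings
  t_cache <- system.time(
    r2 <- run_experiment(cfg, use_cache = TRUE, progress = FALSE))
  expect_identical(unname(r2$embeddings$embeddings),
                   unname(r1$embeddings$embeddings))
  expect_identical(r2$report$category$accuracy, r1$report$category$accuracy)

  # fresh directory, cache off: bit-identical full recomputation
  cfg3 <- micro_config(out_dir = file.path(td, "run2"))
  r3 <- run_experiment(cfg3, use_cache = FALSE, progress = FALSE)
  expect_identical(unname(r3$embeddings$embeddings),
                   unname(r1$embeddings$embeddings))
  expect_identical(r3$report$category$confusion, r1$report$category$confusion)
  expect_identical(r3$baseline$category$accuracy, r1$baseline$category$accuracy)
})

test_that("cli: plan and run subcommands execute", {
  out <- capture.output(metanet_main(c("plan")))
  expect_true(any(grepl("n_meta_train_datasets\\s+20", out)))
  expect_true(any(grepl("modality_eval_nets\\s+4100", out)))
  td <- withr::local_tempdir()
  cfgf <- file.path(td, "cfg.json")
  cfg <- micro_config(out_dir = file.path(td, "cli_run"))
  jsonlite::write_json(unclass(cfg), cfgf, auto_unbox = TRUE)
  out2 <- capture.output(suppressMessages(
    metanet_main(c("run", "--config", cfgf))))
  expect_true(any(grepl("category accuracy", out2)))
  expect_true(any(grepl("modality accuracy", out2)))
  out3 <- capture.output(metanet_main("nope"))
  expect_true(any(grepl("unknown command", out3)))
})

test_that("cli: stage subcommands compose over containers", {
  td <- withr::local_tempdir()
  suite_dir <- file.path(td, "suite")
  save_suite(tiny_suite(), suite_dir)
  zoo_dir <- file.path(td, "zoo")
  capture.output(suppressMessages(metanet_main(c(
    "train-zoo", "--suite", suite_dir, "--n-models", "4", "--n-train", "3",
    "--seed", "21", "--out", zoo_dir))))
  expect_true(file.exists(file.path(zoo_dir, "weights.csv")))
  meta_f <- file.path(td, "meta.json")
  capture.output(metanet_main(c(
    "train-meta", "--zoo", zoo_dir, "--epochs", "2", "--seed", "3",
    "--out", meta_f)))
  emb_f <- file.path(td, "emb.csv")
  capture.output(metanet_main(c(
    "embed", "--zoo", zoo_dir, "--meta", meta_f, "--out", emb_f)))
  emb <- read_embeddings(emb_f)
  expect_equal(ncol(emb$embeddings), 16L)
  eval_dir <- file.path(td, "eval")
  capture.output(metanet_main(c(
    "eval", "--zoo", zoo_dir, "--meta", meta_f, "--k", "3",
    "--baseline", "--out", eval_dir)))
  expect_true(file.exists(file.path(eval_dir, "eval_meta.json")))
  expect_true(file.exists(file.path(eval_dir, "eval_baseline.json")))
})
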