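test_that("classifier construction enforces its preconditions", {
  set.seed(1)
  ref <- matrix(rnorm(40 * 16), 40, 16)
  labs <- rep(c("d1", "d2"), each = 20)
  clf <- fit_meta_classifier(ref, labs, k = 10)
  expect_s3_class(clf, "meta_classifier")
  expect_error(fit_meta_classifier(ref[1:5, ], labs[1:5], k = 10), "exceeds")
  expect_error(fit_meta_classifier(ref, labs[1:10], k = 3), "labels length")
  expect_error(predict_dataset(clf, rnorm(4)), "dimension")
})

test_that("unanimous and nearest-neighbour cases", {
  ref <- rbind(matrix(0, 12, 4), matrix(10, 12, 4))
  labs <- rep(c("zero", "ten"), each = 12)
  clf <- fit_meta_classifier(ref, labs, k = 10)
  expect_equal(predict_dataset(clf, rep(0, 4)), "zero")
  expect_equal(predict_dataset(clf, rep(10, 4)), "ten")
  clf1 <- fit_meta_classifier(rbind(c(0, 0), c(5, 5), c(9, 9)),
                              c("a", "b", "c"), k = 1)
  expect_equal(predict_dataset(clf1, c(8.6, 8.6)), "c")
})

test_that("kNN agrees with the brute-force oracle on random instances", {
  set.seed(42)
  ref <- matrix(rnorm(200 * 16), 200, 16)
  labs <- sample(paste0("d", 1:8), 200, replace = TRUE)
  q <- matrix(rnorm(50 * 16), 50, 16)
  clf <- fit_meta_classifier(ref, labs, k = 10)
  expect_identical(predict_dataset(clf, q), unname(oracle_knn(ref, labs, q, 10)))
  clf5 <- fit_meta_classifier(ref, labs, k = 5)
  expect_identical(predict_dataset(clf5, q), unname(oracle_knn(ref, labs, q, 5)))
})

test_that("deterministic tie handling: vote ties resolved by distance then label", {
  # two labels, equal vote counts; the 'near' label has smaller mean distance
  ref <- rbind(matrix(c(1, 0), 2, 2, byrow = TRUE),
               matrix(c(-2, 0), 2, 2, byrow = TRUE))
  labs <- c("near", "near", "far", "far")
  clf <- fit_meta_classifier(ref, labs, k = 4)
  expect_equal(predict_dataset(clf, c(0, 0)), "near")
  # fully symmetric tie falls back to the lexicographically smaller label
  ref2 <- rbind(c(1, 0), c(-1, 0))
  clf2 <- fit_meta_classifier(ref2, c("bbb", "aaa"), k = 2)
  expect_equal(predict_dataset(clf2, c(0, 0)), "aaa")
})

test_that("modality prediction coarsens dataset predictions via the map", {
  ref <- rbind(matrix(0, 10, 3), matrix(10, 10, 3))
  labs <- rep(c("sv:1", "sa:1"), each = 10)
  clf <- fit_meta_classifier(ref, labs, k = 3,
                             modality_map = c("sv:1" = "A", "sa:1" = "B"))
  expect_equal(predict_modality(clf, rep(0, 3)), "A")
  expect_equal(predict_modality(clf, rep(10, 3)), "B")
  clf_nomap <- fit_meta_classifier(ref, labs, k = 3)
  expect_error(predict_modality(clf_nomap, rep(0, 3)), "map")
})

test_that("evaluation reports: perfect case, confusion accounting, chance", {
  ref <- rbind(matrix(0, 10, 2), matrix(10, 10, 2))
  labs <- rep(c("sv:1", "sa:1"), each = 10)
  clf <- fit_meta_classifier(ref, labs, k = 3,
                             modality_map = c("sv:1" = "A", "sa:1" = "B"))
  q <- rbind(matrix(0.1, 6, 2), matrix(9.9, 4, 2))
  man <- data.frame(dataset_id = rep(c("sv:1", "sa:1"), c(6, 4)),
                    modality = rep(c("A", "B"), c(6, 4)))
  rep_cat <- evaluate_classifier(clf, q, man, "category")
  expect_equal(rep_cat$accuracy, 1)
  expect_equal(rep_cat$n_eval, 10L)
  expect_equal(rep_cat$chance, 0.5)
  cm <- rep_cat$confusion
  expect_equal(sum(cm), 10)
  expect_equal(unname(diag(cm)), unname(rowSums(cm))) # diagonal
  expect_equal(unname(rowSums(cm)[c("sa:1", "sv:1")]), c(4, 6))
  rep_mod <- evaluate_classifier(clf, q, man, "modality")
  expect_equal(rep_mod$accuracy, 1)
})

test_that("modality accuracy dominates category accuracy (label coarsening)", {
  zoo <- tiny_zoo(); mt <- tiny_meta()
  rep <- evaluate_zoo(zoo, mt$uw, mt$iu, k = 3)
  expect_gte(rep$modality$accuracy, rep$category$accuracy)
  # confusion rows recount the per-dataset validation nets
  expect_equal(unname(rowSums(rep$category$confusion)),
               rep(1, 4)) # 1 validation net per dataset in the tiny zoo
})

test_that("raw-weight baseline follows the same protocol in 4096-d", {
  zoo <- tiny_zoo()
  bl <- baseline_raw_weights(zoo, k = 3)
  expect_equal(ncol(bl$classifier$ref), 4096L)
  expect_equal(bl$category$n_eval, 4L)
  # same validation nets as the meta pipeline (protocol parity)
  mt <- tiny_meta()
  rep <- evaluate_zoo(zoo, mt$uw, mt$iu, k = 3)
  expect_equal(bl$category$n_eval, rep$category$n_eval)
  expect_equal(bl$modality$n_eval, rep$modality$n_eval)
  # brute-force oracle agreement on the raw-weight classifier
  flat <- t(vapply(zoo$nets, function(n) as.vector(n$W), numeric(4096)))
  va <- zoo$manifest$split == "validation"
  want <- oracle_knn(flat[!va, ], zoo$manifest$dataset_id[!va],
                     flat[va, , drop = FALSE], 3)
  expect_identical(predict_dataset(bl$classifier, flat[va, , drop = FALSE]),
                   unname(want))
})

test_that("eval report serialization writes json and confusion csv", {
  zoo <- tiny_zoo(); mt <- tiny_meta()
  rep <- evaluate_zoo(zoo, mt$uw, mt$iu, k = 3)
  td <- withr::local_tempdir()
  write_eval_report(rep, td, "eval_meta")
  j <- jsonlite::read_json(file.path(td, "eval_meta.json"))
  expect_equal(j$category_accuracy, rep$category$accuracy)
  cm <- data.table::fread(file.path(td, "eval_meta_confusion.csv"))
  expect_equal(nrow(cm), 4L)
})
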