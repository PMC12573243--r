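# kNN meta-classifier and evaluation protocol.
#
# The classifier stores labelled reference embeddings (no iterative
# training) and predicts by majority vote among the k nearest references.
# Ties are broken deterministically: smallest mean neighbour distance
# first, then lexicographically smallest label. Accuracy is reported at
# two levels: dataset id ("category") and modality (the dataset label
# coarsened), so modality accuracy always dominates category accuracy.

#' Fit a kNN meta-classifier on reference embeddings
#'
#' @param embeddings numeric matrix, one reference point per row.
#' @param labels character vector of dataset ids, one per row.
#' @param k neighbour count (replication setting: 10).
#' @param modality_map named character vector mapping dataset ids to
#'   modalities; defaults to the map implied by `labels` names or must be
#'   supplied for [predict_modality()].
#' @return A `meta_classifier`.
#' @export
fit_meta_classifier <- function(embeddings, labels, k = 10L,
                                modality_map = NULL) {
  if (!is.matrix(embeddings) || nrow(embeddings) < 1L)
    stop_param("embeddings must be a non-empty matrix")
  k <- check_count(k, "k")
  if (nrow(embeddings) < k)
    stop_param("k = %d exceeds the number of reference points (%d)",
               k, nrow(embeddings))
  if (length(labels) != nrow(embeddings))
    stop_param("labels length (%d) != reference count (%d)",
               length(labels), nrow(embeddings))
  structure(list(ref = embeddings, labels = as.character(labels), k = k,
                 metric = "euclidean", modality_map = modality_map),
            class = "meta_classifier")
}

#' @export
print.meta_classifier <- function(x, ...) {
  cat(sprintf("<meta_classifier> k=%d, %d references (%d labels), %s\n",
              x$k, nrow(x$ref), length(unique(x$labels)), x$metric))
  invisible(x)
}

# vote among k nearest references; ties by smallest mean neighbour
# distance, then lexicographic label
knn_vote <- function(d, labels, k) {
  nn <- order(d)[seq_len(k)]
  nl <- labels[nn]
  counts <- table(nl)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    means <- vapply(top, function(lb) mean(d[nn[nl == lb]]), numeric(1))
    top <- top[means == min(means)]
    top <- sort(top)[1L]
  }
  top
}

#' Predict the training dataset of one or more query embeddings
#'
#' @param clf a [fit_meta_classifier()] object.
#' @param query numeric vector (one point) or matrix (one per row).
#' @return Character vector of predicted dataset ids.
#' @export
predict_dataset <- function(clf, query) {
  stopifnot(inherits(clf, "meta_classifier"))
  if (is.vector(query)) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(clf$ref))
    stop_param("query dimension %d != reference dimension %d",
               ncol(query), ncol(clf$ref))
  # full distance matrix: reference sets here are small (<= 10^4)
  d2 <- outer(rowSums(query^2), rowSums(clf$ref^2), "+") -
    2 * tcrossprod(query, clf$ref)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  vapply(seq_len(nrow(query)), function(i) knn_vote(d[i, ], clf$labels, clf$k),
         character(1))
}

#' Predict the modality of query embeddings
#'
#' Predicts the dataset id and coarsens it through the classifier's
#' dataset -> modality map.
#'
#' @inheritParams predict_dataset
#' @return Character vector of modality tags.
#' @export
predict_modality <- function(clf, query) {
  if (is.null(clf$modality_map))
    stop_param("classifier has no dataset -> modality map")
  ids <- predict_dataset(clf, query)
  miss <- setdiff(unique(ids), names(clf$modality_map))
  if (length(miss))
    stop_param("no modality mapping for dataset id(s): %s",
               paste(miss, collapse = ", "))
  unname(clf$modality_map[ids])
}

#' Evaluate a meta-classifier on labelled embeddings
#'
#' Two scopes mirror the replication protocol: `"modality"` evaluates
#' modality prediction over all supplied nets (including nets from
#' datasets absent from the reference set); `"category"` evaluates
#' dataset-id prediction restricted to nets whose dataset is in the
#' reference label set, and accumulates the confusion matrix.
#'
#' @param clf a [fit_meta_classifier()] object.
#' @param embeddings matrix of query points (one per row).
#' @param manifest data.frame with `dataset_id` and `modality` for each
#'   row of `embeddings`.
#' @param scope `"category"` or `"modality"`.
#' @return An `eval_report`: list with `scope`, `accuracy`, `n_eval`,
#'   `chance`, and for the category scope a `confusion` matrix
#'   (true x predicted counts over reference dataset ids).
#' @export
evaluate_classifier <- function(clf, embeddings, manifest,
                                scope = c("category", "modality")) {
  scope <- match.arg(scope)
  stopifnot(inherits(clf, "meta_classifier"),
            nrow(embeddings) == nrow(manifest))
  ref_ids <- sort(unique(clf$labels))
  if (scope == "category") {
    keep <- manifest$dataset_id %in% ref_ids
    if (!any(keep)) stop_param("no evaluation nets from reference datasets")
    emb <- embeddings[keep, , drop = FALSE]
    man <- manifest[keep, , drop = FALSE]
    pred <- predict_dataset(clf, emb)
    acc <- mean(pred == man$dataset_id)
    confusion <- table(factor(man$dataset_id, levels = ref_ids),
                       factor(pred, levels = ref_ids))
    confusion <- unclass(as.matrix(confusion))
    names(dimnames(confusion)) <- c("true", "predicted")
    report <- list(scope = scope, accuracy = acc, n_eval = nrow(emb),
                   chance = 1 / length(ref_ids), confusion = confusion)
  } else {
    if (nrow(embeddings) == 0L) stop_param("empty evaluation set")
    pred <- predict_modality(clf, embeddings)
    acc <- mean(pred == manifest$modality)
    report <- list(scope = scope, accuracy = acc, n_eval = nrow(embeddings),
                   chance = 1 / length(unique(manifest$modality)),
                   confusion = NULL)
  }
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s accuracy %.3f (n = %d, chance %.3f)\n",
              x$scope, x$accuracy, x$n_eval, x$chance))
  invisible(x)
}

#' Evaluate zoo validation nets through the full meta-pipeline
#'
#' Convenience wrapper: embeds the train split as kNN references, embeds
#' the validation split as queries, and returns category and modality
#' reports.
#'
#' @param zoo a `model_zoo` with train and validation splits.
#' @param unitwise_params,interunit_params trained meta-stages.
#' @param k neighbour count.
#' @return List with `category` and `modality` [evaluate_classifier()]
#'   reports plus the fitted classifier.
#' @export
evaluate_zoo <- function(zoo, unitwise_params, interunit_params, k = 10L) {
  tr <- embed_zoo(zoo_subset(zoo, split = "train"), unitwise_params,
                  interunit_params)
  va <- embed_zoo(zoo_subset(zoo, split = "validation"), unitwise_params,
                  interunit_params)
  mm <- modality_map_of(zoo$manifest)
  clf <- fit_meta_classifier(tr$embeddings, tr$manifest$dataset_id, k = k,
                             modality_map = mm)
  list(category = evaluate_classifier(clf, va$embeddings, va$manifest,
                                      "category"),
       modality = evaluate_classifier(clf, va$embeddings, va$manifest,
                                      "modality"),
       classifier = clf)
}

modality_map_of <- function(manifest) {
  m <- manifest[!duplicated(manifest$dataset_id), ]
  stats::setNames(m$modality, m$dataset_id)
}

#' Raw-weight kNN baseline
#'
#' Identical protocol to the meta-pipeline, but queries and references
#' are the flattened 4096-dimensional weight matrices themselves instead
#' of 16-d meta-representations.
#'
#' @param zoo a `model_zoo` with both splits.
#' @param k neighbour count.
#' @return List with `category` and `modality` reports and the
#'   classifier.
#' @export
baseline_raw_weights <- function(zoo, k = 10L) {
  stopifnot(inherits(zoo, "model_zoo"))
  flat <- function(sub) t(vapply(sub$nets, function(n) as.vector(n$W),
                                 numeric(4096L)))
  tr <- zoo_subset(zoo, split = "train")
  va <- zoo_subset(zoo, split = "validation")
  clf <- fit_meta_classifier(flat(tr), tr$manifest$dataset_id, k = k,
                             modality_map = modality_map_of(zoo$manifest))
  list(category = evaluate_classifier(clf, flat(va), va$manifest, "category"),
       modality = evaluate_classifier(clf, flat(va), va$manifest, "modality"),
       classifier = clf)
}

#' Write an evaluation report pair to disk
#'
#' JSON for the accuracies and a CSV for the confusion matrix.
#'
#' @param reports list with `category` and `modality` reports.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(reports, dir, prefix = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    category_accuracy = reports$category$accuracy,
    category_n_eval = reports$category$n_eval,
    category_chance = reports$category$chance,
    modality_accuracy = reports$modality$accuracy,
    modality_n_eval = reports$modality$n_eval,
    modality_chance = reports$modality$chance)
  jsonlite::write_json(out, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA)
  cm <- reports$category$confusion
  if (!is.null(cm)) {
    df <- cbind(true = rownames(cm), as.data.frame.matrix(cm))
    data.table::fwrite(df, file.path(dir, paste0(prefix, "_confusion.csv")))
  }
  invisible(dir)
}
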