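# First-order networks: tiny patch autoencoders whose encoder weights are
# the objects the meta-stage embeds.
#
# Architecture: 256 -> 16 linear encoder without bias, 16 -> 256 linear
# decoder with bias (the decoder is discarded after training). MSE loss,
# one epoch of Adam over the dataset's patch matrix in shuffled order.

#' Construct a first-order network record
#'
#' @param W 256 x 16 numeric matrix of encoder weights (column j is the
#'   filter of hidden unit j).
#' @param dataset_id training dataset id.
#' @param modality modality tag of the training dataset.
#' @param seed replicate seed the network was trained with.
#' @param split `"train"` or `"validation"`.
#' @return A `first_order_net` object.
#' @export
first_order_net <- function(W, dataset_id, modality, seed,
                            split = c("train", "validation")) {
  split <- match.arg(split)
  if (!is.matrix(W) || nrow(W) != 256L || ncol(W) != 16L)
    stop_param("W must be 256 x 16, got %s", paste(dim(W), collapse = "x"))
  if (anyNA(W) || !all(is.finite(W)))
    stop_param("W contains non-finite entries")
  structure(list(W = W, dataset_id = dataset_id, modality = modality,
                 seed = as.integer(seed), split = split),
            class = "first_order_net")
}

#' @export
print.first_order_net <- function(x, ...) {
  cat(sprintf("<first_order_net> %s (%s, %s), seed %d\n",
              x$dataset_id, x$modality, x$split, x$seed))
  invisible(x)
}

#' Train one first-order autoencoder
#'
#' Trains a 256 -> 16 -> 256 autoencoder (linear encoder without bias,
#' linear decoder with bias) on the given patches: Glorot uniform
#' initialization, MSE loss, Adam, one pass over the data in shuffled
#' order by default. Only the encoder weights are kept.
#'
#' @param patches a [patch_matrix()] (N x 256).
#' @param seed integer seed governing initialization and shuffling.
#' @param epochs training epochs (the replication setting is 1).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param split split tag recorded on the result.
#' @return A [first_order_net()]; attributes `initial_mse` / `final_mse`
#'   record whole-data reconstruction error before and after training.
#' @export
train_first_order <- function(patches, seed = 1L, epochs = 1L,
                              batch_size = 256L, lr = 1e-3,
                              split = "train") {
  if (!is.matrix(patches) || ncol(patches) != 256L || nrow(patches) < 1L)
    stop_param("patches must be a non-empty N x 256 matrix")
  layers <- init_layers(list(layer_fc(256L, 16L, bias = FALSE),
                             layer_fc(16L, 256L, bias = TRUE)),
                        seed = derive_seed(seed, "fo-init"))
  X <- t(patches)
  fit <- train_net(layers, X, epochs = epochs, batch_size = batch_size,
                   lr = lr, seed = derive_seed(seed, "fo-train"))
  net <- first_order_net(t(fit$layers[[1]]$W),
                         dataset_id = attr(patches, "dataset_id") %||% "unknown",
                         modality = attr(patches, "modality") %||% "unknown",
                         seed = seed, split = split)
  attr(net, "initial_mse") <- fit$initial_mse
  attr(net, "final_mse") <- fit$final_mse
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a model zoo over a dataset suite
#'
#' Trains `n_models` replicate networks per dataset; the first `n_train`
#' replicates are tagged `train`, the rest `validation`. Each replicate's
#' RNG stream is derived from (`base_seed`, dataset id, replicate index)
#' only, so results do not depend on training order.
#'
#' @param suite named list of [patch_matrix()] (e.g. from
#'   [make_synthetic_suite()]).
#' @param n_models replicates per dataset.
#' @param n_train training replicates per dataset (< `n_models`).
#' @param base_seed integer seed.
#' @param epochs,batch_size,lr forwarded to [train_first_order()].
#' @param progress print per-dataset progress.
#' @return A `model_zoo`: list with `nets` (list of [first_order_net()])
#'   and `manifest` (data.frame: dataset_id, modality, seed, split).
#' @export
train_zoo <- function(suite, n_models = 60L, n_train = 50L, base_seed = 1L,
                      epochs = 1L, batch_size = 256L, lr = 1e-3,
                      progress = FALSE) {
  if (length(suite) == 0L) stop_param("empty dataset suite")
  n_models <- check_count(n_models, "n_models")
  n_train <- check_count(n_train, "n_train")
  if (n_train >= n_models)
    stop_param("n_train (%d) must be smaller than n_models (%d)",
               n_train, n_models)
  nets <- vector("list", length(suite) * n_models)
  k <- 0L
  for (id in names(suite)) {
    if (progress) message("training ", n_models, " nets on ", id)
    for (r in seq_len(n_models)) {
      k <- k + 1L
      nets[[k]] <- train_first_order(
        suite[[id]],
        seed = derive_seed(base_seed, "zoo", id, r),
        epochs = epochs, batch_size = batch_size, lr = lr,
        split = if (r <= n_train) "train" else "validation")
    }
  }
  model_zoo(nets)
}

#' Assemble a model zoo from a list of networks
#'
#' @param nets list of [first_order_net()].
#' @return A `model_zoo` with a manifest data.frame.
#' @export
model_zoo <- function(nets) {
  stopifnot(length(nets) > 0L,
            all(vapply(nets, inherits, logical(1), "first_order_net")))
  manifest <- data.frame(
    dataset_id = vapply(nets, `[[`, character(1), "dataset_id"),
    modality = vapply(nets, `[[`, character(1), "modality"),
    seed = vapply(nets, `[[`, integer(1), "seed"),
    split = vapply(nets, `[[`, character(1), "split"),
    row.names = NULL)
  structure(list(nets = nets, manifest = manifest), class = "model_zoo")
}

#' @export
print.model_zoo <- function(x, ...) {
  tab <- table(x$manifest$dataset_id, x$manifest$split)
  cat(sprintf("<model_zoo> %d nets, %d datasets\n", length(x$nets),
              nrow(tab)))
  print(tab)
  invisible(x)
}

#' Subset a zoo by split and/or dataset
#'
#' @param zoo a `model_zoo`.
#' @param split optional `"train"` or `"validation"`.
#' @param dataset_ids optional character vector of dataset ids.
#' @return A `model_zoo` with the selected nets.
#' @export
zoo_subset <- function(zoo, split = NULL, dataset_ids = NULL) {
  stopifnot(inherits(zoo, "model_zoo"))
  keep <- rep(TRUE, length(zoo$nets))
  if (!is.null(split)) keep <- keep & zoo$manifest$split == split
  if (!is.null(dataset_ids)) keep <- keep & zoo$manifest$dataset_id %in% dataset_ids
  if (!any(keep)) stop_param("zoo subset is empty")
  model_zoo(zoo$nets[keep])
}

# -- serialization -----------------------------------------------------------
# Plain-text container: a directory holding manifest.json plus one
# weights.csv with a 4096-value row per net, written with %.17g so the
# round trip is bit-exact.

#' Save a model zoo to a plain-text container
#'
#' Writes `manifest.json` (per-net dataset_id, modality, seed, split) and
#' `weights.csv` (one row of 4096 values per net, column-major flattening
#' of the 256 x 16 weight matrix, `%.17g` formatting) under `path`.
#'
#' @param zoo a `model_zoo`.
#' @param path directory to create or overwrite.
#' @return `path`, invisibly.
#' @export
save_zoo <- function(zoo, path) {
  stopifnot(inherits(zoo, "model_zoo"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(container = "metanet_zoo", version = 1L, n_nets = length(zoo$nets),
         nets = zoo$manifest),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  Wm <- vapply(zoo$nets, function(n) as.vector(n$W), numeric(4096L))
  txt <- matrix(sprintf("%.17g", Wm), nrow = nrow(Wm))
  data.table::fwrite(data.table::as.data.table(txt), # one column per net
                     file.path(path, "weights.csv"),
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a model zoo saved by [save_zoo()]
#'
#' Validates the container (shape, finiteness, mandatory attributes) and
#' reconstructs every net bit-exactly.
#'
#' @param path container directory.
#' @return A `model_zoo`.
#' @export
load_zoo <- function(path) {
  mf <- file.path(path, "manifest.json")
  wf <- file.path(path, "weights.csv")
  if (!file.exists(mf)) stop_param("missing manifest.json in %s", path)
  if (!file.exists(wf)) stop_param("missing weights.csv in %s", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$container, "metanet_zoo"))
    stop_param("%s is not a metanet zoo container", path)
  nets_df <- man$nets
  for (fld in c("dataset_id", "modality", "seed", "split")) {
    if (is.null(nets_df[[fld]]))
      stop_param("zoo manifest missing field '%s'", fld)
  }
  Wm <- as.matrix(data.table::fread(wf, header = FALSE, colClasses = "numeric"))
  if (nrow(Wm) != 4096L || ncol(Wm) != nrow(nets_df))
    stop_param("weights.csv shape %dx%d does not match manifest (%d nets)",
               nrow(Wm), ncol(Wm), nrow(nets_df))
  nets <- lapply(seq_len(nrow(nets_df)), function(i) {
    first_order_net(matrix(Wm[, i], 256L, 16L),
                    dataset_id = nets_df$dataset_id[i],
                    modality = nets_df$modality[i],
                    seed = nets_df$seed[i],
                    split = nets_df$split[i])
  })
  model_zoo(nets)
}
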