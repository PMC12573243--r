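# Two-stage meta-autoencoder over first-order weight matrices.
#
# Stage 1 ("unitwise") treats each of the 16 encoder filters as a 16x16
# image and compresses it to a 3-d latent with a small conv autoencoder.
# Stage 2 ("interunit") canonically sorts the 16 filter latents, flattens
# them to 48 values and compresses to the 16-d meta-representation with a
# purely linear autoencoder. Sorting makes the embedding invariant to the
# arbitrary order of hidden units in the first-order network.

#' Unitwise conv autoencoder architecture
#'
#' Encoder: three 3x3 same-padding conv layers (8, 16, 32 channels), each
#' followed by batch normalization, ReLU and 2x2 max pooling
#' (16 -> 8 -> 4 -> 2 spatial), then fully connected 128 -> 32 -> 3.
#' Decoder mirrors the encoder with nearest-neighbour upsampling and a
#' linear output layer.
#'
#' @return List with `layers` (uninitialized) and `n_encoder` (index of
#'   the last encoder layer).
#' @keywords internal
unitwise_architecture <- function() {
  layers <- list(
    layer_unflatten(1L, 256L),
    layer_conv(1L, 8L, 16L, 16L), layer_bn(8L), layer_relu(),
    layer_pool(16L, 16L, 8L),
    layer_conv(8L, 16L, 8L, 8L), layer_bn(16L), layer_relu(),
    layer_pool(8L, 8L, 16L),
    layer_conv(16L, 32L, 4L, 4L), layer_bn(32L), layer_relu(),
    layer_pool(4L, 4L, 32L),
    layer_flatten(32L, 4L),
    layer_fc(128L, 32L), layer_relu(), layer_fc(32L, 3L),
    # decoder
    layer_fc(3L, 32L), layer_relu(), layer_fc(32L, 128L), layer_relu(),
    layer_unflatten(32L, 4L),
    layer_up(2L, 2L, 32L), layer_conv(32L, 16L, 4L, 4L), layer_bn(16L),
    layer_relu(),
    layer_up(4L, 4L, 16L), layer_conv(16L, 8L, 8L, 8L), layer_bn(8L),
    layer_relu(),
    layer_up(8L, 8L, 8L), layer_conv(8L, 1L, 16L, 16L),
    layer_flatten(1L, 256L))
  list(layers = layers, n_encoder = 17L)
}

#' Split a first-order network into its 16 filter images
#'
#' Filter j is column j of the 256 x 16 encoder weight matrix, reshaped
#' row-major to 16 x 16.
#'
#' @param net a [first_order_net()] or a bare 256 x 16 matrix.
#' @return List of 16 matrices of 16 x 16.
#' @export
filters_of <- function(net) {
  W <- if (inherits(net, "first_order_net")) net$W else net
  if (!is.matrix(W) || nrow(W) != 256L || ncol(W) != 16L)
    stop_param("expected a 256 x 16 weight matrix, got %s",
               paste(dim(W), collapse = "x"))
  lapply(seq_len(16L), function(j) matrix(W[, j], 16L, 16L, byrow = TRUE))
}

# flatten a filter image back to the 256-vector (inverse of filters_of)
filter_vec <- function(f) {
  if (is.matrix(f)) {
    if (!all(dim(f) == c(16L, 16L))) stop_param("filter image must be 16 x 16")
    as.vector(t(f))
  } else {
    if (length(f) != 256L) stop_param("filter vector must have length 256")
    as.numeric(f)
  }
}

#' Train the unitwise meta-autoencoder
#'
#' Pools the filters of every training-split net (16 per net) and trains
#' the conv autoencoder of [unitwise_architecture()] with MSE loss and
#' Adam.
#'
#' @param zoo a `model_zoo`; only its `split == "train"` nets are used.
#' @param epochs training epochs (replication setting: 50).
#' @param seed integer seed.
#' @param batch_size,lr optimizer settings.
#' @return `unitwise_params` with trained layers, the encoder boundary,
#'   and initial/final reconstruction MSE.
#' @export
train_unitwise <- function(zoo, epochs = 50L, seed = 1L, batch_size = 128L,
                           lr = 1e-3) {
  stopifnot(inherits(zoo, "model_zoo"))
  train <- zoo_subset(zoo, split = "train")
  X <- do.call(cbind, lapply(train$nets, `[[`, "W")) # 256 x (16 * n)
  # standardize the filter pool (scalar mean/sd): raw encoder weights live
  # at Glorot scale (~0.1 sd) while the batch-normalized decoder emits O(1)
  # outputs, and without this the optimizer spends the whole budget
  # re-scaling instead of learning structure
  norm_mean <- mean(X)
  norm_sd <- stats::sd(X)
  if (norm_sd == 0) norm_sd <- 1
  X <- (X - norm_mean) / norm_sd
  arch <- unitwise_architecture()
  layers <- init_layers(arch$layers, seed = derive_seed(seed, "uw-init"))
  fit <- train_net(layers, X, epochs = epochs, batch_size = batch_size,
                   lr = lr, seed = derive_seed(seed, "uw-train"))
  structure(list(layers = fit$layers, n_encoder = arch$n_encoder,
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 initial_mse = fit$initial_mse, final_mse = fit$final_mse,
                 epochs = epochs, seed = seed, bottleneck = 3L),
            class = "unitwise_params")
}

#' @export
print.unitwise_params <- function(x, ...) {
  cat(sprintf("<unitwise_params> conv AE 256->3, %d epochs, MSE %.4g -> %.4g\n",
              x$epochs, x$initial_mse, x$final_mse))
  invisible(x)
}

#' Embed one filter into the 3-d unitwise latent space
#'
#' Deterministic encoder pass in inference mode (batch normalization uses
#' running statistics), so the result is independent of any batch
#' context.
#'
#' @param params trained [train_unitwise()] output.
#' @param f a 16 x 16 filter image or 256-vector.
#' @return Numeric 3-vector.
#' @export
embed_filter <- function(params, f) {
  if (!inherits(params, "unitwise_params") || is.null(params$layers))
    stop_param("params is not a trained unitwise_params object")
  v <- (filter_vec(f) - params$norm_mean) / params$norm_sd
  enc <- params$layers[seq_len(params$n_encoder)]
  fw <- net_forward(enc, matrix(v, 256L, 1L), train = FALSE,
                    keep_cache = FALSE)
  as.numeric(fw$out)
}

# all 16 filter latents of one net; column-per-filter loop keeps each
# filter's arithmetic identical to a standalone embed_filter call, which
# is what makes permutation invariance exact
net_filter_latents <- function(params, net) {
  W <- if (inherits(net, "first_order_net")) net$W else net
  t(vapply(seq_len(16L), function(j) embed_filter(params, W[, j]),
           numeric(3L)))
}

#' Canonically sort 16 filter latents
#'
#' Rows are ordered ascending by the first latent coordinate, with ties
#' broken by the second and then third coordinate, giving a total order
#' whenever latents are distinct.
#'
#' @param latents 16 x 3 matrix (or list of 16 3-vectors).
#' @return 16 x 3 matrix with reordered rows.
#' @export
sort_filters <- function(latents) {
  if (is.list(latents)) latents <- do.call(rbind, latents)
  if (!is.matrix(latents) || nrow(latents) != 16L || ncol(latents) != 3L)
    stop_param("expected 16 x 3 latents, got %s",
               paste(dim(latents), collapse = "x"))
  latents[order(latents[, 1L], latents[, 2L], latents[, 3L]), , drop = FALSE]
}

#' Train the interunit meta-autoencoder
#'
#' For every training-split net: embed its 16 filters, sort the latents,
#' flatten filter-major to 48 values; then train the 48 -> 16 -> 48
#' linear autoencoder (bias terms, MSE, Adam).
#'
#' @param zoo a `model_zoo`; only `split == "train"` nets are used.
#' @param unitwise_params trained stage-1 parameters.
#' @param epochs training epochs (replication setting: 50).
#' @param seed integer seed.
#' @param batch_size minibatch size; `NULL` (default) scales the
#'   full-protocol batch of 128 with the training-set size
#'   (`ceiling(128 * n / 10000)`, i.e. 128 at the full 10,000-net scale),
#'   holding the optimizer steps per epoch roughly constant so the small
#'   linear stage is not starved of updates on desk-scale zoos.
#' @param lr Adam learning rate.
#' @return `interunit_params`.
#' @export
train_interunit <- function(zoo, unitwise_params, epochs = 50L, seed = 1L,
                            batch_size = NULL, lr = 1e-3) {
  stopifnot(inherits(zoo, "model_zoo"))
  if (!inherits(unitwise_params, "unitwise_params"))
    stop_param("unitwise stage must be trained first")
  train <- zoo_subset(zoo, split = "train")
  Z <- vapply(train$nets, function(net) {
    s <- sort_filters(net_filter_latents(unitwise_params, net))
    as.vector(t(s)) # filter-major: (z1, z2, z3) of filter 1, then 2, ...
  }, numeric(48L))
  # z-score each of the 48 coordinates over the training nets: the sorted
  # latents carry large rank-dependent offsets that would otherwise eat
  # the whole optimization budget of the small linear autoencoder
  norm_mean <- rowMeans(Z)
  norm_sd <- apply(Z, 1L, stats::sd)
  norm_sd[!is.finite(norm_sd) | norm_sd == 0] <- 1
  Z <- (Z - norm_mean) / norm_sd
  if (is.null(batch_size))
    batch_size <- max(2L, as.integer(ceiling(128 * ncol(Z) / 10000)))
  layers <- init_layers(list(layer_fc(48L, 16L), layer_fc(16L, 48L)),
                        seed = derive_seed(seed, "iu-init"))
  fit <- train_net(layers, Z, epochs = epochs, batch_size = batch_size,
                   lr = lr, seed = derive_seed(seed, "iu-train"))
  structure(list(layers = fit$layers, n_encoder = 1L,
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 initial_mse = fit$initial_mse, final_mse = fit$final_mse,
                 epochs = epochs, seed = seed, bottleneck = 16L),
            class = "interunit_params")
}

#' @export
print.interunit_params <- function(x, ...) {
  cat(sprintf("<interunit_params> linear AE 48->16->48, %d epochs, MSE %.4g -> %.4g\n",
              x$epochs, x$initial_mse, x$final_mse))
  invisible(x)
}

#' Embed a first-order network into the 16-d meta-representation space
#'
#' Pipeline: 16 filters -> unitwise 3-d latents -> canonical sort ->
#' flatten to 48 -> interunit linear encoder. Fully deterministic; as
#' long as the 16 latents have distinct first coordinates the result is
#' invariant to any permutation of the network's hidden units.
#'
#' @param net a [first_order_net()] or bare 256 x 16 matrix.
#' @param unitwise_params,interunit_params trained stage parameters.
#' @return A `meta_representation`: numeric 16-vector with provenance
#'   attributes (`dataset_id`, `modality`, `seed`) when available.
#' @export
embed_network <- function(net, unitwise_params, interunit_params) {
  if (!inherits(interunit_params, "interunit_params"))
    stop_param("interunit stage must be trained first")
  lat <- net_filter_latents(unitwise_params, net)
  z <- as.vector(t(sort_filters(lat)))
  z <- (z - interunit_params$norm_mean) / interunit_params$norm_sd
  enc <- interunit_params$layers[[1L]]
  m <- as.numeric(enc$W %*% z + enc$b)
  if (inherits(net, "first_order_net")) {
    attr(m, "dataset_id") <- net$dataset_id
    attr(m, "modality") <- net$modality
    attr(m, "seed") <- net$seed
  }
  class(m) <- "meta_representation"
  m
}

#' Embed every network of a zoo
#'
#' @param zoo a `model_zoo`.
#' @param unitwise_params,interunit_params trained stage parameters.
#' @return List with `embeddings` (n x 16 matrix) and `manifest` (the
#'   zoo manifest rows, same order).
#' @export
embed_zoo <- function(zoo, unitwise_params, interunit_params) {
  stopifnot(inherits(zoo, "model_zoo"))
  E <- t(vapply(zoo$nets, function(net)
    as.numeric(embed_network(net, unitwise_params, interunit_params)),
    numeric(16L)))
  list(embeddings = E, manifest = zoo$manifest)
}

# -- parameter serialization -------------------------------------------------

#' Save trained meta-autoencoder parameters
#'
#' JSON container holding both stages' weights at full precision plus the
#' architecture descriptor.
#'
#' @param unitwise_params,interunit_params trained stages.
#' @param path output file (.json).
#' @return `path`, invisibly.
#' @export
save_meta_params <- function(unitwise_params, interunit_params, path) {
  # tensors are stored as %.17g strings so IEEE doubles round-trip exactly
  tensor_names <- c("W", "b", "gamma", "beta", "run_mean", "run_var")
  ser_tensor <- function(x) list(dim = if (is.matrix(x)) dim(x) else length(x),
                                 data = sprintf("%.17g", as.vector(x)))
  ser_layers <- function(layers) lapply(layers, function(ly) {
    keep <- intersect(names(ly),
                      c("type", "n_in", "n_out", "bias", "c_in", "c_out",
                        "h", "w", "hw", "c", "momentum", "eps", tensor_names))
    ly <- ly[keep]
    for (nm in intersect(names(ly), tensor_names))
      ly[[nm]] <- ser_tensor(ly[[nm]])
    ly
  })
  ser_stage <- function(p) list(
    layers = ser_layers(p$layers), n_encoder = p$n_encoder,
    norm_mean = if (!is.null(p$norm_mean)) sprintf("%.17g", p$norm_mean),
    norm_sd = if (!is.null(p$norm_sd)) sprintf("%.17g", p$norm_sd),
    initial_mse = sprintf("%.17g", p$initial_mse),
    final_mse = sprintf("%.17g", p$final_mse),
    epochs = p$epochs, seed = p$seed)
  obj <- list(container = "metanet_meta_params", version = 1L,
              unitwise = ser_stage(unitwise_params),
              interunit = ser_stage(interunit_params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load meta-autoencoder parameters saved by [save_meta_params()]
#'
#' @param path JSON file.
#' @return List with `unitwise` and `interunit` parameter objects.
#' @export
load_meta_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$container, "metanet_meta_params"))
    stop_param("%s is not a meta-parameter container", path)
  tensor_names <- c("W", "b", "gamma", "beta", "run_mean", "run_var")
  de_tensor <- function(t) {
    v <- as.numeric(unlist(t$data))
    d <- unlist(t$dim)
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  }
  fix_layers <- function(ls_raw) {
    lapply(ls_raw, function(ly) {
      out <- list()
      for (nm in names(ly)) {
        v <- ly[[nm]]
        out[[nm]] <- if (nm %in% tensor_names) de_tensor(v)
        else if (is.list(v)) unlist(v) else v
      }
      out
    })
  }
  de_stage <- function(p, bottleneck, cls) {
    structure(list(
      layers = fix_layers(p$layers),
      n_encoder = unlist(p$n_encoder),
      norm_mean = if (!is.null(p$norm_mean)) as.numeric(unlist(p$norm_mean)),
      norm_sd = if (!is.null(p$norm_sd)) as.numeric(unlist(p$norm_sd)),
      initial_mse = as.numeric(p$initial_mse),
      final_mse = as.numeric(p$final_mse),
      epochs = unlist(p$epochs), seed = unlist(p$seed),
      bottleneck = bottleneck), class = cls)
  }
  list(unitwise = de_stage(obj$unitwise, 3L, "unitwise_params"),
       interunit = de_stage(obj$interunit, 16L, "interunit_params"))
}
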