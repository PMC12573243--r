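# Config-driven experiment orchestration.
#
# A single JSON config describes the whole pipeline: synthetic suite ->
# model zoo -> two meta-stages -> embeddings -> evaluation. Stages are
# cached under the output directory keyed by a hash of the config subtree
# they depend on, so the expensive zoo can be reused while meta-stages
# are re-run.

#' Default desk-scale experiment configuration
#'
#' Two modalities of four categories each, 20,000 patches per dataset,
#' 60 first-order nets per dataset (50 train / 10 validation), 50 meta
#' epochs, kNN with k = 10. Sized to run the full pipeline in minutes on
#' one CPU.
#'
#' @param seed base seed.
#' @param out_dir output directory.
#' @return Config list (see [validate_config()]).
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("metanet_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    suite = list(type = "synthetic",
                 n_categories_A = 4L, n_categories_B = 4L,
                 noise_sd = 0.05,
                 n_patches_per_dataset = 20000L),
    zoo = list(n_models = 60L, n_train = 50L, epochs = 1L,
               batch_size = 256L, lr = 1e-3),
    meta = list(epochs = 50L, batch_size = 128L, lr = 1e-3),
    eval = list(k = 10L, tsne = FALSE, tsne_perplexity = 20, n_iter_tsne = 500L))
}

#' Paper-scale configuration stub
#'
#' Carries the counts of the full replication (20 vision classes of which
#' 10 train the meta-stage; 10 + 11 audio classes of which 5 + 5 train;
#' 600 nets per dataset split 500/100; 1,000,000 patches per dataset) for
#' structural planning. Running it requires the external corpora; only
#' [plan_experiment()] consumes it here.
#'
#' @param seed base seed.
#' @return Config list with a `paper_scale` suite stub.
#' @export
paper_scale_config <- function(seed = 1L) {
  cfg <- default_config(seed = seed)
  cfg$suite <- list(type = "paper_scale",
                    n_patches_per_dataset = 1000000L,
                    datasets = corpus_dataset_table())
  cfg$zoo$n_models <- 600L
  cfg$zoo$n_train <- 500L
  cfg$eval$tsne <- TRUE
  cfg$eval$tsne_perplexity <- 30
  cfg
}

# the three corpora behind the full replication: every class is one
# dataset; `meta_train` marks datasets whose nets train the meta-stages
corpus_dataset_table <- function() {
  voc <- c("aeroplane", "bicycle", "bird", "boat", "bottle", "bus", "car",
           "cat", "chair", "cow", "diningtable", "dog", "horse",
           "motorbike", "person", "pottedplant", "sheep", "sofa", "train",
           "tvmonitor")
  us8k <- c("air_conditioner", "car_horn", "children_playing", "dog_bark",
            "drilling", "engine_idling", "gun_shot", "jackhammer", "siren",
            "street_music")
  irmas <- c("cel", "cla", "flu", "gac", "gel", "org", "pia", "sax", "tru",
             "vio", "voi")
  rbind(
    data.frame(class_name = voc, corpus = "VOC", modality = "vision",
               meta_train = seq_along(voc) <= 10L),
    data.frame(class_name = us8k, corpus = "UrbanSound8k", modality = "audio",
               meta_train = seq_along(us8k) <= 5L),
    data.frame(class_name = irmas, corpus = "IRMAS", modality = "audio",
               meta_train = seq_along(irmas) <= 5L))
}

#' Validate and resolve an experiment configuration
#'
#' Accepts a config list, a JSON string or a path to a JSON file. Missing
#' fields are filled from [default_config()]; cross-field constraints are
#' checked (train/validation split, kNN reference count, t-SNE
#' perplexity vs. evaluation-set size). The fully resolved config is what
#' gets hashed for stage caching and written next to the results.
#'
#' @param raw config list, JSON text, or file path.
#' @return Resolved config list (class `metanet_config`).
#' @export
validate_config <- function(raw) {
  cfg <- if (is.character(raw) && length(raw) == 1L) {
    if (file.exists(raw)) jsonlite::read_json(raw, simplifyVector = TRUE)
    else jsonlite::fromJSON(raw, simplifyVector = TRUE)
  } else if (is.list(raw)) raw
  else stop_param("config must be a list, JSON text or file path")
  def <- default_config()
  for (top in names(def)) {
    if (is.null(cfg[[top]])) cfg[[top]] <- def[[top]]
    else if (is.list(def[[top]])) {
      for (k in names(def[[top]]))
        if (is.null(cfg[[top]][[k]])) cfg[[top]][[k]] <- def[[top]][[k]]
    }
  }
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  st <- cfg$suite$type
  if (!st %in% c("synthetic", "paper_scale", "real_dirs"))
    stop_param("suite.type must be synthetic, paper_scale or real_dirs")
  cfg$zoo$n_models <- check_count(cfg$zoo$n_models, "zoo.n_models")
  cfg$zoo$n_train <- check_count(cfg$zoo$n_train, "zoo.n_train")
  if (cfg$zoo$n_train >= cfg$zoo$n_models)
    stop_param("zoo.n_train (%d) must be smaller than zoo.n_models (%d)",
               cfg$zoo$n_train, cfg$zoo$n_models)
  cfg$meta$epochs <- check_count(cfg$meta$epochs, "meta.epochs")
  cfg$eval$k <- check_count(cfg$eval$k, "eval.k")
  n_datasets <- switch(st,
    synthetic = cfg$suite$n_categories_A + cfg$suite$n_categories_B,
    paper_scale = sum(cfg$suite$datasets$meta_train),
    real_dirs = NA_integer_)
  if (!is.na(n_datasets)) {
    n_ref <- n_datasets * cfg$zoo$n_train
    if (cfg$eval$k > n_ref)
      stop_param("eval.k (%d) exceeds the kNN reference count (%d = %d datasets x %d train nets)",
                 cfg$eval$k, n_ref, n_datasets, cfg$zoo$n_train)
    n_val <- n_datasets * (cfg$zoo$n_models - cfg$zoo$n_train)
    if (isTRUE(cfg$eval$tsne) && n_val <= 3 * cfg$eval$tsne_perplexity)
      stop_param("eval.tsne_perplexity (%g) too large for %d validation nets",
                 cfg$eval$tsne_perplexity, n_val)
  }
  class(cfg) <- c("metanet_config", "list")
  cfg
}

#' Structural plan of an experiment
#'
#' Pure arithmetic over the resolved config: dataset counts, split sizes,
#' kNN reference points and evaluation-set sizes, before any data is
#' generated or trained.
#'
#' @param config anything accepted by [validate_config()].
#' @return List of named counts.
#' @export
plan_experiment <- function(config) {
  cfg <- validate_config(config)
  st <- cfg$suite$type
  if (st == "synthetic") {
    n_train_ds <- cfg$suite$n_categories_A + cfg$suite$n_categories_B
    n_eval_ds <- n_train_ds
  } else if (st == "paper_scale") {
    ds <- cfg$suite$datasets
    n_train_ds <- sum(ds$meta_train)
    n_eval_ds <- nrow(ds)
  } else {
    stop_param("plan_experiment needs a synthetic or paper_scale suite")
  }
  n_val_per_ds <- cfg$zoo$n_models - cfg$zoo$n_train
  list(
    n_meta_train_datasets = n_train_ds,
    n_eval_datasets = n_eval_ds,
    nets_per_dataset = cfg$zoo$n_models,
    n_train_per_dataset = cfg$zoo$n_train,
    n_validation_per_dataset = n_val_per_ds,
    knn_reference_points = n_train_ds * cfg$zoo$n_train,
    modality_eval_nets = n_eval_ds * n_val_per_ds,
    category_eval_nets = n_train_ds * n_val_per_ds,
    embedding_dim = 16L,
    raw_weight_dim = 4096L)
}

# build the patch suite described by the config
build_suite <- function(cfg) {
  st <- cfg$suite$type
  if (st == "synthetic") {
    cfgA <- synthetic_modality_config("A", cfg$suite$n_categories_A,
                                      noise_sd = cfg$suite$noise_sd,
                                      seed = derive_seed(cfg$seed, "cfgA"))
    cfgB <- synthetic_modality_config("B", cfg$suite$n_categories_B,
                                      noise_sd = cfg$suite$noise_sd,
                                      seed = derive_seed(cfg$seed, "cfgB"))
    make_synthetic_suite(cfgA, cfgB, cfg$suite$n_patches_per_dataset)
  } else if (st == "real_dirs") {
    suites <- list()
    if (!is.null(cfg$suite$vision_dir))
      suites <- c(suites, unclass(dir_to_suite(cfg$suite$vision_dir, "vision",
                                               cfg$suite$n_patches_per_dataset,
                                               seed = derive_seed(cfg$seed, "vdir"))))
    if (!is.null(cfg$suite$audio_dir))
      suites <- c(suites, unclass(dir_to_suite(cfg$suite$audio_dir, "audio",
                                               cfg$suite$n_patches_per_dataset,
                                               seed = derive_seed(cfg$seed, "adir"))))
    if (length(suites) == 0L) stop_param("real_dirs suite needs vision_dir and/or audio_dir")
    attr(suites, "manifest") <- data.frame(
      dataset_id = names(suites),
      modality = vapply(suites, function(p) attr(p, "modality"), character(1)),
      row.names = NULL)
    class(suites) <- "patch_suite"
    suites
  } else {
    stop_param("suite type '%s' cannot be materialized without external data", st)
  }
}

read_run_manifest <- function(out_dir) {
  f <- file.path(out_dir, "run_manifest.json")
  if (!file.exists(f)) return(list(stages = list()))
  jsonlite::read_json(f, simplifyVector = TRUE)
}

write_run_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full experiment described by a config
#'
#' Stages: build suite -> train zoo -> train meta-stages -> embed all
#' nets -> evaluate (meta and raw-weight baseline), with per-stage
#' caching keyed by config-subtree hashes under `out_dir`. The patch
#' suite itself is regenerated rather than cached (it is cheap and
#' deterministic); zoo weights, meta parameters, embeddings and reports
#' are persisted as plain-text artifacts.
#'
#' @param config anything accepted by [validate_config()].
#' @param use_cache reuse artifacts whose stage hash matches.
#' @param progress emit per-stage messages.
#' @return List with `report` (meta evaluation), `baseline`, `embeddings`,
#'   `config`, `plan`, artifact `paths`, and optional `tsne` coordinates.
#' @export
run_experiment <- function(config = default_config(), use_cache = TRUE,
                           progress = TRUE) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(out, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- if (use_cache) read_run_manifest(out) else list(stages = list())
  say <- function(...) if (progress) message("[metanet] ", ...)

  h_zoo <- config_hash(list(cfg$seed, cfg$suite, cfg$zoo))
  zoo_dir <- file.path(out, "zoo")
  zoo <- NULL
  if (use_cache && identical(manifest$stages$zoo, h_zoo) &&
      file.exists(file.path(zoo_dir, "manifest.json"))) {
    say("zoo: cache hit (", h_zoo, ")")
    zoo <- load_zoo(zoo_dir)
  } else {
    say("suite: generating patches")
    suite <- build_suite(cfg)
    say("zoo: training ", cfg$zoo$n_models, " nets x ", length(suite),
        " datasets")
    zoo <- train_zoo(suite, n_models = cfg$zoo$n_models,
                     n_train = cfg$zoo$n_train,
                     base_seed = derive_seed(cfg$seed, "zoo-stage"),
                     epochs = cfg$zoo$epochs,
                     batch_size = cfg$zoo$batch_size, lr = cfg$zoo$lr,
                     progress = progress)
    save_zoo(zoo, zoo_dir)
    manifest$stages$zoo <- h_zoo
    write_run_manifest(out, manifest)
  }

  h_meta <- config_hash(list(h_zoo, cfg$meta))
  meta_path <- file.path(out, "meta_params.json")
  if (use_cache && identical(manifest$stages$meta, h_meta) &&
      file.exists(meta_path)) {
    say("meta: cache hit (", h_meta, ")")
    mp <- load_meta_params(meta_path)
    uw <- mp$unitwise; iu <- mp$interunit
  } else {
    say("meta: training unitwise stage (", cfg$meta$epochs, " epochs)")
    uw <- train_unitwise(zoo, epochs = cfg$meta$epochs,
                         seed = derive_seed(cfg$seed, "uw-stage"),
                         batch_size = cfg$meta$batch_size, lr = cfg$meta$lr)
    say("meta: training interunit stage")
    iu <- train_interunit(zoo, uw, epochs = cfg$meta$epochs,
                          seed = derive_seed(cfg$seed, "iu-stage"),
                          batch_size = cfg$meta$iu_batch_size, # NULL = auto
                          lr = cfg$meta$lr)
    save_meta_params(uw, iu, meta_path)
    manifest$stages$meta <- h_meta
    write_run_manifest(out, manifest)
  }

  h_emb <- config_hash(list(h_meta))
  emb_path <- file.path(out, "embeddings.csv")
  if (use_cache && identical(manifest$stages$embed, h_emb) &&
      file.exists(emb_path)) {
    say("embed: cache hit")
    emb <- read_embeddings(emb_path)
  } else {
    say("embed: embedding ", length(zoo$nets), " nets")
    emb <- embed_zoo(zoo, uw, iu)
    write_embeddings(emb, emb_path)
    manifest$stages$embed <- h_emb
    write_run_manifest(out, manifest)
  }

  say("eval: kNN evaluation (k = ", cfg$eval$k, ") + raw-weight baseline")
  is_tr <- emb$manifest$split == "train"
  mm <- modality_map_of(emb$manifest)
  clf <- fit_meta_classifier(emb$embeddings[is_tr, , drop = FALSE],
                             emb$manifest$dataset_id[is_tr],
                             k = cfg$eval$k, modality_map = mm)
  va_emb <- emb$embeddings[!is_tr, , drop = FALSE]
  va_man <- emb$manifest[!is_tr, , drop = FALSE]
  report <- list(
    category = evaluate_classifier(clf, va_emb, va_man, "category"),
    modality = evaluate_classifier(clf, va_emb, va_man, "modality"),
    classifier = clf)
  baseline <- baseline_raw_weights(zoo, k = cfg$eval$k)
  write_eval_report(report, out, "eval_meta")
  write_eval_report(baseline, out, "eval_baseline")

  tsne <- NULL
  if (isTRUE(cfg$eval$tsne)) {
    say("tsne: projecting validation embeddings")
    tsne <- tsne_coords(va_emb, perplexity = cfg$eval$tsne_perplexity,
                        seed = derive_seed(cfg$seed, "tsne-stage"),
                        n_iter = cfg$eval$n_iter_tsne)
    df <- cbind(va_man, x = tsne[, 1], y = tsne[, 2])
    data.table::fwrite(df, file.path(out, "tsne.csv"))
  }

  list(report = report, baseline = baseline, embeddings = emb,
       meta = list(unitwise = uw, interunit = iu),
       tsne = tsne, config = cfg, plan = plan_experiment(cfg),
       paths = list(out_dir = out, zoo = zoo_dir, meta = meta_path,
                    embeddings = emb_path))
}
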