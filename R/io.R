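# Plain-text containers for patch suites and embeddings.
#
# No binary formats: a suite is a directory with manifest.json and one
# CSV per dataset; embeddings are a single CSV with provenance columns.
# Weight containers live next to the zoo code (save_zoo / load_zoo).

sanitize_id <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

#' Save a patch suite to a directory container
#'
#' Writes `manifest.json` plus `<dataset>.csv` (one patch per row, 256
#' columns, `%.17g`) per dataset.
#'
#' @param suite a `patch_suite`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
save_suite <- function(suite, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- attr(suite, "manifest")
  man$file <- paste0(sanitize_id(man$dataset_id), ".csv")
  jsonlite::write_json(list(container = "metanet_suite", version = 1L,
                            datasets = man),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(nrow(man))) {
    pm <- suite[[man$dataset_id[i]]]
    txt <- matrix(sprintf("%.17g", pm), nrow(pm), ncol(pm))
    data.table::fwrite(data.table::as.data.table(txt),
                       file.path(path, man$file[i]),
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a patch suite saved by [save_suite()]
#'
#' @param path container directory.
#' @return A `patch_suite`.
#' @export
load_suite <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_param("missing manifest.json in %s", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$container, "metanet_suite"))
    stop_param("%s is not a metanet suite container", path)
  ds <- man$datasets
  suite <- list()
  for (i in seq_len(nrow(ds))) {
    f <- file.path(path, ds$file[i])
    if (!file.exists(f)) stop_param("suite container missing %s", ds$file[i])
    m <- as.matrix(data.table::fread(f, header = FALSE, colClasses = "numeric"))
    dimnames(m) <- NULL
    suite[[ds$dataset_id[i]]] <- patch_matrix(m, dataset_id = ds$dataset_id[i],
                                              modality = ds$modality[i])
  }
  attr(suite, "manifest") <- data.frame(dataset_id = ds$dataset_id,
                                        modality = ds$modality,
                                        row.names = NULL)
  class(suite) <- "patch_suite"
  suite
}

#' Write zoo embeddings with provenance to CSV
#'
#' @param emb output of [embed_zoo()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  df <- cbind(emb$manifest,
              as.data.frame(matrix(sprintf("%.17g", emb$embeddings),
                                   nrow(emb$embeddings),
                                   ncol(emb$embeddings))))
  names(df)[(ncol(emb$manifest) + 1L):ncol(df)] <-
    paste0("m", seq_len(ncol(emb$embeddings)))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#'
#' @param path CSV file path.
#' @return List with `embeddings` matrix and `manifest` data.frame.
#' @export
read_embeddings <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  mcols <- grep("^m[0-9]+$", names(df))
  list(embeddings = as.matrix(df[, mcols, drop = FALSE]),
       manifest = df[, setdiff(seq_along(df), mcols), drop = FALSE])
}
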