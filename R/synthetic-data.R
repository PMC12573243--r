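# Synthetic two-modality patch generator.
#
# The pipeline's claim is that the second-order statistics of a network's
# training patches leave a recoverable trace in its weights. To test that
# without external corpora we generate two patch families whose covariance
# structure differs the way image patches differ from spectrogram windows:
#
#   modality A ("vision-like"): stationary Gaussian random fields on a
#     16x16 grid with a squared-exponential correlation function. Category
#     parameters: correlation length in pixels, plus an optional
#     anisotropic elongation along a fixed orientation.
#   modality B ("audio-like"): 16 frequency rows x 16 time columns with
#     energy stacked on the harmonic rows of a fundamental, modulated by a
#     temporally smooth AR(1) envelope, plus white background noise.
#
# Every patch is min-max rescaled to [0,1] per patch (constant patches map
# to 0.5), mirroring the 01-normalization of the real-data path.

#' Configuration for one synthetic modality
#'
#' @param modality `"A"` (vision-like Gaussian random fields) or `"B"`
#'   (audio-like harmonic stacks).
#' @param n_categories number of category datasets (>= 2).
#' @param category_params list with one record per category. For modality
#'   A each record has `corr_len` (correlation length, pixels; may be
#'   `Inf`), `aniso_theta` (orientation of the anisotropic axis, radians)
#'   and `aniso_ratio` (elongation factor, 1 = isotropic). For modality B:
#'   `f0` (fundamental row index, 0..15), `n_harmonics` (number of
#'   harmonic rows including the fundamental) and `smooth` (AR(1)
#'   temporal smoothness coefficient in [0, 1)). `NULL` picks the package
#'   defaults for `n_categories` <= 4.
#' @param noise_sd standard deviation of additive white noise before
#'   rescaling (>= 0).
#' @param seed integer seed mixed into every draw from this config.
#' @return A `synthetic_modality_config` object.
#' @export
#' @examples
#' cfg <- synthetic_modality_config("A", n_categories = 2)
synthetic_modality_config <- function(modality = c("A", "B"),
                                      n_categories = 4L,
                                      category_params = NULL,
                                      noise_sd = 0.05,
                                      seed = 1L) {
  modality <- match.arg(modality)
  n_categories <- check_count(n_categories, "n_categories", min = 2L)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(category_params)) {
    category_params <- default_category_params(modality, n_categories)
  }
  if (length(category_params) != n_categories)
    stop_param("need %d category parameter records, got %d",
               n_categories, length(category_params))
  keys <- vapply(category_params, function(p)
    paste(unlist(p), collapse = "|"), character(1))
  if (anyDuplicated(keys))
    stop_param("category parameter records must be pairwise distinct")
  for (p in category_params) validate_category_params(modality, p)
  structure(list(modality = modality, n_categories = n_categories,
                 category_params = category_params, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_modality_config")
}

default_category_params <- function(modality, n) {
  if (modality == "A") {
    pool <- list(
      list(corr_len = 1.0, aniso_theta = 0, aniso_ratio = 1),
      list(corr_len = 2.5, aniso_theta = 0, aniso_ratio = 1),
      list(corr_len = 4.0, aniso_theta = 0, aniso_ratio = 1),
      list(corr_len = 2.0, aniso_theta = 0, aniso_ratio = 2),
      list(corr_len = 2.0, aniso_theta = pi / 2, aniso_ratio = 2),
      list(corr_len = 6.0, aniso_theta = 0, aniso_ratio = 1))
  } else {
    pool <- list(
      list(f0 = 1L, n_harmonics = 4L, smooth = 0.90),
      list(f0 = 2L, n_harmonics = 3L, smooth = 0.85),
      list(f0 = 3L, n_harmonics = 2L, smooth = 0.90),
      list(f0 = 5L, n_harmonics = 3L, smooth = 0.80),
      list(f0 = 4L, n_harmonics = 2L, smooth = 0.95),
      list(f0 = 7L, n_harmonics = 2L, smooth = 0.85))
  }
  if (n > length(pool))
    stop_param("no default parameters for %d categories; supply category_params", n)
  pool[seq_len(n)]
}

validate_category_params <- function(modality, p) {
  if (modality == "A") {
    if (is.null(p$corr_len) || p$corr_len <= 0)
      stop_param("modality A categories need corr_len > 0")
    if (!is.null(p$aniso_ratio) && p$aniso_ratio < 1)
      stop_param("aniso_ratio must be >= 1")
  } else {
    if (is.null(p$f0) || p$f0 < 0 || p$f0 > 15)
      stop_param("modality B categories need f0 in [0, 15]")
    if (is.null(p$n_harmonics) || p$n_harmonics < 1)
      stop_param("modality B categories need n_harmonics >= 1")
    if (is.null(p$smooth) || p$smooth < 0 || p$smooth >= 1)
      stop_param("smooth must be in [0, 1)")
  }
  invisible(TRUE)
}

# squared-exponential covariance over the 16x16 pixel grid, optionally
# elongated by `ratio` along direction `theta`; Cholesky factor cached by
# parameter key since it only depends on the category
grf_chol_cache <- new.env(parent = emptyenv())

grf_chol <- function(corr_len, theta, ratio, size = 16L) {
  key <- paste(corr_len, theta, ratio, size, sep = "_")
  hit <- get0(key, envir = grf_chol_cache)
  if (!is.null(hit)) return(hit)
  idx <- expand.grid(col = seq_len(size), row = seq_len(size))
  dx <- outer(idx$col, idx$col, "-")
  dy <- outer(idx$row, idx$row, "-")
  # rotate into the anisotropy frame, scale the major axis by `ratio`
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  d2 <- (u / ratio)^2 + v^2
  C <- exp(-d2 / (2 * corr_len^2))
  R <- chol(C + diag(1e-8, size * size))
  assign(key, R, envir = grf_chol_cache)
  R
}

#' Generate vision-like synthetic patches
#'
#' Draws `n` stationary Gaussian-random-field patches on a 16x16 grid with
#' the category's correlation structure, adds white noise of
#' `cfg$noise_sd`, and rescales each patch to `[0, 1]` (min-max, constant
#' patches map to 0.5). A category with `corr_len = Inf` degenerates to
#' patches that are constant before rescaling.
#'
#' @param cfg a modality-A [synthetic_modality_config()].
#' @param category 1-based category index.
#' @param n number of patches.
#' @param seed integer seed; output is bit-identical for identical inputs.
#' @return A [patch_matrix()] with `n` rows and 256 columns.
#' @export
gen_vision_like_patches <- function(cfg, category, n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_modality_config"))
  if (cfg$modality != "A") stop_param("cfg is not a modality-A config")
  category <- check_count(category, "category")
  if (category > cfg$n_categories)
    stop_param("category %d out of range (n_categories = %d)",
               category, cfg$n_categories)
  n <- check_count(n, "n")
  p <- cfg$category_params[[category]]
  theta <- if (is.null(p$aniso_theta)) 0 else p$aniso_theta
  ratio <- if (is.null(p$aniso_ratio)) 1 else p$aniso_ratio
  raw <- with_seed(derive_seed(seed, "vision", category, n), {
    field <- if (is.infinite(p$corr_len)) {
      # infinite correlation length: each field is one shared draw per patch
      matrix(stats::rnorm(n), n, 256)
    } else {
      R <- grf_chol(p$corr_len, theta, ratio)
      matrix(stats::rnorm(n * 256), n, 256) %*% R
    }
    if (cfg$noise_sd > 0)
      field <- field + matrix(stats::rnorm(n * 256, sd = cfg$noise_sd), n, 256)
    field
  })
  patch_matrix(rescale01_rows(raw),
               dataset_id = paste0("sv:", category),
               modality = "A")
}

#' Generate audio-like synthetic patches
#'
#' Each patch is a 16 (frequency rows) x 16 (time columns) block. Energy
#' is concentrated on the harmonic rows `f0 * (1, 2, ...)` (0-based row
#' indices, capped at 15) with amplitude decaying as 1/h across
#' harmonics, modulated in time by a stationary AR(1) envelope with the
#' category's smoothness coefficient; white noise of `cfg$noise_sd` is
#' added everywhere. Patches are flattened row-major (row = frequency)
#' and min-max rescaled to `[0, 1]`.
#'
#' @inheritParams gen_vision_like_patches
#' @return A [patch_matrix()] with `n` rows and 256 columns.
#' @export
gen_audio_like_patches <- function(cfg, category, n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_modality_config"))
  if (cfg$modality != "B") stop_param("cfg is not a modality-B config")
  category <- check_count(category, "category")
  if (category > cfg$n_categories)
    stop_param("category %d out of range (n_categories = %d)",
               category, cfg$n_categories)
  n <- check_count(n, "n")
  p <- cfg$category_params[[category]]
  mult <- seq_len(p$n_harmonics)
  rows0 <- p$f0 * mult
  rows0 <- rows0[rows0 <= 15]
  if (p$f0 == 0) rows0 <- 0
  amps <- 1 / seq_along(rows0)
  raw <- with_seed(derive_seed(seed, "audio", category, n), {
    rho <- p$smooth
    innov <- matrix(stats::rnorm(n * 16), n, 16)
    env <- matrix(0, n, 16)
    env[, 1] <- innov[, 1]
    if (rho > 0) {
      sc <- sqrt(1 - rho^2)
      for (t in 2:16) env[, t] <- rho * env[, t - 1] + sc * innov[, t]
    } else {
      env <- innov
    }
    env <- abs(env) + 0.5 # positive amplitude envelope, bounded off zero
    out <- matrix(0, n, 256)
    for (j in seq_along(rows0)) {
      cols <- rows0[j] * 16L + 1:16 # row-major offset of frequency row
      out[, cols] <- out[, cols] + amps[j] * env
    }
    if (cfg$noise_sd > 0)
      out <- out + matrix(stats::rnorm(n * 256, sd = cfg$noise_sd), n, 256)
    out
  })
  patch_matrix(rescale01_rows(raw),
               dataset_id = paste0("sa:", category),
               modality = "B")
}

#' Generate the full synthetic dataset suite
#'
#' One dataset per (modality, category) pair, named `"sv:<k>"` for
#' modality A and `"sa:<k>"` for modality B in analogy to the `v:`/`a:`
#' naming used for real corpora.
#'
#' @param cfgA modality-A config.
#' @param cfgB modality-B config.
#' @param n_patches_per_dataset rows per patch matrix.
#' @param seed integer seed (defaults to mixing the two config seeds).
#' @return Named list of [patch_matrix()] objects, one per dataset, with
#'   attribute `manifest`: a data.frame of dataset_id and modality.
#' @export
make_synthetic_suite <- function(cfgA, cfgB, n_patches_per_dataset = 20000L,
                                 seed = NULL) {
  stopifnot(inherits(cfgA, "synthetic_modality_config"),
            inherits(cfgB, "synthetic_modality_config"))
  if (cfgA$modality != "A" || cfgB$modality != "B")
    stop_param("make_synthetic_suite needs one A and one B config, in order")
  n <- check_count(n_patches_per_dataset, "n_patches_per_dataset")
  if (is.null(seed)) seed <- derive_seed(cfgA$seed, "suite", cfgB$seed)
  suite <- list()
  for (k in seq_len(cfgA$n_categories)) {
    pm <- gen_vision_like_patches(cfgA, k, n, seed = derive_seed(seed, "A", k))
    suite[[attr(pm, "dataset_id")]] <- pm
  }
  for (k in seq_len(cfgB$n_categories)) {
    pm <- gen_audio_like_patches(cfgB, k, n, seed = derive_seed(seed, "B", k))
    suite[[attr(pm, "dataset_id")]] <- pm
  }
  if (anyDuplicated(names(suite)))
    stop_param("duplicate dataset ids in suite")
  attr(suite, "manifest") <- data.frame(
    dataset_id = names(suite),
    modality = vapply(suite, function(p) attr(p, "modality"), character(1)),
    row.names = NULL)
  class(suite) <- "patch_suite"
  suite
}

#' @export
print.patch_suite <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("<patch_suite> %d datasets (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(man$modality)),
                            table(man$modality)), collapse = ", ")))
  for (id in names(x))
    cat(sprintf("  %-8s %s  %d x %d\n", id, attr(x[[id]], "modality"),
                nrow(x[[id]]), ncol(x[[id]])))
  invisible(x)
}
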