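# Shared fixtures (memoized per session) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  hit <- get0(key, envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  val <- build()
  assign(key, val, envir = .fixture_env)
  val
}

tiny_suite <- function() memo("tiny_suite", function() {
  cfgA <- synthetic_modality_config("A", 2, noise_sd = 0.05, seed = 11)
  cfgB <- synthetic_modality_config("B", 2, noise_sd = 0.05, seed = 12)
  make_synthetic_suite(cfgA, cfgB, 600)
})

tiny_zoo <- function() memo("tiny_zoo", function() {
  train_zoo(tiny_suite(), n_models = 5, n_train = 4, base_seed = 21)
})

tiny_meta <- function() memo("tiny_meta", function() {
  zoo <- tiny_zoo()
  uw <- train_unitwise(zoo, epochs = 3, seed = 31)
  iu <- train_interunit(zoo, uw, epochs = 20, seed = 32)
  list(uw = uw, iu = iu)
})

# the default-scale experiment shared by the acceptance criteria
acceptance_run <- function() memo("acceptance_run", function() {
  cfg <- default_config(seed = 20260909,
                        out_dir = file.path(tempdir(), "metanet_acc_run"))
  run_experiment(cfg, use_cache = FALSE, progress = FALSE)
})

# -- independent oracles -----------------------------------------------------

# mean lag-1 spatial autocorrelation of a patch matrix, computed directly
# from the entries of each reshaped 16x16 patch
oracle_lag1_autocorr <- function(pm) {
  vals <- vapply(seq_len(nrow(pm)), function(i) {
    m <- matrix(pm[i, ], 16, 16, byrow = TRUE)
    h <- stats::cor(as.vector(m[, -16]), as.vector(m[, -1]))
    v <- stats::cor(as.vector(m[-16, ]), as.vector(m[-1, ]))
    mean(c(h, v))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# per-row energy (sum of squares) of one flattened audio patch
oracle_row_energy <- function(patch_row) {
  m <- matrix(patch_row, 16, 16, byrow = TRUE)
  rowSums(m^2)
}

# covariance anisotropy: |mean lag-1 correlation along time (columns)
# minus along frequency/space (rows)|
oracle_anisotropy <- function(pm, n_sample = 20) {
  idx <- seq_len(min(n_sample, nrow(pm)))
  vals <- vapply(idx, function(i) {
    m <- matrix(pm[i, ], 16, 16, byrow = TRUE)
    along_col <- stats::cor(as.vector(m[, -16]), as.vector(m[, -1]))
    along_row <- stats::cor(as.vector(m[-16, ]), as.vector(m[-1, ]))
    abs(along_col - along_row)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# brute-force kNN with the package's documented tie rule: full distance
# sort, majority vote, ties by smallest mean neighbour distance then
# lexicographic label
oracle_knn <- function(ref, labels, query, k) {
  apply(query, 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    nn <- order(d)[seq_len(k)]
    nl <- labels[nn]
    counts <- table(nl)
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) {
      means <- vapply(top, function(lb) mean(d[nn[nl == lb]]), numeric(1))
      top <- sort(top[means == min(means)])[1]
    }
    top
  })
}

# mean pairwise euclidean distance between two sets of rows
oracle_mean_cross_dist <- function(A, B) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(A))) {
    d <- sqrt(rowSums((B - matrix(A[i, ], nrow(B), ncol(B), byrow = TRUE))^2))
    s <- s + sum(d); n <- n + length(d)
  }
  s / n
}

oracle_mean_within_dist <- function(A) {
  d <- as.matrix(stats::dist(A))
  mean(d[upper.tri(d)])
}
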