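# Exact t-SNE (no Barnes-Hut approximation).
#
# Evaluation sets here are a few hundred points, so the O(N^2) exact
# gradient is cheap and avoids approximation parameters entirely.
# Standard recipe: perplexity-calibrated Gaussian affinities (binary
# search on the kernel precision per point), symmetrized and normalized;
# Student-t low-dimensional kernel; gradient descent with momentum and
# early exaggeration.

# conditional affinities for one point given squared distances
tsne_point_affinity <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  target <- log(perplexity)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (it in seq_len(max_iter)) {
    p <- exp(-d2 * beta)
    sum_p <- sum(p)
    if (sum_p == 0) { h <- 0; pn <- p }
    else {
      pn <- p / sum_p
      h <- -sum(pn[pn > 0] * log(pn[pn > 0]))
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  pn
}

#' 2-D t-SNE coordinates of an embedding matrix
#'
#' @param embeddings numeric matrix, one point per row.
#' @param perplexity Gaussian neighbourhood size; requires
#'   `nrow(embeddings) > 3 * perplexity` (replication setting: 30).
#' @param seed integer seed for the random initialization.
#' @param n_iter gradient-descent iterations.
#' @return N x 2 matrix of coordinates (rows aligned with input).
#' @export
tsne_coords <- function(embeddings, perplexity = 30, seed = 1L,
                        n_iter = 500L) {
  if (!is.matrix(embeddings)) embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  perplexity <- check_number(perplexity, "perplexity", min = 1)
  if (n <= 3 * perplexity)
    stop_param("perplexity %g too large for %d points (need n > 3*perplexity)",
               perplexity, n)
  d2 <- as.matrix(stats::dist(embeddings))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, -i] <- tsne_point_affinity(d2[i, -i], perplexity)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  with_seed(derive_seed(seed, "tsne"), {
    Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
    G <- matrix(0, n, 2L)
    gains <- matrix(1, n, 2L)
    eta <- 200
    for (it in seq_len(n_iter)) {
      mult <- if (it <= 100L) 12 else 1 # early exaggeration
      momentum <- if (it <= 250L) 0.5 else 0.8
      qnum <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(qnum) <- 0
      Q <- qnum / sum(qnum)
      Q[Q < 1e-12] <- 1e-12
      L <- (mult * P - Q) * qnum
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      G <- momentum * G - eta * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
  })
}
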