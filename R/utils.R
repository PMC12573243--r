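#' @keywords internal
#' @useDynLib metanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the default RNG with `seed`,
#' evaluates `code`, and restores the previous RNG state so that library
#' calls never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a base seed and arbitrary labels
#'
#' Deterministic 31-bit hash mixing the base seed with any number of
#' integer or character labels (dataset ids, replicate indices, stage
#' names). Used so that every stochastic stage has a reproducible stream
#' that depends only on its identity, never on execution order.
#'
#' @param base_seed integer.
#' @param ... integers or strings to mix in.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "sv:1", 7)
derive_seed <- function(base_seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(base_seed) %% m
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(paste(lab, collapse = "\r")) else as.numeric(lab)
    for (v in codes) {
      h <- (h * 48271 + (v %% m) + 11) %% m
    }
    h <- (h * 69621 + 1) %% m
  }
  as.integer(h)
}

#' Polynomial hash of a character string
#'
#' 31-bit rolling hash used for config fingerprints in run manifests.
#' Not cryptographic; only change detection matters here.
#'
#' @param x character scalar.
#' @return Hex string of 8 characters.
#' @keywords internal
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 7
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Fingerprint an R object for stage caching
#' @param x any jsonlite-serializable object.
#' @return Hex string.
#' @keywords internal
config_hash <- function(x) {
  str_hash31(as.character(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)))
}

# Parameter checking helpers ------------------------------------------------

stop_param <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_param("`%s` must be a single integer >= %d (got %s)", name, min,
               paste(format(x), collapse = ","))
  as.integer(x)
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop_param("`%s` must be a single number >= %g", name, min)
  as.numeric(x)
}

#' Min-max rescale a vector to `[0, 1]` with a zero-range guard
#'
#' Constant input maps to 0.5 everywhere, so degenerate patches (uniform
#' images, silence) stay inside the contract rather than producing NaN.
#'
#' @param x numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @keywords internal
rescale01 <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) stop_param("non-finite values in rescale01 input")
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Row-wise min-max rescale of a matrix to `[0, 1]`
#' @param m numeric matrix.
#' @return matrix of the same shape with each row in `[0, 1]`.
#' @keywords internal
rescale01_rows <- function(m) {
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  out <- (m - lo) / rng
  if (any(const)) out[const, ] <- 0.5
  out
}
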