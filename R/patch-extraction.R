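# Patch extraction from real images and audio.
#
# Both modalities are funnelled into the same 256-dimensional patch
# format: images become grayscale 16x16 crops, audio becomes 16-mel-bin
# spectrogram windows of 16 frames. Flattening is row-major (for audio:
# frequency rows major), which must match the 16x16 reshape used by the
# meta-autoencoder's filter images.

#' Construct and validate a patch matrix
#'
#' @param values numeric matrix, N x 256, entries in `[0, 1]`.
#' @param dataset_id dataset identifier (see [make_dataset_id()]).
#' @param modality modality tag (`"vision"`, `"audio"`, `"A"`, `"B"`).
#' @return The validated matrix with class `patch_matrix` and attributes
#'   `dataset_id` and `modality`.
#' @export
patch_matrix <- function(values, dataset_id = "unknown", modality = "vision") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_param("patch matrix must be a numeric matrix")
  if (ncol(values) != 256L)
    stop_param("patch rows must have length 256, got %d", ncol(values))
  if (nrow(values) < 1L) stop_param("patch matrix needs at least one row")
  if (anyNA(values) || !all(is.finite(values)))
    stop_param("patch matrix contains non-finite values")
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 1)
    stop_param("patch values must lie in [0, 1] (range %g..%g)", rng[1], rng[2])
  structure(values, dataset_id = dataset_id, modality = modality,
            class = c("patch_matrix", "matrix", "array"))
}

#' @export
print.patch_matrix <- function(x, ...) {
  cat(sprintf("<patch_matrix> %s (%s): %d patches of 256\n",
              attr(x, "dataset_id"), attr(x, "modality"), nrow(x)))
  invisible(x)
}

#' Dataset naming convention
#'
#' `"v:"` or `"a:"` plus the first three letters of the class name
#' (lowercased); names shorter than three characters are used whole.
#'
#' @param modality `"vision"` or `"audio"`.
#' @param class_name non-empty class name, e.g. `"aeroplane"`.
#' @return A dataset id string such as `"v:aer"`.
#' @export
#' @examples
#' make_dataset_id("vision", "aeroplane") # "v:aer"
#' make_dataset_id("audio", "air-conditioner") # "a:air"
make_dataset_id <- function(modality = c("vision", "audio"), class_name) {
  modality <- match.arg(modality)
  if (!is.character(class_name) || length(class_name) != 1L ||
      !nzchar(class_name))
    stop_param("class_name must be a non-empty string")
  stem <- tolower(substr(class_name, 1L, 3L))
  paste0(if (modality == "vision") "v:" else "a:", stem)
}

#' Extract random 16x16 patches from an image
#'
#' The image is converted to grayscale (luminance weights
#' 0.299/0.587/0.114 for 3-channel input), min-max normalized to `[0, 1]`
#' per image (constant images map to 0.5), and `n_patches` 16x16 crops
#' are sampled uniformly with replacement and flattened row-major.
#'
#' @param image numeric matrix (grayscale) or H x W x 3 array.
#' @param n_patches number of patches.
#' @param seed integer seed.
#' @param dataset_id,modality provenance carried on the result.
#' @return A [patch_matrix()].
#' @export
image_to_patches <- function(image, n_patches, seed = 1L,
                             dataset_id = "unknown", modality = "vision") {
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] < 3L) image <- image[, , 1L]
    else image <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
        0.114 * image[, , 3L]
  }
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop_param("image must be a numeric matrix or H x W x 3 array")
  h <- nrow(image); w <- ncol(image)
  if (h < 16L || w < 16L)
    stop_param("image must be at least 16x16 (got %dx%d)", h, w)
  n_patches <- check_count(n_patches, "n_patches")
  img <- matrix(rescale01(image), h, w)
  out <- with_seed(derive_seed(seed, "imgpatch", n_patches), {
    r0 <- sample.int(h - 15L, n_patches, replace = TRUE)
    c0 <- sample.int(w - 15L, n_patches, replace = TRUE)
    m <- matrix(0, n_patches, 256L)
    for (i in seq_len(n_patches)) {
      # row-major flatten: 16 consecutive row segments of 16 pixels
      m[i, ] <- as.vector(t(img[r0[i]:(r0[i] + 15L), c0[i]:(c0[i] + 15L)]))
    }
    m
  })
  patch_matrix(out, dataset_id = dataset_id, modality = modality)
}

#' Mel filter bank
#'
#' Standard triangular filters on mel-spaced center frequencies
#' (HTK mel scale, 2595 log10(1 + f/700)), spanning 0..sr/2.
#'
#' @param n_mels number of mel bins.
#' @param n_fft FFT length.
#' @param sr sample rate in Hz.
#' @return `n_mels` x `(n_fft/2 + 1)` filter matrix.
#' @export
mel_filterbank <- function(n_mels = 16L, n_fft = 1024L, sr) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2L + 1L
  freqs <- seq(0, sr / 2, length.out = n_bins)
  pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sr / 2),
                       length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel spectrogram of a waveform
#'
#' Hann-windowed STFT magnitudes pooled through [mel_filterbank()], then
#' log-compressed. Frames shorter than `n_fft` at the tail are dropped.
#'
#' @param wave numeric waveform.
#' @param sr sample rate in Hz.
#' @param n_mels,n_fft,hop spectrogram parameters.
#' @return `n_mels` x n_frames matrix of log mel magnitudes.
#' @export
mel_spectrogram <- function(wave, sr, n_mels = 16L, n_fft = 1024L,
                            hop = 512L) {
  if (!is.numeric(wave) || length(wave) < n_fft)
    stop_param("waveform shorter than one FFT frame (%d samples)", n_fft)
  n_frames <- (length(wave) - n_fft) %/% hop + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_fft) / n_fft)
  n_bins <- n_fft %/% 2L + 1L
  frames <- matrix(0, n_fft, n_frames)
  for (t in seq_len(n_frames)) {
    frames[, t] <- wave[((t - 1L) * hop + 1L):((t - 1L) * hop + n_fft)] * win
  }
  spec <- abs(stats::mvfft(frames))[seq_len(n_bins), , drop = FALSE]
  fb <- mel_filterbank(n_mels, n_fft, sr)
  log(fb %*% spec + 1e-10)
}

#' Extract random 16x16 spectrogram windows from audio
#'
#' Converts the waveform to a 16-mel-bin log spectrogram, min-max
#' normalizes the whole spectrogram to `[0, 1]` (silence maps to 0.5),
#' then samples `n_patches` windows of 16 consecutive frames uniformly
#' with replacement. Each 16x16 block (rows = mel bins) is flattened
#' row-major.
#'
#' @param wave numeric waveform.
#' @param sr sample rate in Hz.
#' @param n_patches number of windows.
#' @param seed integer seed.
#' @param n_fft,hop STFT parameters.
#' @param dataset_id,modality provenance carried on the result.
#' @return A [patch_matrix()].
#' @export
audio_to_patches <- function(wave, sr, n_patches, seed = 1L,
                             n_fft = 1024L, hop = 512L,
                             dataset_id = "unknown", modality = "audio") {
  n_patches <- check_count(n_patches, "n_patches")
  spec <- mel_spectrogram(wave, sr, n_mels = 16L, n_fft = n_fft, hop = hop)
  if (ncol(spec) < 16L)
    stop_param("clip too short: %d spectrogram frames, need >= 16", ncol(spec))
  spec <- matrix(rescale01(spec), nrow(spec), ncol(spec))
  out <- with_seed(derive_seed(seed, "audpatch", n_patches), {
    t0 <- sample.int(ncol(spec) - 15L, n_patches, replace = TRUE)
    m <- matrix(0, n_patches, 256L)
    for (i in seq_len(n_patches)) {
      m[i, ] <- as.vector(t(spec[, t0[i]:(t0[i] + 15L)]))
    }
    m
  })
  patch_matrix(out, dataset_id = dataset_id, modality = modality)
}

# -- plain-format readers ----------------------------------------------------
# Only uncompressed formats are supported (no PNG/JPEG codecs in the
# dependency footprint): PGM/PPM for images, PCM WAV for audio.

#' Read a PGM or PPM image
#'
#' Supports plain (P2/P3) and binary (P5/P6) variants with 8-bit depth.
#'
#' @param path file path.
#' @return Numeric matrix (PGM) or H x W x 3 array (PPM), values in `[0,1]`.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_param("unsupported PNM magic '%s' in %s", magic, path)
  tokens <- character(0)
  while (length(tokens) < 3L) {
    line <- readLines(con, 1L)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE))
  } else {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  }
  vals <- vals / maxval
  if (nch == 1L) {
    matrix(vals, h, w, byrow = TRUE)
  } else {
    arr <- array(0, c(h, w, 3L))
    for (ch in 1:3) arr[, , ch] <- matrix(vals[seq(ch, n, by = 3L)], h, w,
                                          byrow = TRUE)
    arr
  }
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 8- or 16-bit PCM; channels
#' are averaged to mono.
#'
#' @param path file path.
#' @return List with `wave` (numeric in `[-1, 1]`) and `sr` (sample rate).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stop_param("%s is not a RIFF file", path)
  readBin(con, "integer", 1L, 4L)
  if (readChar(con, 4L) != "WAVE") stop_param("%s is not a WAVE file", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1L, 4L)
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", sz %/% 2L, 2L, signed = FALSE)
      if (sz %% 2L) readBin(con, "raw", 1L)
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
      if (sz %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop_param("missing fmt/data chunk in %s", path)
  audio_format <- fmt[1]
  n_channels <- fmt[2]
  sr <- fmt[3] + fmt[4] * 65536
  bits <- fmt[8]
  if (audio_format != 1L) stop_param("only PCM WAV supported (format %d)", audio_format)
  wave <- if (bits == 16L) {
    readBin(data, "integer", length(data) %/% 2L, 2L, signed = TRUE) / 32768
  } else if (bits == 8L) {
    (as.numeric(readBin(data, "integer", length(data), 1L, signed = FALSE)) - 128) / 128
  } else stop_param("unsupported bit depth %d", bits)
  if (n_channels > 1L) {
    nf <- length(wave) %/% n_channels
    wave <- rowMeans(matrix(wave[seq_len(nf * n_channels)], nf,
                            n_channels, byrow = TRUE))
  }
  list(wave = wave, sr = sr)
}

#' Build patch matrices for a directory of class folders
#'
#' Each subdirectory of `dir` is one class dataset; its files are read
#' (PGM/PPM for vision, WAV for audio), patches are pooled across files
#' proportionally, and one [patch_matrix()] per class is returned.
#'
#' @param dir directory with one subdirectory per class.
#' @param modality `"vision"` or `"audio"`.
#' @param n_patches patches per class dataset.
#' @param seed integer seed.
#' @return Named list of [patch_matrix()] (a `patch_suite`).
#' @export
dir_to_suite <- function(dir, modality = c("vision", "audio"),
                         n_patches = 20000L, seed = 1L) {
  modality <- match.arg(modality)
  classes <- list.dirs(dir, recursive = FALSE)
  if (length(classes) == 0L) stop_param("no class subdirectories in %s", dir)
  suite <- list()
  for (cls in classes) {
    id <- make_dataset_id(modality, basename(cls))
    pat <- if (modality == "vision") "\\.(pgm|ppm|pnm)$" else "\\.wav$"
    files <- list.files(cls, pattern = pat, full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) {
      warning("no readable files in ", cls, "; skipping")
      next
    }
    per <- diff(round(seq(0, n_patches, length.out = length(files) + 1L)))
    parts <- list()
    for (i in seq_along(files)) {
      if (per[i] == 0L) next
      fseed <- derive_seed(seed, id, i)
      parts[[length(parts) + 1L]] <- tryCatch({
        if (modality == "vision") {
          image_to_patches(read_pnm(files[i]), per[i], seed = fseed,
                           dataset_id = id, modality = modality)
        } else {
          au <- read_wav(files[i])
          audio_to_patches(au$wave, au$sr, per[i], seed = fseed,
                           dataset_id = id, modality = modality)
        }
      }, error = function(e) {
        warning("skipping ", files[i], ": ", conditionMessage(e))
        NULL
      })
    }
    parts <- Filter(Negate(is.null), parts)
    if (length(parts) == 0L) next
    suite[[id]] <- patch_matrix(do.call(rbind, parts), dataset_id = id,
                                modality = modality)
  }
  attr(suite, "manifest") <- data.frame(
    dataset_id = names(suite),
    modality = vapply(suite, function(p) attr(p, "modality"), character(1)),
    row.names = NULL)
  class(suite) <- "patch_suite"
  suite
}
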