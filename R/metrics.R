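# Statistical security evaluation of (plaintext, ciphertext) pairs: MSE,
# PSNR, Shannon entropy, adjacent-pixel correlation, GLCM energy/contrast,
# plus salt-and-pepper noise-attack trials.

#' Mean squared error between two images
#'
#' @param a,b Integer image matrices of equal dimensions, values 0..255.
#' @return Mean of squared pixel differences (intensity^2).
#' @export
img_mse <- function(a, b) {
  .validate_image(a, "a"); .validate_image(b, "b")
  if (!all(dim(a) == dim(b))) stop("images must have equal dimensions", call. = FALSE)
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(255^2 / MSE)`; identical images (MSE 0) report `Inf`.
#'
#' @inheritParams img_mse
#' @return PSNR in dB.
#' @export
img_psnr <- function(a, b) {
  m <- img_mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Shannon entropy of an 8-bit image
#'
#' `-sum(p_i * log2(p_i))` over the 256-level intensity histogram, with
#' `0 * log(0) = 0`. The ideal value for an 8-bit ciphertext is 8 bits.
#'
#' @param img Integer image matrix, values 0..255.
#' @return Entropy in bits, in `[0, 8]`.
#' @export
shannon_entropy <- function(img) {
  .validate_image(img)
  p <- tabulate(as.integer(img) + 1L, nbins = 256L) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Correlation of adjacent pixel pairs
#'
#' Pearson correlation over all adjacent pixel pairs in the given direction.
#' A natural image scores close to 1; a well-encrypted one close to 0.
#'
#' @param img Integer image matrix.
#' @param direction `"horizontal"` (right neighbor), `"vertical"` (below) or
#'   `"diagonal"` (below-right).
#' @return Correlation coefficient in `[-1, 1]`, or `NA` (with a warning) for
#'   a degenerate (constant) image.
#' @export
adjacent_correlation <- function(img,
                                 direction = c("horizontal", "vertical", "diagonal")) {
  .validate_image(img)
  direction <- match.arg(direction)
  n <- nrow(img); m <- ncol(img)
  pair <- switch(direction,
    horizontal = {
      if (m < 2L) stop("need at least 2 columns", call. = FALSE)
      list(img[, -m, drop = FALSE], img[, -1L, drop = FALSE])
    },
    vertical = {
      if (n < 2L) stop("need at least 2 rows", call. = FALSE)
      list(img[-n, , drop = FALSE], img[-1L, , drop = FALSE])
    },
    diagonal = {
      if (n < 2L || m < 2L) stop("need at least 2 rows and columns", call. = FALSE)
      list(img[-n, -m, drop = FALSE], img[-1L, -1L, drop = FALSE])
    }
  )
  x <- as.numeric(pair[[1L]]); y <- as.numeric(pair[[2L]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for constant image")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' GLCM energy and contrast
#'
#' Quantizes intensities to `levels` gray levels via
#' `floor(p * levels / 256)`, builds the normalized (unsymmetric) gray-level
#' co-occurrence matrix for the given neighbor offset, and returns
#' `energy = sum(P^2)` and `contrast = sum((i - j)^2 * P)`. With the default
#' 8 levels and one-pixel horizontal offset an ideal ciphertext scores energy
#' close to 1/64 and contrast close to 10.5.
#'
#' @param img Integer image matrix.
#' @param levels Number of quantization levels (>= 2; default 8).
#' @param offset Integer `(row, col)` neighbor displacement; default `c(0, 1)`
#'   (one step right).
#' @return Named numeric vector `c(energy = , contrast = )`.
#' @export
glcm_features <- function(img, levels = 8L, offset = c(0L, 1L)) {
  .validate_image(img)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  dr <- as.integer(offset[1L]); dc <- as.integer(offset[2L])
  if (dr == 0L && dc == 0L) stop("offset must be nonzero", call. = FALSE)
  n <- nrow(img); m <- ncol(img)
  if (abs(dr) >= n || abs(dc) >= m) {
    stop("image smaller than the requested offset", call. = FALSE)
  }
  q <- matrix(as.integer(floor(as.numeric(img) * levels / 256)), n, m)

  rows <- seq_len(n - abs(dr)); cols <- seq_len(m - abs(dc))
  r1 <- if (dr >= 0L) rows else rows + abs(dr)
  c1 <- if (dc >= 0L) cols else cols + abs(dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]

  idx <- as.integer(a) * levels + as.integer(b) + 1L
  counts <- tabulate(idx, nbins = levels * levels)
  p <- counts / sum(counts)
  diff2 <- (rep(0:(levels - 1L), each = levels) - rep(0:(levels - 1L), levels))^2
  c(energy = sum(p^2), contrast = sum(diff2 * p))
}

#' Full security report for a (plaintext, ciphertext) pair
#'
#' Bundles the whole metric suite: MSE and PSNR between the pair, and entropy,
#' adjacent-pixel correlation (all three directions) and GLCM energy/contrast
#' of the ciphertext. Wall-clock time of the metric computation is included
#' for information only — it is hardware-dependent and never asserted.
#'
#' @param plain,cipher Integer image matrices of equal dimensions.
#' @param levels GLCM quantization levels (default 8).
#' @return Object of class `security_report`: a list with fields `mse`,
#'   `psnr_db`, `entropy_bits`, `correlation` (list `h`, `v`, `d`), `energy`,
#'   `contrast`, `elapsed_s`.
#' @export
security_report <- function(plain, cipher, levels = 8L) {
  .validate_image(plain, "plain"); .validate_image(cipher, "cipher")
  if (!all(dim(plain) == dim(cipher))) {
    stop("images must have equal dimensions", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  g <- glcm_features(cipher, levels = levels)
  rep <- list(
    mse = img_mse(plain, cipher),
    psnr_db = img_psnr(plain, cipher),
    entropy_bits = shannon_entropy(cipher),
    correlation = list(
      h = adjacent_correlation(cipher, "horizontal"),
      v = adjacent_correlation(cipher, "vertical"),
      d = adjacent_correlation(cipher, "diagonal")
    ),
    energy = unname(g[["energy"]]),
    contrast = unname(g[["contrast"]]),
    elapsed_s = NA_real_
  )
  rep$elapsed_s <- proc.time()[["elapsed"]] - t0
  structure(rep, class = "security_report")
}

#' @export
print.security_report <- function(x, digits = 4, ...) {
  cat("<security_report>\n")
  cat("  MSE:        ", format(x$mse, digits = digits), "\n")
  cat("  PSNR (dB):  ", format(x$psnr_db, digits = digits), "\n")
  cat("  Entropy:    ", format(x$entropy_bits, digits = 6), "bits\n")
  cat("  Correlation: h =", format(x$correlation$h, digits = digits),
      " v =", format(x$correlation$v, digits = digits),
      " d =", format(x$correlation$d, digits = digits), "\n")
  cat("  GLCM energy:", format(x$energy, digits = digits),
      " contrast:", format(x$contrast, digits = digits), "\n")
  invisible(x)
}

#' @export
as.data.frame.security_report <- function(x, ...) {
  data.frame(
    mse = x$mse, psnr_db = x$psnr_db, entropy_bits = x$entropy_bits,
    corr_h = x$correlation$h, corr_v = x$correlation$v, corr_d = x$correlation$d,
    energy = x$energy, contrast = x$contrast, elapsed_s = x$elapsed_s
  )
}

#' Write / read a security report as JSON
#'
#' Infinite PSNR (identical images) is stored as the string `"Inf"` so the
#' JSON round trip is lossless.
#'
#' @param report A `security_report`.
#' @param path Output file path.
#' @return `write_security_report` returns `path` invisibly;
#'   `read_security_report` returns the reconstructed `security_report`.
#' @export
write_security_report <- function(report, path) {
  stopifnot(inherits(report, "security_report"))
  out <- unclass(report)
  if (is.infinite(out$psnr_db)) out$psnr_db <- "Inf"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_security_report
#' @export
read_security_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$psnr_db, "Inf")) x$psnr_db <- Inf
  x$correlation <- as.list(x$correlation)
  structure(x, class = "security_report")
}

# run code with a private, seeded RNG stream, leaving the session RNG alone
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Add salt-and-pepper noise
#'
#' Each pixel is independently corrupted with probability `density`; a
#' corrupted pixel becomes 0 or 255 with equal odds. Seeded and reproducible;
#' the session RNG state is left untouched.
#'
#' @param img Integer image matrix.
#' @param density Corruption probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted image.
#' @export
salt_pepper <- function(img, density, seed = 1L) {
  .validate_image(img)
  if (!is.numeric(density) || density < 0 || density > 1) {
    stop("density must lie in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    n <- length(img)
    hit <- stats::runif(n) < density
    val <- ifelse(stats::runif(n) < 0.5, 0L, 255L)
    out <- img
    out[hit] <- val[hit]
    out
  })
}

#' Noise-attack trial: encrypt, corrupt, decrypt
#'
#' Encrypts `img`, adds salt-and-pepper noise of the given density to the
#' ciphertext, decrypts with the correct key, and reports how much of the
#' plaintext survives. Because the cipher is a position permutation plus a
#' stateless per-pixel SP-box, each corrupted ciphertext pixel damages exactly
#' one plaintext pixel — noise is not amplified, so the recovered image stays
#' recognizable.
#'
#' @param img Plaintext image matrix.
#' @param key An `encryption_key` or hex string.
#' @param density Salt-and-pepper density in `[0, 1]`.
#' @param seed Integer seed for the noise.
#' @param cfg Optional [generator_config()].
#' @return List with `psnr_db` (decrypted vs plaintext), `diff_fraction`
#'   (fraction of differing plaintext pixels) and `density`.
#' @export
noise_attack_trial <- function(img, key, density, seed = 1L, cfg = NULL) {
  .validate_image(img)
  cipher <- encrypt_image(img, key, cfg)
  noisy <- salt_pepper(cipher, density, seed)
  dec <- decrypt_image(noisy, key, cfg)
  list(
    psnr_db = img_psnr(dec, img),
    diff_fraction = mean(dec != img),
    density = density
  )
}
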