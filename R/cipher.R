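# Two-stage image cipher: a pixel-position permutation (P-box) driven by the
# raw OP4w stream, followed by a per-pixel substitution + DNA-complement bit
# permutation (SP-box) driven by the OP4x and OP4y byte streams. Images are
# linearized in row-major scan order.

.validate_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`", name, "` must be a numeric matrix", call. = FALSE)
  }
  if (any(is.na(img)) || any(img < 0) || any(img > 255) || any(img != floor(img))) {
    stop("`", name, "` must hold 8-bit intensities (integers 0..255)", call. = FALSE)
  }
  invisible(img)
}

# row-major linearization and its inverse
.img_to_vec <- function(img) as.integer(t(img))
.vec_to_img <- function(v, n_row, n_col) matrix(v, n_row, n_col, byrow = TRUE)

#' Build a P-box permutation plan from a raw keystream
#'
#' Swap step `t` (for `t = 1 .. N*M`) exchanges the pixel at scan-order
#' position `t` with the target position `1 + floor(u_t * N*M)` taken from the
#' next raw unit-interval keystream value. A sequence of transpositions is a
#' bijection by construction and is exactly invertible by replaying the swaps
#' in reverse order.
#'
#' @param raw_w Numeric vector of unit-interval keystream values, length at
#'   least `n_row * n_col`.
#' @param n_row,n_col Image dimensions.
#' @return An object of class `permutation_plan` with 1-based `target`
#'   positions, one per swap step.
#' @export
build_permutation <- function(raw_w, n_row, n_col) {
  n <- as.integer(n_row) * as.integer(n_col)
  if (n < 1L) stop("image must have at least one pixel", call. = FALSE)
  if (length(raw_w) < n) {
    stop("keystream exhausted: need ", n, " values, got ", length(raw_w),
         call. = FALSE)
  }
  u <- raw_w[seq_len(n)]
  if (any(u < 0) || any(u >= 1)) stop("raw_w values must lie in [0, 1)", call. = FALSE)
  target <- pmin(as.integer(floor(u * n)), n - 1L) + 1L
  structure(
    list(n_row = as.integer(n_row), n_col = as.integer(n_col), target = target),
    class = "permutation_plan"
  )
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat("<permutation_plan> ", x$n_row, "x", x$n_col,
      " (", length(x$target), " swaps)\n", sep = "")
  invisible(x)
}

#' Apply (or undo) a P-box permutation plan
#'
#' @param img Integer image matrix.
#' @param plan A `permutation_plan` from `build_permutation()`, built for
#'   `img`'s dimensions.
#' @param inverse If `TRUE`, replay the swaps in reverse order, undoing the
#'   forward permutation exactly.
#' @return The permuted image; the multiset of pixel values (and hence the
#'   histogram) is unchanged.
#' @export
apply_permutation <- function(img, plan, inverse = FALSE) {
  .validate_image(img)
  stopifnot(inherits(plan, "permutation_plan"))
  if (nrow(img) != plan$n_row || ncol(img) != plan$n_col) {
    stop("plan was built for ", plan$n_row, "x", plan$n_col,
         " but image is ", nrow(img), "x", ncol(img), call. = FALSE)
  }
  v <- cpp_apply_swaps(.img_to_vec(img), plan$target - 1L, isTRUE(inverse))
  .vec_to_img(v, plan$n_row, plan$n_col)
}

# --- DNA-coded bit permutation -------------------------------------------

# The 8 canonical 2-bit <-> base codings. Row r gives the 2-bit codes of
# (A, C, G, T); in every rule Watson-Crick complementation (A<->T, C<->G)
# corresponds to flipping both bits of the code.
.dna_rule_codes <- rbind(
  c(0L, 1L, 2L, 3L),
  c(0L, 2L, 1L, 3L),
  c(1L, 0L, 3L, 2L),
  c(1L, 3L, 0L, 2L),
  c(2L, 0L, 3L, 1L),
  c(2L, 3L, 0L, 1L),
  c(3L, 1L, 2L, 0L),
  c(3L, 2L, 1L, 0L)
)

#' The eight canonical DNA coding rules
#'
#' Each rule is a bijection between 2-bit values and the bases A, C, G, T in
#' which the Watson-Crick complement (A<->T, C<->G) is the bitwise complement
#' of the code — the defining property of the canonical rules.
#'
#' @return An 8x4 integer matrix; row `r`, column `b` is the 2-bit code that
#'   rule `r` assigns to base `b` (bases ordered A, C, G, T).
#' @export
dna_rules <- function() {
  m <- .dna_rule_codes
  colnames(m) <- c("A", "C", "G", "T")
  m
}

# DNA stage for one key byte ky, vectorized over the input bytes:
# split into four 2-bit groups (MSB first), encode as bases under rule
# (ky mod 8), complement each base, rotate the base string left by
# ((ky >> 3) mod 4), decode under the same rule, reassemble.
.dna_stage <- function(bytes, ky) {
  rule <- .dna_rule_codes[(ky %% 8L) + 1L, ]      # base -> code
  decode <- integer(4L); decode[rule + 1L] <- 0:3 # code -> base
  rot <- (ky %/% 8L) %% 4L

  g <- cbind(bytes %/% 64L, (bytes %/% 16L) %% 4L,
             (bytes %/% 4L) %% 4L, bytes %% 4L)
  bases <- matrix(decode[g + 1L], ncol = 4L)       # 2-bit groups -> bases
  bases <- 3L - bases                              # Watson-Crick complement
  if (rot > 0L) bases <- bases[, c((rot + 1L):4L, 1L:rot), drop = FALSE]
  codes <- matrix(rule[bases + 1L], ncol = 4L)     # bases -> 2-bit groups
  codes[, 1L] * 64L + codes[, 2L] * 16L + codes[, 3L] * 4L + codes[, 4L]
}

# Lazily built 256x256 lookup tables: entry [p+1, ky+1] is the DNA stage
# output (forward) or its inverse. The stage depends on ky only; caching the
# full table makes whole-image encryption a single vectorized lookup.
.cipher_cache <- new.env(parent = emptyenv())

.dna_tables <- function() {
  if (is.null(.cipher_cache$fwd)) {
    fwd <- matrix(0L, 256L, 256L)
    for (ky in 0:255) fwd[, ky + 1L] <- .dna_stage(0:255, ky)
    inv <- matrix(0L, 256L, 256L)
    for (ky in 0:255) inv[fwd[, ky + 1L] + 1L, ky + 1L] <- 0:255
    .cipher_cache$fwd <- fwd
    .cipher_cache$inv <- inv
  }
  list(fwd = .cipher_cache$fwd, inv = .cipher_cache$inv)
}

#' SP-box: per-pixel substitution and DNA-coded bit permutation
#'
#' Forward direction: the pixel is substituted by XOR with the key byte `kx`,
#' then the result is encoded as four DNA bases under rule `ky mod 8`, each
#' base is replaced by its Watson-Crick complement, the base string is rotated
#' left by `(ky >> 3) mod 4` positions, and the string is decoded under the
#' same rule. The inverse applies the exact reverse. Total and bijective on
#' bytes for every `(kx, ky)`.
#'
#' @param p Pixel value(s), 0..255.
#' @param kx Substitution key byte(s) from stream x.
#' @param ky Bit-permutation key byte(s) from stream y.
#' @param inverse If `TRUE`, invert the transformation.
#' @return Integer vector of transformed pixel values.
#' @export
sp_box_pixel <- function(p, kx, ky, inverse = FALSE) {
  p <- as.integer(p); kx <- as.integer(kx); ky <- as.integer(ky)
  for (v in list(p, kx, ky)) {
    if (any(is.na(v)) || any(v < 0L) || any(v > 255L)) {
      stop("pixel and key bytes must lie in 0..255", call. = FALSE)
    }
  }
  tabs <- .dna_tables()
  if (!inverse) {
    c_ <- bitwXor(p, kx)
    tabs$fwd[cbind(c_ + 1L, ky + 1L)]
  } else {
    bitwXor(tabs$inv[cbind(p + 1L, ky + 1L)], kx)
  }
}

.keystreams_for <- function(key, cfg, n) {
  if (is.null(cfg)) cfg <- generator_config()
  generate_keystream(init_generator(key, cfg), n)
}

#' Encrypt an 8-bit grayscale image
#'
#' Expands the key into one keystream pass per pixel, permutes pixel positions
#' with the P-box (raw OP4w stream), then applies the SP-box to every pixel in
#' scan order (OP4x substitution bytes, OP4y bit-permutation bytes).
#'
#' @param img Integer matrix with values 0..255.
#' @param key An `encryption_key` or 16-hex-character string.
#' @param cfg Optional [generator_config()]; `NULL` for defaults.
#' @return Ciphertext image of the same dimensions.
#' @seealso [decrypt_image()]
#' @export
encrypt_image <- function(img, key, cfg = NULL) {
  .validate_image(img)
  n <- nrow(img) * ncol(img)
  ks <- .keystreams_for(key, cfg, n)
  plan <- build_permutation(ks$w_raw, nrow(img), ncol(img))
  v <- cpp_apply_swaps(.img_to_vec(img), plan$target - 1L, FALSE)
  v <- sp_box_pixel(v, ks$x, ks$y, inverse = FALSE)
  .vec_to_img(v, nrow(img), ncol(img))
}

#' Decrypt an 8-bit grayscale image
#'
#' Regenerates the same keystreams from the key, inverts the SP-box on every
#' pixel, then undoes the P-box by replaying its swaps in reverse order.
#' Exact inverse of [encrypt_image()] under the same key and configuration.
#'
#' @inheritParams encrypt_image
#' @param img Ciphertext matrix produced by [encrypt_image()].
#' @return The recovered plaintext image.
#' @export
decrypt_image <- function(img, key, cfg = NULL) {
  .validate_image(img)
  n <- nrow(img) * ncol(img)
  ks <- .keystreams_for(key, cfg, n)
  v <- sp_box_pixel(.img_to_vec(img), ks$x, ks$y, inverse = TRUE)
  plan <- build_permutation(ks$w_raw, nrow(img), ncol(img))
  v <- cpp_apply_swaps(v, plan$target - 1L, TRUE)
  .vec_to_img(v, nrow(img), ncol(img))
}
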