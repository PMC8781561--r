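# 64-bit encryption keys: parsing and the 32-bit-half -> unit-interval mapping.

#' Parse a 64-bit encryption key
#'
#' Accepts exactly 16 hexadecimal characters (an optional `0x` prefix is
#' allowed) and splits the 64-bit value into its two 32-bit halves: the first
#' half seeds the generator's neuron states, the second seeds the cubic map
#' that builds the generator's weight, bias and control-parameter matrices.
#'
#' @param key Character scalar, e.g. `"0123456789ABCDEF"`.
#' @return An object of class `encryption_key`: a list with `hex` (canonical
#'   upper-case form), `half_init` and `half_cubic` (the two 32-bit halves as
#'   doubles).
#' @examples
#' k <- parse_key("0123456789ABCDEF")
#' k$half_init  # 0x01234567
#' @export
parse_key <- function(key) {
  if (inherits(key, "encryption_key")) return(key)
  if (!is.character(key) || length(key) != 1L) {
    stop("key must be a single character string", call. = FALSE)
  }
  hex <- sub("^0[xX]", "", trimws(key))
  if (!grepl("^[0-9a-fA-F]{16}$", hex)) {
    stop("key must be exactly 16 hexadecimal characters", call. = FALSE)
  }
  hex <- toupper(hex)
  # parse in 4-hex-digit chunks: 64-bit values exceed R's integer range
  chunk <- function(i) strtoi(substr(hex, i, i + 3L), base = 16L)
  half_init <- chunk(1L) * 65536 + chunk(5L)
  half_cubic <- chunk(9L) * 65536 + chunk(13L)
  structure(
    list(hex = hex, half_init = half_init, half_cubic = half_cubic),
    class = "encryption_key"
  )
}

#' @export
print.encryption_key <- function(x, ...) {
  cat("<encryption_key> 0x", x$hex, "\n", sep = "")
  invisible(x)
}

#' Map the two 32-bit key halves into the unit interval
#'
#' Each half `h` maps to `(h + 0.5) / 2^32`, which is strictly inside (0, 1)
#' for every possible 32-bit value — in particular the all-zero key cannot
#' produce the absorbing state 0.
#'
#' @param key An `encryption_key` or a 16-hex-character string.
#' @return Named numeric vector `c(init = , cubic = )`, both in (0, 1).
#' @examples
#' split_key("0000000000000000") # both halves ~ 1.16e-10
#' @export
split_key <- function(key) {
  key <- parse_key(key)
  c(
    init  = (key$half_init + 0.5) / 2^32,
    cubic = (key$half_cubic + 0.5) / 2^32
  )
}

#' Flip a single bit of a key
#'
#' Utility for key-sensitivity experiments: returns a new key differing from
#' `key` in exactly one bit position (0 = least-significant bit of the whole
#' 64-bit value, 63 = most-significant).
#'
#' @param key An `encryption_key` or hex string.
#' @param bit Bit position to flip, 0..63.
#' @return An `encryption_key`.
#' @export
flip_key_bit <- function(key, bit) {
  key <- parse_key(key)
  if (bit < 0 || bit > 63) stop("bit must be in 0..63", call. = FALSE)
  nib_idx <- 16L - bit %/% 4L            # which hex character (1-based)
  nib_bit <- bit %% 4L
  nib <- strtoi(substr(key$hex, nib_idx, nib_idx), base = 16L)
  nib <- bitwXor(nib, bitwShiftL(1L, nib_bit))
  hex <- key$hex
  substr(hex, nib_idx, nib_idx) <- toupper(format(as.hexmode(nib)))
  parse_key(hex)
}
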