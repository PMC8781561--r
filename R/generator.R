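# The keystream generator: a 4-layer neural network whose neurons use chaotic
# maps as transfer functions. A 64-bit key is split into two 32-bit halves;
# the second half seeds a cubic map whose post-transient outputs fill the
# weight (W), bias (B) and control-parameter (P) matrices, and the first half
# initializes the neuron states. Each forward pass emits four unit-interval
# outputs: OP4w (pixel scrambling), OP4x (pixel substitution), OP4y (pixel
# bit scrambling) and OP4z, which feeds back as the per-neuron map iteration
# count of the next pass.

#' Generator configuration
#'
#' @param nhl Hidden-layer width (number of neurons per hidden layer).
#' @param warmup Cubic-map warm-up iterations discarded before matrix filling.
#' @param r_min Floor on the per-neuron transfer-function iteration count.
#'   Below about 3 iterations the output map has not yet mixed the lumpy
#'   pre-activation distribution down to uniform, which biases the emitted
#'   bytes; 4 keeps a safety margin.
#' @param r_max Cap on the per-neuron transfer-function iteration count; the
#'   OP4z output selects `r_min + floor(OP4z * (r_max - r_min + 1))`
#'   iterations for the next forward pass.
#' @param layer_maps Character vector of length 4 assigning a chaotic map to
#'   each layer (input, hidden 1, hidden 2, output). The output layer defaults
#'   to the PWLCM because its piecewise-linear branches preserve uniform
#'   measure, which keeps the emitted byte streams unbiased.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(nhl = 8L,
                             warmup = 50L,
                             r_min = 4L,
                             r_max = 16L,
                             layer_maps = c("logistic", "pwlcm", "lts", "pwlcm")) {
  nhl <- as.integer(nhl)
  warmup <- as.integer(warmup)
  r_min <- as.integer(r_min)
  r_max <- as.integer(r_max)
  if (nhl < 1L) stop("nhl must be >= 1", call. = FALSE)
  if (warmup < 0L) stop("warmup must be >= 0", call. = FALSE)
  if (r_min < 1L || r_max < r_min) stop("need 1 <= r_min <= r_max", call. = FALSE)
  if (length(layer_maps) != 4L) stop("layer_maps must name 4 maps", call. = FALSE)
  layer_maps <- vapply(
    layer_maps,
    function(m) match.arg(m, c("logistic", "pwlcm", "lts", "cubic")),
    character(1), USE.NAMES = FALSE
  )
  structure(
    list(nhl = nhl, mol = 4L, warmup = warmup, r_min = r_min, r_max = r_max,
         layer_maps = layer_maps),
    class = "generator_config"
  )
}

.map_code <- function(map_id) {
  match(map_id, c("logistic", "pwlcm", "lts", "cubic")) - 1L
}

# Affine rescale of a unit-interval value into a map's control range.
# Unit inputs are strictly inside (0,1), so open ranges stay open.
.rescale_control <- function(u, map_id) {
  rng <- .map_control_range(map_id)
  rng[1] + u * (rng[2] - rng[1])
}

#' Initialize the keystream generator from a 64-bit key
#'
#' Seeds a cubic map (`lambda = 2.59`) with the key's second 32-bit half,
#' discards `warmup` iterations so the transient has died out, then uses the
#' following outputs — in fixed row-major order — to fill the weight matrices
#' W0 (1x1), W1 (nhl x 1), W2 (nhl x nhl), W3 (4 x nhl), the bias matrices
#' B0..B3 and the control-parameter matrices P0..P3 (shapes 1, nhl, nhl, 4).
#' Raw unit values destined for a P matrix are rescaled into the control range
#' of that layer's chaotic map. Neuron states start at the unit-interval image
#' of the key's first half; the iteration count starts at 1.
#'
#' @param key An `encryption_key` or 16-hex-character string.
#' @param cfg A [generator_config()].
#' @return An object of class `generator_state`.
#' @export
init_generator <- function(key, cfg = generator_config()) {
  key <- parse_key(key)
  stopifnot(inherits(cfg, "generator_config"))
  halves <- split_key(key)
  nhl <- cfg$nhl

  n_w <- 1L + nhl + nhl * nhl + 4L * nhl
  n_b <- 1L + nhl + nhl + 4L
  n_p <- n_b
  vals <- iterate_map("cubic", halves[["cubic"]],
                      n = cfg$warmup + n_w + n_b + n_p,
                      discard = cfg$warmup, control = 2.59)

  take <- local({
    pos <- 0L
    function(k) {
      out <- vals[(pos + 1L):(pos + k)]
      pos <<- pos + k
      out
    }
  })

  W0 <- take(1L)
  W1 <- take(nhl)
  W2 <- matrix(take(nhl * nhl), nhl, nhl, byrow = TRUE)
  W3 <- matrix(take(4L * nhl), 4L, nhl, byrow = TRUE)
  B0 <- take(1L); B1 <- take(nhl); B2 <- take(nhl); B3 <- take(4L)
  P0 <- .rescale_control(take(1L), cfg$layer_maps[1])
  P1 <- .rescale_control(take(nhl), cfg$layer_maps[2])
  P2 <- .rescale_control(take(nhl), cfg$layer_maps[3])
  P3 <- .rescale_control(take(4L), cfg$layer_maps[4])

  structure(
    list(
      key = key, cfg = cfg,
      W0 = W0, W1 = W1, W2 = W2, W3 = W3,
      B0 = B0, B1 = B1, B2 = B2, B3 = B3,
      P0 = P0, P1 = P1, P2 = P2, P3 = P3,
      input_state = halves[["init"]],
      neuron_states = rep(halves[["init"]], 1L + 2L * nhl + 4L),
      iter_count = cfg$r_min
    ),
    class = "generator_state"
  )
}

#' @export
print.generator_state <- function(x, ...) {
  cat("<generator_state> key 0x", x$key$hex,
      ", nhl=", x$cfg$nhl,
      ", maps=", paste(x$cfg$layer_maps, collapse = "/"),
      ", iter_count=", x$iter_count, "\n", sep = "")
  invisible(x)
}

.run_generator <- function(state, n) {
  cpp_generate(
    state$input_state, state$iter_count,
    state$W0, state$B0, state$P0,
    state$W1, state$B1, state$P1,
    state$W2, state$B2, state$P2,
    state$W3, state$B3, state$P3,
    .map_code(state$cfg$layer_maps), state$cfg$r_min, state$cfg$r_max,
    as.integer(n)
  )
}

.advance_state <- function(state, res) {
  if (isTRUE(res$ran)) {
    state$input_state <- res$input_state
    state$neuron_states <- res$states
    state$iter_count <- as.integer(res$iter_count)
  }
  state
}

#' Run one forward pass of the generator
#'
#' Each neuron computes its pre-activation `(weighted input sum + bias) mod 1`
#' and then applies its layer's chaotic map `iter_count` times with its own
#' control parameter. The four output-layer values are (OP4w, OP4x, OP4y,
#' OP4z); after the pass the iteration count becomes
#' `r_min + floor(OP4z * (r_max - r_min + 1))` and the neuron states take the
#' new outputs.
#'
#' @param state A `generator_state`.
#' @return List with `outputs` (named numeric vector w, x, y, z, each strictly
#'   in (0, 1)) and `state` (the advanced generator state).
#' @export
forward_pass <- function(state) {
  stopifnot(inherits(state, "generator_state"))
  res <- .run_generator(state, 1L)
  outputs <- as.numeric(res$out[1L, ])
  names(outputs) <- c("w", "x", "y", "z")
  list(outputs = outputs, state = .advance_state(state, res))
}

#' Quantize unit-interval values to bytes
#'
#' `b = min(floor(u * 256), 255)` — the clamp only matters for a value exactly
#' at 1, which sanitation already excludes.
#'
#' @param u Numeric vector in (0, 1).
#' @return Integer vector in 0..255.
#' @export
unit_to_byte <- function(u) {
  pmin(as.integer(floor(u * 256)), 255L)
}

#' Generate keystreams
#'
#' Runs `n` forward passes and packages the three operational streams as
#' bytes: `w` (pixel scrambling), `x` (pixel substitution), `y` (pixel bit
#' scrambling). The raw unit-interval OP4w values (`w_raw`) are retained for
#' permutation-index generation, and the internally consumed OP4z stream (`z`)
#' is exposed for testing.
#'
#' @param state A `generator_state`.
#' @param n Number of passes (one per pixel when driving the cipher).
#' @return An object of class `keystreams`: list with byte vectors `w`, `x`,
#'   `y`, raw streams `w_raw` and `z`, the pass count `n`, and `state` (the
#'   advanced generator state).
#' @export
generate_keystream <- function(state, n) {
  stopifnot(inherits(state, "generator_state"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative count", call. = FALSE)
  res <- .run_generator(state, n)
  out <- res$out
  structure(
    list(
      w = unit_to_byte(out[, 1L]),
      x = unit_to_byte(out[, 2L]),
      y = unit_to_byte(out[, 3L]),
      w_raw = as.numeric(out[, 1L]),
      z = as.numeric(out[, 4L]),
      n = n,
      state = .advance_state(state, res)
    ),
    class = "keystreams"
  )
}

#' @export
print.keystreams <- function(x, ...) {
  cat("<keystreams> n=", x$n, " passes (streams w/x/y as bytes)\n", sep = "")
  invisible(x)
}
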