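# Independent replay of the generator's forward-pass rules using only the
# exported scalar map functions and plain double arithmetic (explicit
# left-to-right accumulation; sum() would use extended precision and diverge
# from the compiled path under chaotic amplification).
oracle_forward_pass <- function(st) {
  cfg <- st$cfg
  r <- st$iter_count
  apply_map <- function(map, a, g) {
    for (i in seq_len(r)) {
      a <- switch(map,
        logistic = step_logistic(a, g),
        pwlcm    = step_pwlcm(a, g),
        lts      = step_lts(a, g),
        cubic    = step_cubic(a, g)
      )
    }
    a
  }
  pre <- function(a) sanitize_unit(a %% 1)

  out0 <- apply_map(cfg$layer_maps[1], pre(st$W0 * st$input_state + st$B0), st$P0)
  out1 <- numeric(cfg$nhl)
  for (j in seq_len(cfg$nhl)) {
    out1[j] <- apply_map(cfg$layer_maps[2], pre(st$W1[j] * out0 + st$B1[j]), st$P1[j])
  }
  out2 <- numeric(cfg$nhl)
  for (j in seq_len(cfg$nhl)) {
    acc <- 0
    for (k in seq_len(cfg$nhl)) acc <- acc + st$W2[j, k] * out1[k]
    out2[j] <- apply_map(cfg$layer_maps[3], pre(acc + st$B2[j]), st$P2[j])
  }
  outs <- numeric(4)
  for (j in 1:4) {
    acc <- 0
    for (k in seq_len(cfg$nhl)) acc <- acc + st$W3[j, k] * out2[k]
    outs[j] <- apply_map(cfg$layer_maps[4], pre(acc + st$B3[j]), st$P3[j])
  }
  outs
}

# deterministic i.i.d.-uniform test image
rand_img <- function(n_row, n_col, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:255, n_row * n_col, replace = TRUE), n_row, n_col)
}

TEST_KEY <- "0123456789ABCDEF"
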