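test_that("permutation plans follow the keystream swap rule", {
  # single pixel: the only possible swap is the identity
  p1 <- build_permutation(0.2, 1, 1)
  expect_identical(p1$target, 1L)
  img1 <- matrix(42L, 1, 1)
  expect_identical(apply_permutation(img1, p1), img1)

  # hand trace on 2x2 (scan order a b / c d, targets floor(u*4)+1 = 4,3,4,4):
  # swap(1,4) -> d b c a; swap(2,3) -> d c b a; swap(3,4) -> d c a b; swap(4,4)
  plan <- build_permutation(c(0.99, 0.60, 0.99, 0.99), 2, 2)
  img <- matrix(c(10L, 20L, 30L, 40L), 2, 2, byrow = TRUE)
  expect_identical(apply_permutation(img, plan),
                   matrix(c(40L, 30L, 10L, 20L), 2, 2, byrow = TRUE))

  # bijection: permuting the position labels themselves yields all positions
  n <- 12L * 7L
  u <- (seq_len(n) * 0.61803398875) %% 1
  plan <- build_permutation(u, 12, 7)
  pos <- matrix(0:(n - 1L), 12, 7, byrow = TRUE)
  perm <- apply_permutation(pos %% 256L, plan) # labels fit in a byte? n<256 yes
  expect_identical(sort(as.integer(perm)), 0:(n - 1L))

  expect_error(build_permutation(c(0.1, 0.2), 2, 2), "exhausted")
})

test_that("P-box preserves the histogram and inverts exactly", {
  img <- rand_img(64, 64, seed = 11)
  ks <- generate_keystream(init_generator(TEST_KEY), length(img))
  plan <- build_permutation(ks$w_raw, 64, 64)

  const <- matrix(7L, 64, 64)
  expect_identical(apply_permutation(const, plan), const)

  perm <- apply_permutation(img, plan)
  expect_identical(tabulate(perm + 1L, 256), tabulate(img + 1L, 256))
  expect_identical(apply_permutation(perm, plan, inverse = TRUE), img)

  expect_error(apply_permutation(rand_img(8, 8, 1), plan), "built for")
})

test_that("the eight DNA rules are bijections whose complement is an involution", {
  rules <- dna_rules()
  expect_identical(dim(rules), c(8L, 4L))
  for (r in 1:8) {
    expect_identical(sort(unname(rules[r, ])), 0:3)
    # Watson-Crick complement (A<->T, C<->G) == 2-bit complement of the code
    expect_identical(unname(rules[r, c("T", "G", "C", "A")]),
                     unname(3L - rules[r, c("A", "C", "G", "T")]))
  }
})

test_that("the SP-box substitutes, permutes bits and inverts per pixel", {
  # ky = 0: rule 0, rotation 0 -> DNA stage is the base-wise complement,
  # i.e. the bitwise complement of the substituted byte
  expect_identical(sp_box_pixel(0:255, 0L, 0L),
                   bitwXor(0:255, 255L))
  # complementing twice returns the original
  expect_identical(sp_box_pixel(sp_box_pixel(0:255, 0L, 0L), 0L, 0L), 0:255)

  # hand XOR check: 0b10110010 xor 0b11111111 = 0b01001101, then complemented
  # back by the ky=0 DNA stage
  expect_identical(sp_box_pixel(178L, 255L, 0L), 178L)
  expect_identical(bitwXor(178L, 255L), 77L)

  # inversion over all pixels x all bit-permutation bytes, several kx
  p <- rep(0:255, each = 256)
  ky <- rep(0:255, times = 256)
  for (kx in c(0L, 1L, 77L, 128L, 255L)) {
    enc <- sp_box_pixel(p, kx, ky)
    expect_identical(sp_box_pixel(enc, kx, ky, inverse = TRUE), p)
  }

  # for a fixed ky the map p -> c is a bijection on bytes
  expect_identical(sort(sp_box_pixel(0:255, 77L, 139L)), 0:255)

  expect_error(sp_box_pixel(300L, 0L, 0L), "0..255")
})

test_that("decrypt is the exact inverse of encrypt", {
  shapes <- list(c(32L, 32L), c(37L, 61L), c(1L, 1L), c(1L, 40L), c(64L, 16L))
  keys <- c(TEST_KEY, "FEDCBA9876543210")
  for (key in keys) {
    for (sh in shapes) {
      img <- rand_img(sh[1], sh[2], seed = sh[1] + sh[2])
      ct <- encrypt_image(img, key)
      expect_identical(dim(ct), dim(img))
      expect_identical(decrypt_image(ct, key), img)
    }
  }

  # synthetic smooth plaintext round trip
  img <- synth_xray(48, 48, seed = 5)
  expect_identical(decrypt_image(encrypt_image(img, TEST_KEY), TEST_KEY), img)

  # custom generator config must round-trip too
  cfg <- generator_config(nhl = 3L, layer_maps = c("lts", "pwlcm", "logistic", "pwlcm"))
  img <- rand_img(20, 20, seed = 3)
  expect_identical(decrypt_image(encrypt_image(img, TEST_KEY, cfg), TEST_KEY, cfg), img)

  # decrypting arbitrary bytes is total and yields a valid 8-bit image
  junk <- rand_img(16, 16, seed = 99)
  dec <- decrypt_image(junk, TEST_KEY)
  expect_true(all(dec >= 0L & dec <= 255L))

  expect_error(encrypt_image(matrix(0.5, 4, 4), TEST_KEY), "8-bit")
})

test_that("decrypting with a near-miss key destroys the image", {
  img <- synth_xray(64, 64, seed = 8)
  ct <- encrypt_image(img, TEST_KEY)
  for (bit in c(0L, 13L, 33L, 50L, 63L)) {
    dec <- decrypt_image(ct, flip_key_bit(TEST_KEY, bit))
    expect_lt(img_psnr(dec, img), 10)
  }
})

test_that("encryption destroys adjacent-pixel correlation", {
  img <- synth_xray(256, 256, seed = 1)
  expect_gte(adjacent_correlation(img, "horizontal"), 0.9)
  ct <- encrypt_image(img, TEST_KEY)
  for (dir in c("horizontal", "vertical", "diagonal")) {
    expect_lte(abs(adjacent_correlation(ct, dir)), 0.02)
  }
})
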