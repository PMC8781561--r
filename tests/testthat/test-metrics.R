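test_that("MSE and PSNR reproduce closed-form values and stay consistent", {
  a <- matrix(0L, 4, 4)
  b <- matrix(255L, 4, 4)
  expect_equal(img_mse(a, a), 0)
  expect_equal(img_mse(a, b), 65025)
  expect_equal(img_mse(matrix(c(10L, 20L), 1), matrix(c(13L, 16L), 1)), 12.5)

  expect_equal(img_psnr(a, b), 0)           # MSE = 255^2 -> 0 dB
  expect_identical(img_psnr(a, a), Inf)     # identical images

  # psnr computed from mse agrees with direct evaluation
  x <- rand_img(32, 32, 1); y <- rand_img(32, 32, 2)
  expect_equal(img_psnr(x, y), 10 * log10(255^2 / img_mse(x, y)), tolerance = 1e-9)

  expect_error(img_mse(a, matrix(0L, 2, 2)), "equal dimensions")
})

test_that("Shannon entropy hits the exact degenerate and balanced cases", {
  expect_equal(shannon_entropy(matrix(7L, 10, 10)), 0)
  balanced <- matrix(rep(0:255, 4L), 32, 32)
  expect_equal(shannon_entropy(balanced), 8)

  # monotone non-decreasing as a two-level histogram flattens toward balance
  ent <- vapply(seq(2L, 32L, by = 2L), function(k) {
    shannon_entropy(matrix(c(rep(0L, k), rep(255L, 64L - k)), 8, 8))
  }, numeric(1))
  expect_true(all(diff(ent) >= 0))
  expect_true(all(ent >= 0 & ent <= 8))
})

test_that("adjacent correlation distinguishes structured from flat images", {
  ramp <- matrix(rep(0:15 * 17L, each = 8), 8, 16) # value rises along each row
  expect_equal(adjacent_correlation(ramp, "horizontal"), 1)
  expect_equal(adjacent_correlation(t(ramp), "vertical"), 1)

  checker <- 255L * ((outer(1:8, 1:8, "+") %% 2L))
  expect_equal(adjacent_correlation(checker, "horizontal"), -1)
  expect_equal(adjacent_correlation(checker, "diagonal"), 1)

  expect_warning(r <- adjacent_correlation(matrix(5L, 4, 4), "horizontal"),
                 "constant")
  expect_true(is.na(r))
  expect_error(adjacent_correlation(matrix(0L, 3, 1), "horizontal"), "columns")
})

test_that("GLCM features match closed forms on constant and uniform images", {
  const <- matrix(99L, 16, 16)
  g <- glcm_features(const)
  expect_equal(unname(g["energy"]), 1)
  expect_equal(unname(g["contrast"]), 0)

  # i.i.d. uniform bytes: co-occurrence is the uniform product distribution,
  # energy -> 1/64, contrast -> E[(i-j)^2] = 2*Var(U{0..7}) = 10.5
  u <- rand_img(256, 256, seed = 42)
  g <- glcm_features(u, levels = 8L)
  expect_equal(unname(g["energy"]), 1 / 64, tolerance = 0.02)
  expect_equal(unname(g["contrast"]), 10.5, tolerance = 0.02)

  # offsets and level counts are honored
  g2 <- glcm_features(u, levels = 4L, offset = c(1L, 0L))
  expect_equal(unname(g2["energy"]), 1 / 16, tolerance = 0.02)

  expect_error(glcm_features(const, offset = c(0L, 0L)), "nonzero")
  expect_error(glcm_features(matrix(0L, 2, 2), offset = c(0L, 5L)), "smaller")
})

test_that("security_report bundles the standalone metrics and survives JSON", {
  plain <- synth_xray(64, 64, seed = 2)
  cipher <- encrypt_image(plain, TEST_KEY)
  rep <- security_report(plain, cipher)

  expect_equal(rep$mse, img_mse(plain, cipher))
  expect_equal(rep$psnr_db, img_psnr(plain, cipher))
  expect_equal(rep$entropy_bits, shannon_entropy(cipher))
  expect_equal(rep$correlation$h, adjacent_correlation(cipher, "horizontal"))
  g <- glcm_features(cipher)
  expect_equal(rep$energy, unname(g["energy"]))
  expect_equal(rep$contrast, unname(g["contrast"]))

  self <- security_report(plain, plain)
  expect_equal(self$mse, 0)
  expect_identical(self$psnr_db, Inf)

  path <- tempfile(fileext = ".json")
  write_security_report(rep, path)
  back <- read_security_report(path)
  for (f in c("mse", "psnr_db", "entropy_bits", "energy", "contrast")) {
    expect_equal(back[[f]], rep[[f]])
  }
  expect_equal(back$correlation$v, rep$correlation$v)

  # infinite PSNR round-trips through the string sentinel
  write_security_report(self, path)
  expect_identical(read_security_report(path)$psnr_db, Inf)
})

test_that("salt-and-pepper noise hits the requested density", {
  img <- matrix(100L, 100, 100)
  expect_identical(salt_pepper(img, 0, seed = 1), img)
  all_noise <- salt_pepper(img, 1, seed = 1)
  expect_true(all(all_noise %in% c(0L, 255L)))

  noisy <- salt_pepper(img, 0.05, seed = 7)
  hits <- sum(noisy != img)
  sigma <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(hits - 500), 3 * sigma)
  expect_identical(salt_pepper(img, 0.05, seed = 7), noisy)

  expect_error(salt_pepper(img, 1.5), "density")
})

test_that("the cipher does not amplify ciphertext noise", {
  img <- synth_xray(128, 128, seed = 3)

  clean <- noise_attack_trial(img, TEST_KEY, density = 0, seed = 1)
  expect_identical(clean$psnr_db, Inf)
  expect_equal(clean$diff_fraction, 0)

  trial <- noise_attack_trial(img, TEST_KEY, density = 0.05, seed = 2)
  expect_gt(trial$psnr_db, 15)
  # each corrupted ciphertext pixel damages exactly one plaintext pixel;
  # a corrupted pixel decrypts back to the original with probability 1/256
  expected <- 0.05 * 255 / 256
  sigma <- sqrt(0.05 * 0.95 / length(img))
  expect_lt(abs(trial$diff_fraction - expected), 3 * sigma)
})
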