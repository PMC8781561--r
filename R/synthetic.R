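# Synthetic test data: seeded chest-radiograph-like images (the real X-ray
# dataset is private) and the packaged 60-patient symptom table.

# bilinear upsampling of a coarse field to n x m
.bilinear_upsample <- function(coarse, n, m) {
  nc <- nrow(coarse); mc <- ncol(coarse)
  # sample coordinates in the coarse grid
  ry <- seq(1, nc, length.out = n)
  rx <- seq(1, mc, length.out = m)
  y0 <- pmin(floor(ry), nc - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), mc - 1L); fx <- rx - x0
  a <- coarse[y0, x0, drop = FALSE]
  b <- coarse[y0, x0 + 1L, drop = FALSE]
  c_ <- coarse[y0 + 1L, x0, drop = FALSE]
  d <- coarse[y0 + 1L, x0 + 1L, drop = FALSE]
  wfx <- matrix(fx, n, m, byrow = TRUE); wfy <- matrix(fy, n, m)
  a * (1 - wfy) * (1 - wfx) + b * (1 - wfy) * wfx +
    c_ * wfy * (1 - wfx) + d * wfy * wfx
}

#' Synthetic chest-radiograph-like test image
#'
#' Builds a smooth, anatomy-like 8-bit intensity field: a low-frequency
#' random field (coarse Gaussian grid, bilinearly upsampled), two bright
#' elliptical "lung field" regions with smooth falloff, and mild pixel noise.
#' The construction is low-pass, so horizontally adjacent pixels correlate at
#' 0.9 or higher — the regime in which encryption-induced decorrelation is a
#' meaningful test. Seeded and reproducible; the session RNG is untouched.
#'
#' This is a synthetic stand-in with the second-order statistics the cipher
#' cares about (smoothness, high adjacent-pixel correlation, mid-gray
#' histogram); it is not a radiographic simulation.
#'
#' @param n_row,n_col Image dimensions, each at least 16.
#' @param seed Integer seed.
#' @return Integer matrix `n_row` x `n_col` with values 0..255.
#' @examples
#' img <- synth_xray(64, 64, seed = 1)
#' adjacent_correlation(img, "horizontal") # > 0.9
#' @export
synth_xray <- function(n_row, n_col, seed = 1L) {
  n_row <- as.integer(n_row); n_col <- as.integer(n_col)
  if (n_row < 16L || n_col < 16L) {
    stop("image must be at least 16x16", call. = FALSE)
  }
  .with_seed(seed, {
    nc <- max(4L, ceiling(n_row / 32))
    mc <- max(4L, ceiling(n_col / 32))
    base <- .bilinear_upsample(matrix(stats::rnorm(nc * mc), nc, mc), n_row, n_col)
    base <- base / max(stats::sd(base), 1e-8)

    # two bright elliptical regions, roughly where lung fields sit
    yy <- matrix(seq(0, 1, length.out = n_row), n_row, n_col)
    xx <- matrix(seq(0, 1, length.out = n_col), n_row, n_col, byrow = TRUE)
    ellipse <- function(cx, cy, rx, ry) {
      exp(-(((xx - cx) / rx)^2 + ((yy - cy) / ry)^2))
    }
    field <- 0.9 * base +
      2.2 * ellipse(0.32, 0.45, 0.16, 0.28) +
      2.2 * ellipse(0.68, 0.45, 0.16, 0.28) +
      stats::rnorm(n_row * n_col, sd = 0.02)

    lo <- min(field); hi <- max(field)
    img <- round(20 + 215 * (field - lo) / (hi - lo))
    matrix(as.integer(pmin(pmax(img, 0), 255)), n_row, n_col)
  })
}

#' Packaged 60-patient symptom table
#'
#' The printed coding table of 60 patients (30 Normal, 30 Pneumonia), with 13
#' symptom columns coded 0 (absent), 1 (present) or 2 (high-intensity). The
#' printed table carries one unlabeled column between fatigue and vomiting;
#' the packaged copy preserves the 13-column layout as-is under the name
#' `unlabeled`.
#'
#' @return A data frame with columns `patient`, the 13 symptom codes and
#'   `label` (`"Normal"` or `"Pneumonia"`).
#' @export
load_symptom_table <- function() {
  path <- system.file("extdata", "symptom_table.csv", package = "chaoscrypt",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
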