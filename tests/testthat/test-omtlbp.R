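test_that("oriented sampling: constant image, linear ramp, convexity", {
  const <- matrix(3.7, 9, 9)
  s <- sample_oriented(const, 5, 5)
  expect_equal(s$P1, rep(3.7, 8)); expect_equal(s$P2, rep(3.7, 8))
  expect_equal(s$P3, rep(3.7, 8)); expect_equal(s$C, 3.7)

  ramp <- matrix(rep(1:9, each = 9), 9, 9)   # value = column index
  r <- sample_oriented(ramp, 5, 5)
  expect_equal(r$P1[1], 6)                   # angle 0: one column right
  expect_equal(r$P1[3], 5)                   # angle 90: same column
  expect_equal(r$P1[5], 4)                   # angle 180: one column left

  set.seed(3)
  img <- matrix(runif(81), 9, 9)
  s <- sample_oriented(img, 5, 5)
  for (p in list(s$P1, s$P2, s$P3)) {
    expect_true(all(p >= min(img) - 1e-12 & p <= max(img) + 1e-12))
  }
  expect_error(sample_oriented(img, 2, 5), "border")
})

test_that("scale fusion follows U1 = P1, U2 = (P1+P2)/2, U3 = (P2+P3)/2", {
  s <- list(P1 = rep(0, 8), P2 = rep(2, 8), P3 = rep(6, 8), C = 1)
  u <- fuse_scales(s)
  expect_equal(u$U1, rep(0, 8))
  expect_equal(u$U2, rep(1, 8))
  expect_equal(u$U3, rep(4, 8))
  set.seed(8)
  s <- list(P1 = runif(8), P2 = runif(8), P3 = runif(8), C = 0.5)
  u <- fuse_scales(s)
  for (k in 1:8) {                          # brute-force element-wise means
    expect_equal(u$U2[k], mean(c(s$P1[k], s$P2[k])))
    expect_equal(u$U3[k], mean(c(s$P2[k], s$P3[k])))
  }
})

test_that("LDSMT: sign of zero is +1 and s*m reconstructs the differences", {
  z <- ldsmt(rep(1.5, 8), 1.5)
  expect_equal(z$signs, rep(1, 8))
  expect_equal(z$magnitudes, rep(0, 8))
  d <- ldsmt(c(1, -2, 3, -4, 5, -6, 7, -8) + 2, 2)
  expect_equal(d$signs, c(1, -1, 1, -1, 1, -1, 1, -1))
  expect_equal(d$magnitudes, 1:8)
  set.seed(12)
  for (i in 1:20) {
    U <- rnorm(8); C <- rnorm(1)
    r <- ldsmt(U, C)
    expect_equal(r$signs * r$magnitudes, U - C)
    expect_true(all(r$signs %in% c(-1, 1)))
  }
})

test_that("riu2 sign encoding matches the exhaustive transition oracle", {
  expect_equal(encode_sign_riu2(rep(1, 8)), 8)
  expect_equal(encode_sign_riu2(rep(-1, 8)), 0)
  expect_equal(encode_sign_riu2(rep(c(1, -1), 4)), 9)
  codes <- integer(256)
  for (pat in 0:255) {
    bits <- as.integer(bitwAnd(bitwShiftR(pat, 0:7), 1L))
    signs <- 2 * bits - 1
    codes[pat + 1] <- encode_sign_riu2(signs)
    expect_equal(codes[pat + 1], oracle_riu2(bits))
  }
  expect_equal(sort(unique(codes)), 0:9)
  expect_equal(sum(codes <= 8), 58)
  expect_equal(sum(codes == 9), 198)
})

test_that("riu2 magnitude encoding thresholds inclusively at rho_m", {
  expect_equal(encode_magnitude_riu2(rep(0.4, 8), 0.4), 8)   # eta(x, x) = 1
  expect_equal(encode_magnitude_riu2(c(rep(5, 4), rep(0, 4)), 1), 4)
  expect_equal(encode_magnitude_riu2(rep(c(5, 0), 4), 1), 9)
})

test_that("center encoding is inclusive", {
  expect_equal(encode_center(2, 2), 1)
  expect_equal(encode_center(1, 2), 0)
})

test_that("rotation invariance: circular shifts never change s/m codes", {
  set.seed(21)
  for (i in 1:250) {
    signs <- sample(c(-1, 1), 8, replace = TRUE)
    mags <- runif(8)
    rho <- runif(1)
    s0 <- encode_sign_riu2(signs)
    m0 <- encode_magnitude_riu2(mags, rho)
    for (sh in 1:7) {
      idx <- c((sh + 1):8, 1:sh)
      expect_identical(encode_sign_riu2(signs[idx]), s0)
      expect_identical(encode_magnitude_riu2(mags[idx], rho), m0)
    }
  }
})

test_that("constant image puts all mass in bin (s=8, m=8, c=1) per structure", {
  d <- omtlbp_describe(matrix(1, 10, 10), normalize = FALSE)
  expect_length(d, 600)
  # all differences zero: signs all +1 (code 8), mags all >= rho_m = 0
  # (code 8), center >= mean (bit 1)
  bin <- 8 * 20 + 8 * 2 + 1 + 1
  nz <- which(d != 0)
  expect_equal(nz, bin + c(0, 200, 400))
  expect_equal(unname(d[nz]), rep(16, 3))   # 4x4 interior pixels
})

test_that("descriptor length and mass conservation", {
  set.seed(5)
  img <- matrix(runif(20 * 14), 20, 14)
  d_raw <- omtlbp_describe(img, normalize = FALSE)
  expect_length(d_raw, 600)
  expect_equal(sum(d_raw), 3 * (20 - 6) * (14 - 6))
  d_norm <- omtlbp_describe(img, normalize = TRUE)
  expect_equal(sum(d_norm), 1, tolerance = 1e-12)
  expect_true(all(d_norm >= 0))
  expect_error(omtlbp_describe(matrix(0, 6, 6)), "7 x 7")
})

test_that("vectorized descriptor matches the pixel-by-pixel oracle exactly", {
  set.seed(31)
  for (i in 1:3) {
    img <- matrix(runif(16 * 16), 16, 16)
    expect_identical(as.numeric(omtlbp_describe(img, normalize = FALSE)),
                     oracle_omtlbp(img, normalize = FALSE))
    expect_identical(as.numeric(omtlbp_describe(img, normalize = TRUE)),
                     oracle_omtlbp(img, normalize = TRUE))
  }
})

test_that("sample_oriented and the descriptor use the same ring geometry", {
  set.seed(9)
  img <- matrix(runif(12 * 12), 12, 12)
  s <- sample_oriented(img, 6, 7)
  for (k in 1:8) {
    expect_equal(s$P2[k], mean(vapply(0:4, function(i) {
      th <- 22.5 * i + 45 * (k - 2)
      oracle_bilinear(img, 6 - 2 * sinpi(th / 180), 7 + 2 * cospi(th / 180))
    }, numeric(1))))
  }
})

test_that("90-degree image rotation changes the descriptor only slightly", {
  # band-limited smooth image: low-frequency sinusoidal texture
  n <- 32
  g <- outer(seq_len(n), seq_len(n), function(i, j) {
    sin(2 * pi * i / 16) + cos(2 * pi * j / 16) + 0.5 * sin(2 * pi * (i + j) / 20)
  })
  g <- (g - min(g)) / (max(g) - min(g))
  rot90 <- function(m) t(m)[ncol(m):1, ]
  d0 <- omtlbp_describe(g)
  d90 <- omtlbp_describe(rot90(g))
  d180 <- omtlbp_describe(rot90(rot90(g)))
  expect_lt(sum(abs(d90 - d0)), 0.02)
  expect_lt(sum(abs(d180 - d0)), 0.02)
})
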