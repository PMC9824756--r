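test_that("all-zero signal gives an all-zero spectrogram", {
  sp <- compute_stft(numeric(600), fs = 100, stft_config())
  expect_true(all(sp$A == 0))
  expect_true(all(sp$S == 0))
  expect_equal(nrow(sp$A), (600 - 100) %/% 50 + 1)
})

test_that("sinusoid at an exact bin frequency concentrates on bins k0 and L-k0", {
  fs <- 128; L <- 64          # bin frequency k0 = 4 -> 4*fs/L = 8 Hz
  cfg <- stft_config(window_len = L, hop = L, window_shape = "rectangular")
  x <- sin(2 * pi * (4 * fs / L) * (0:639) / fs)
  sp <- compute_stft(x, fs, cfg)
  for (m in seq_len(nrow(sp$A))) {
    a <- sp$A[m, ]
    peak <- max(a)
    expect_equal(sort(order(a, decreasing = TRUE)[1:2]), c(5, 61)) # k0, L-k0 (1-based)
    expect_lt(max(a[-c(5, 61)]), 1e-10 * peak)
  }
})

test_that("single-frame unit impulse has flat amplitude 1/L", {
  L <- 32
  x <- c(1, numeric(L - 1))
  cfg <- stft_config(window_len = L, hop = L, window_shape = "rectangular")
  sp <- compute_stft(x, fs = 32, cfg)
  expect_equal(nrow(sp$A), 1)
  expect_equal(sp$A[1, ], rep(1 / L, L), tolerance = 1e-12)
})

test_that("frame-wise Parseval identity holds for every window shape", {
  set.seed(7)
  x <- rnorm(1000)
  fs <- 100
  for (shape in c("hamming", "hann", "gaussian", "rectangular")) {
    cfg <- stft_config(window_len = 100, hop = 37, window_shape = shape)
    sp <- compute_stft(x, fs, cfg)
    w <- bohdf:::stft_window(shape, 100)
    for (m in seq_len(nrow(sp$A))) {
      seg <- x[((m - 1) * 37 + 1):((m - 1) * 37 + 100)] * w
      expect_equal(sum(sp$A[m, ]), sum(seg^2), tolerance = 1e-9)
    }
  }
})

test_that("a one-hop delay shifts the spectrogram by one frame", {
  set.seed(1)
  hop <- 50
  z <- rnorm(1100)
  cfg <- stft_config(window_len = 100, hop = hop)
  sx <- compute_stft(z[(hop + 1):1100], fs = 100, cfg)   # advanced signal
  sy <- compute_stft(z, fs = 100, cfg)
  m <- nrow(sx$A) - 1                                    # overlapping frames
  expect_equal(sy$A[2:(m + 1), ], sx$A[1:m, ], tolerance = 1e-12)
})

test_that("too-short signals error with the required length", {
  expect_error(compute_stft(numeric(50), fs = 100, stft_config(window_len = 100)),
               "shorter than the window length")
})

test_that("rendered image is normalized, sized, and oriented", {
  tr <- generate_trial(tiny_spec(), 1, 2)
  filt <- bandpass_filter(tr)
  sp <- compute_stft(filt$samples[1, ], filt$fs)
  img <- render_image(sp)
  expect_equal(dim(img$gray), c(224, 224))
  expect_equal(dim(img$rgb), c(224, 224, 3))
  expect_true(all(img$gray >= 0 & img$gray <= 1))
  # normalization precedes the bilinear resize, which pulls extremes inward
  expect_lt(min(img$gray), 0.1)
  expect_gt(max(img$gray), 0.9)
  # grayscale replicated into rgb by default
  expect_identical(img$rgb[, , 1], img$gray)
})

test_that("constant amplitude renders as uniform mid-gray", {
  sp <- compute_stft(numeric(600), fs = 100, stft_config())
  img <- render_image(sp)
  expect_true(all(img$gray == 0.5))
})

test_that("a single hot bin lands at its mapped pixel after resize", {
  fs <- 100; L <- 100
  cfg <- stft_config(window_len = L, hop = 50, image_size = 224, band = c(4, 45),
                     log_scale = FALSE)
  sp <- compute_stft(rnorm(600, sd = 1e-6), fs, cfg)
  keep <- which(sp$bin_freqs >= 4 & sp$bin_freqs <= 45)
  hot_bin <- keep[10]; hot_frame <- 7
  sp$A[hot_frame, hot_bin] <- 100
  img <- render_image(sp, cfg)
  nr <- length(keep); nc <- nrow(sp$A)
  row_src <- nr - 10 + 1                       # frequency axis is flipped
  exp_row <- round((row_src - 1) * 223 / (nr - 1)) + 1
  exp_col <- round((hot_frame - 1) * 223 / (nc - 1)) + 1
  pos <- which(img$gray == max(img$gray), arr.ind = TRUE)[1, ]
  expect_lte(abs(pos["row"] - exp_row), 1)
  expect_lte(abs(pos["col"] - exp_col), 1)
})

test_that("PNG export writes a readable image", {
  path <- withr::local_tempfile(fileext = ".png")
  tr <- generate_trial(tiny_spec(), 0, 3)
  sp <- compute_stft(bandpass_filter(tr)$samples[1, ], tr$fs)
  write_spectrogram_png(render_image(sp), path)
  expect_equal(dim(png::readPNG(path)), c(224, 224))
})
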