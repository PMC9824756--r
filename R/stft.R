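# Short-time Fourier transform and fixed-size spectrogram images.
#
# A signal is cut into overlapping windowed frames; frame m starts at sample
# m*hop (0-based) and covers L samples. S(m, k) is the length-L DFT of the
# windowed frame, and the amplitude spectrogram is A(m, k) = |S(m, k)|^2 / L,
# so each frame's amplitudes sum to the energy of its windowed segment.

#' STFT / image-rendering configuration
#'
#' @param window_len Window length L in samples; `NULL` (default) means one
#'   second of samples at the signal's rate.
#' @param hop Frame shift in samples; `NULL` means 50\% overlap (`L / 2`).
#' @param window_shape One of `"hamming"` (default), `"hann"`, `"gaussian"`
#'   (MATLAB convention, alpha = 2.5), `"rectangular"`.
#' @param log_scale Log-compress amplitudes (`10 log10(A + 1e-12)`) before
#'   image normalization. EEG spectral dynamic range spans orders of
#'   magnitude; without compression the texture operator sees nothing.
#' @param image_size Side of the square rendered image (default 224, the
#'   common CNN input size).
#' @param band Keep only frequency rows inside `c(low, high)` Hz before
#'   rendering (default the 4-45 Hz analysis band, matching the band-pass
#'   filter); `NULL` keeps all bins up to Nyquist.
#' @param color One of `"gray"` (3-channel image replicates the grayscale
#'   plane) or `"jet"` (colormapped RGB for the CNN backend).
#' @return An `stft_config` object.
#' @export
stft_config <- function(window_len = NULL, hop = NULL,
                        window_shape = c("hamming", "hann", "gaussian", "rectangular"),
                        log_scale = TRUE, image_size = 224, band = c(4, 45),
                        color = c("gray", "jet")) {
  structure(list(window_len = window_len, hop = hop,
                 window_shape = match.arg(window_shape),
                 log_scale = isTRUE(log_scale),
                 image_size = as.integer(image_size), band = band,
                 color = match.arg(color)),
            class = "stft_config")
}

stft_window <- function(shape, L) {
  i <- seq_len(L) - 1
  switch(shape,
    rectangular = rep(1, L),
    hann        = 0.5 - 0.5 * cos(2 * pi * i / (L - 1)),
    hamming     = 0.54 - 0.46 * cos(2 * pi * i / (L - 1)),
    gaussian    = {
      n <- i - (L - 1) / 2
      exp(-0.5 * (2.5 * n / ((L - 1) / 2))^2)
    },
    stop("unknown window shape: ", shape))
}

#' Compute the amplitude spectrogram of one channel
#'
#' @param channel Numeric vector, one EEG channel (already filtered).
#' @param fs Sampling rate in Hz.
#' @param cfg An [stft_config()].
#' @return A `spectrogram` object with components `S` (complex, frames x L),
#'   `A` (`|S|^2 / L`), `fs`, `frame_times` (frame centers, s), `bin_freqs`
#'   (Hz, 0..fs(L-1)/L) and the resolved `cfg`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 200))
#' sp <- compute_stft(x, fs = 200, stft_config())
#' dim(sp$A)
compute_stft <- function(channel, fs, cfg = stft_config()) {
  L <- if (is.null(cfg$window_len)) as.integer(round(fs)) else as.integer(cfg$window_len)
  hop <- if (is.null(cfg$hop)) max(1L, L %/% 2L) else as.integer(cfg$hop)
  n <- length(channel)
  if (n < L) {
    stop(sprintf("signal length %d is shorter than the window length L = %d", n, L))
  }
  if (hop < 1L || hop > L) stop("need 1 <= hop <= L")
  m <- (n - L) %/% hop + 1L
  w <- stft_window(cfg$window_shape, L)
  starts <- (seq_len(m) - 1L) * hop
  segs <- vapply(starts, function(s) channel[(s + 1L):(s + L)] * w, numeric(L))
  S <- t(stats::mvfft(matrix(segs, nrow = L)))      # frames x L
  A <- Mod(S)^2 / L
  cfg$window_len <- L; cfg$hop <- hop
  structure(list(S = S, A = A, fs = fs,
                 frame_times = (starts + (L - 1) / 2) / fs,
                 bin_freqs = (seq_len(L) - 1) * fs / L,
                 cfg = cfg),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, fs = %g Hz, window = %s(L=%d, hop=%d)\n",
              nrow(x$A), ncol(x$A), x$fs, x$cfg$window_shape,
              x$cfg$window_len, x$cfg$hop))
  invisible(x)
}

# Bilinear resize with align-corners index mapping; works down to 1-pixel
# sources (constant extension).
bilinear_resize <- function(mat, out_rows, out_cols) {
  nr <- nrow(mat); nc <- ncol(mat)
  map <- function(n_out, n_in) {
    if (n_in == 1L) return(list(lo = rep(1L, n_out), hi = rep(1L, n_out),
                                w = rep(0, n_out)))
    pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
    lo <- pmin(floor(pos), n_in - 1)
    list(lo = as.integer(lo), hi = as.integer(lo + 1), w = pos - lo)
  }
  r <- map(out_rows, nr); c <- map(out_cols, nc)
  top <- mat[r$lo, , drop = FALSE] * (1 - r$w) + mat[r$hi, , drop = FALSE] * r$w
  t(t(top[, c$lo, drop = FALSE]) * (1 - c$w) + t(top[, c$hi, drop = FALSE]) * c$w)
}

jet_colormap <- function(v) {
  # piecewise-linear jet: blue -> cyan -> yellow -> red over [0, 1]
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  list(r = r, g = g, b = b)
}

#' Render a spectrogram as a fixed-size image
#'
#' Amplitudes are restricted to the configured frequency band, optionally
#' log-compressed, min-max normalized per image to `[0, 1]`, oriented with
#' frequency increasing upward and time rightward, and bilinearly resized to
#' `image_size` x `image_size`. A constant spectrogram (zero dynamic range)
#' renders as uniform mid-gray 0.5.
#'
#' @param spec A `spectrogram` from [compute_stft()].
#' @param cfg An [stft_config()]; `NULL` reuses the spectrogram's own config.
#' @return A `spectro_image`: list with `gray` (`image_size^2` matrix in
#'   `[0, 1]`, the texture descriptor's input) and `rgb`
#'   (`image_size x image_size x 3` array, the deep backend's input).
#' @export
render_image <- function(spec, cfg = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  if (is.null(cfg)) cfg <- spec$cfg
  A <- spec$A
  if (nrow(A) == 0 || ncol(A) == 0) stop("empty spectrogram")
  freqs <- spec$bin_freqs
  keep <- if (is.null(cfg$band)) freqs <= spec$fs / 2 else
    freqs >= cfg$band[1] & freqs <= cfg$band[2]
  if (!any(keep)) stop("no frequency bins inside the configured band")
  M <- t(A[, keep, drop = FALSE])              # rows = freq ascending, cols = time
  M <- M[rev(seq_len(nrow(M))), , drop = FALSE]  # frequency increases upward
  if (cfg$log_scale) M <- 10 * log10(M + 1e-12)
  rng <- range(M)
  M <- if (rng[2] > rng[1]) (M - rng[1]) / (rng[2] - rng[1]) else
    matrix(0.5, nrow(M), ncol(M))
  g <- bilinear_resize(M, cfg$image_size, cfg$image_size)
  g <- pmin(pmax(g, 0), 1)
  rgb <- array(0, dim = c(cfg$image_size, cfg$image_size, 3))
  if (cfg$color == "jet") {
    cm <- jet_colormap(g)
    rgb[, , 1] <- cm$r; rgb[, , 2] <- cm$g; rgb[, , 3] <- cm$b
  } else {
    rgb[, , 1] <- g; rgb[, , 2] <- g; rgb[, , 3] <- g
  }
  structure(list(gray = g, rgb = rgb), class = "spectro_image")
}

#' Write a rendered spectrogram image to PNG
#'
#' @param image A `spectro_image` from [render_image()].
#' @param path Output PNG path.
#' @param what `"gray"` or `"rgb"` plane.
#' @return `path`, invisibly.
#' @export
write_spectrogram_png <- function(image, path, what = c("gray", "rgb")) {
  what <- match.arg(what)
  png::writePNG(image[[what]], target = path)
  invisible(path)
}
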