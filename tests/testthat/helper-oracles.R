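# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scalar loops, explicit formulas, base R only.

# Band-integrated periodogram power of a 1D signal.
band_power <- function(x, fs, lo, hi) {
  p <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                         taper = 0, detrend = FALSE)
  sum(p$spec[p$freq >= lo & p$freq <= hi])
}

# Scalar bilinear interpolation with the same near-integer snapping rule as
# the implementation (the snap is part of the sampling contract, not of the
# vectorization under test).
oracle_bilinear <- function(img, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  if (fy < 1e-9) fy <- 0 else if (fy > 1 - 1e-9) { y0 <- y0 + 1; fy <- 0 }
  if (fx < 1e-9) fx <- 0 else if (fx > 1 - 1e-9) { x0 <- x0 + 1; fx <- 0 }
  out <- (1 - fy) * (1 - fx) * img[y0, x0]
  if (fx > 0) out <- out + (1 - fy) * fx * img[y0, x0 + 1]
  if (fy > 0) out <- out + fy * (1 - fx) * img[y0 + 1, x0]
  if (fy > 0 && fx > 0) out <- out + fy * fx * img[y0 + 1, x0 + 1]
  out
}

# Circular 0/1 transition count of a bit vector.
oracle_transitions <- function(bits) {
  sum(abs(diff(c(bits, bits[1]))))
}

oracle_riu2 <- function(bits) {
  if (oracle_transitions(bits) <= 2) sum(bits) else 9L
}

# Pixel-by-pixel brute-force OMTLBP_SMC: nested loops, no vectorization, no
# lookup tables. Arithmetic accumulation order mirrors the stated
# definitions (sequential sums, then division).
oracle_omtlbp <- function(image, normalize = TRUE) {
  nr <- nrow(image); nc <- ncol(image)
  rows <- 4:(nr - 3); cols <- 4:(nc - 3)
  ring_at <- function(rr, cc, v, k) {
    if (v == 1) { th <- 45 * (k - 1); r <- 1 }
    else if (v == 2) { th <- 22.5 * (0:4) + 45 * (k - 2); r <- 2 }
    else { th <- 15 * (0:6) + 45 * (k - 2); r <- 3 }
    s <- 0
    for (t in th) {
      s <- s + oracle_bilinear(image, rr - r * sinpi(t / 180),
                               cc + r * cospi(t / 180))
    }
    s / length(th)
  }
  # pass 1: fused values per pixel/structure/direction
  np <- length(rows) * length(cols)
  U <- array(0, dim = c(np, 3, 8))
  Cv <- numeric(np)
  i <- 0
  for (cc in cols) for (rr in rows) {
    i <- i + 1
    Cv[i] <- image[rr, cc]
    for (k in 1:8) {
      p1 <- ring_at(rr, cc, 1, k)
      p2 <- ring_at(rr, cc, 2, k)
      p3 <- ring_at(rr, cc, 3, k)
      U[i, 1, k] <- p1
      U[i, 2, k] <- (p1 + p2) / 2
      U[i, 3, k] <- (p2 + p3) / 2
    }
  }
  rho_I <- mean(image)
  hist <- numeric(600)
  for (v in 1:3) {
    mags <- abs(U[, v, ] - Cv)            # np x 8
    rho_m <- mean(apply(mags, 2, mean))   # mean of per-direction means
    for (i in seq_len(np)) {
      sbits <- as.integer(U[i, v, ] - Cv[i] >= 0)
      mbits <- as.integer(mags[i, ] >= rho_m)
      s_code <- oracle_riu2(sbits)
      m_code <- oracle_riu2(mbits)
      c_bit <- as.integer(Cv[i] >= rho_I)
      bin <- (v - 1) * 200 + s_code * 20 + m_code * 2 + c_bit + 1
      hist[bin] <- hist[bin] + 1
    }
  }
  if (normalize) hist <- hist / sum(hist)
  hist
}

# Minimal EDF writer for reader tests: one data record per second, int16
# little-endian, physical = digital scaling chosen to pass zeros through.
write_minimal_edf <- function(path, n_channels, fs, seconds,
                              values = NULL) {
  pad <- function(s, n) formatC(s, width = -n)  # left-aligned, space padded
  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(pad(s, n), con, nchars = n, eos = NULL)
  ns <- n_channels
  header_bytes <- 256 + 256 * ns
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(header_bytes), 8); wr("", 44)
  wr(as.character(seconds), 8); wr("1", 8); wr(as.character(ns), 4)
  for (i in 1:ns) wr(sprintf("EEG ch%d", i), 16)
  for (i in 1:ns) wr("AgAgCl electrode", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr("-32768", 8)   # physical min
  for (i in 1:ns) wr("32767", 8)    # physical max
  for (i in 1:ns) wr("-32768", 8)   # digital min
  for (i in 1:ns) wr("32767", 8)    # digital max
  for (i in 1:ns) wr("none", 80)
  for (i in 1:ns) wr(as.character(fs), 8)
  for (i in 1:ns) wr("", 32)
  for (rec in seq_len(seconds)) {
    for (ch in 1:ns) {
      seg <- if (is.null(values)) integer(fs) else
        as.integer(values[ch, ((rec - 1) * fs + 1):(rec * fs)])
      writeBin(seg, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# Small fast pipeline config + matching synthetic spec for integration
# tests (4 channels, 5 s at 200 Hz keeps feature extraction to ~0.1 s per
# channel while exercising every stage).
tiny_spec <- function(seed = 11L) {
  synthetic_spec(channels = 4, duration = 5, seed = seed)
}
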