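# OMTLBP_SMC: multi-oriented, multi-scale local binary pattern texture
# descriptor with joint sign / magnitude / center histograms.
#
# For every interior pixel, 8-point neighborhoods are sampled at radii 1-3;
# radii 2 and 3 average 5 (22.5 deg apart) and 7 (15 deg apart) sub-samples
# per direction, an overlapped multi-oriented fusion. Adjacent radii are
# then averaged into three 8-point "topological structures" U1, U2, U3.
# Each structure's local differences against the center are split into sign
# and magnitude (LDSMT), encoded with the rotation-invariant uniform (riu2)
# scheme, joined with a one-bit center code, and accumulated into a
# 10 x 10 x 2 joint histogram per structure: 3 x 200 = 600 features.

P_POINTS <- 8L

# Sample offsets (dy, dx) for direction k of structure radius v. Angles are
# measured counter-clockwise from the +column axis; row indices grow
# downward, hence dy = -r sin(theta). cospi/sinpi give exact zeros at the
# axes, so axis-aligned samples hit integer pixels exactly.
omtlbp_offsets <- function(v, k, r1_mode = "circle") {
  if (v == 1L) {
    theta <- 45 * (k - 1)
    r <- if (identical(r1_mode, "integer8") && theta %% 90 != 0) sqrt(2) else 1
  } else if (v == 2L) {
    theta <- 22.5 * (0:4) + 45 * (k - 2)
    r <- 2
  } else {
    theta <- 15 * (0:6) + 45 * (k - 2)
    r <- 3
  }
  cbind(dy = -r * sinpi(theta / 180), dx = r * cospi(theta / 180))
}

bilinear_at <- function(image, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  if (fy < 1e-9) { fy <- 0 } else if (fy > 1 - 1e-9) { y0 <- y0 + 1; fy <- 0 }
  if (fx < 1e-9) { fx <- 0 } else if (fx > 1 - 1e-9) { x0 <- x0 + 1; fx <- 0 }
  y1 <- if (fy > 0) y0 + 1 else y0
  x1 <- if (fx > 0) x0 + 1 else x0
  (1 - fy) * (1 - fx) * image[y0, x0] + (1 - fy) * fx * image[y0, x1] +
    fy * (1 - fx) * image[y1, x0] + fy * fx * image[y1, x1]
}

#' Multi-oriented neighborhood samples around one pixel
#'
#' Returns the three 8-point sample rings: `P1[k]` is the pixel value at
#' angle 45(k-1) degrees, radius 1; `P2[k]` averages 5 sub-samples 22.5
#' degrees apart at radius 2; `P3[k]` averages 7 sub-samples 15 degrees
#' apart at radius 3 (both rings offset by 45(k-2) degrees, overlapping
#' adjacent octants by construction). Non-integer positions are bilinearly
#' interpolated.
#'
#' @param image Numeric matrix (grayscale, e.g. a rendered spectrogram).
#' @param row,col Pixel position, at least 3 pixels from every border.
#' @param r1_mode `"circle"` (radius exactly 1, diagonals interpolated) or
#'   `"integer8"` (diagonals snapped to the 8-connected integer neighbors).
#' @return List with `P1`, `P2`, `P3` (each length 8) and center `C`.
#' @export
sample_oriented <- function(image, row, col, r1_mode = c("circle", "integer8")) {
  r1_mode <- match.arg(r1_mode)
  if (row < 4 || col < 4 || row > nrow(image) - 3 || col > ncol(image) - 3) {
    stop("pixel must be at least 3 pixels away from every image border")
  }
  ring <- function(v) {
    vapply(seq_len(P_POINTS), function(k) {
      off <- omtlbp_offsets(v, k, r1_mode)
      mean(vapply(seq_len(nrow(off)), function(i) {
        bilinear_at(image, row + off[i, "dy"], col + off[i, "dx"])
      }, numeric(1)))
    }, numeric(1))
  }
  list(P1 = ring(1L), P2 = ring(2L), P3 = ring(3L), C = image[row, col])
}

#' Fuse adjacent radii into the three topological structures
#'
#' `U1 = P1` (the innermost ring, unfused), `U2 = (P1 + P2) / 2`,
#' `U3 = (P2 + P3) / 2`: similar orientations of adjacent radii averaged.
#'
#' @param samples Output of [sample_oriented()].
#' @return List with `U1`, `U2`, `U3` (each length 8) and center `C`.
#' @export
fuse_scales <- function(samples) {
  list(U1 = samples$P1,
       U2 = (samples$P1 + samples$P2) / 2,
       U3 = (samples$P2 + samples$P3) / 2,
       C = samples$C)
}

#' Local difference sign-magnitude transform (LDSMT)
#'
#' Decomposes the local differences `Q = U - C` into a sign component
#' (`+1` when `Q >= 0`, `-1` otherwise) and a magnitude component `|Q|`,
#' so that `s * m` reconstructs `Q` exactly.
#'
#' @param U Numeric vector of fused neighborhood values.
#' @param C Center value.
#' @return List with `signs` (in `{-1, +1}`) and `magnitudes` (`>= 0`).
#' @export
ldsmt <- function(U, C) {
  Q <- U - C
  list(signs = ifelse(Q >= 0, 1, -1), magnitudes = abs(Q))
}

# riu2 lookup: for every 8-bit pattern, the rotation-invariant uniform code
# (bit count if <= 2 circular transitions, else P + 1 = 9).
riu2_code_table <- local({
  tab <- integer(256)
  for (pat in 0:255) {
    bits <- as.integer(bitwAnd(bitwShiftR(pat, 0:7), 1L))
    trans <- sum(abs(diff(c(bits, bits[1L]))))
    tab[pat + 1L] <- if (trans <= 2L) sum(bits) else P_POINTS + 1L
  }
  tab
})

#' riu2 encoding of the sign component
#'
#' Signs map to bits (`+1 -> 1`, `-1 -> 0`); a pattern with at most 2
#' circular 0/1 transitions ("uniform") is encoded as its number of set
#' bits (0..8), all other patterns collapse to the catch-all code 9.
#'
#' @param signs Length-8 vector of `-1` / `+1`.
#' @return Integer code in `0..9`.
#' @export
encode_sign_riu2 <- function(signs) {
  stopifnot(length(signs) == P_POINTS, all(signs %in% c(-1, 1)))
  bits <- as.integer(signs > 0)
  riu2_code_table[sum(bits * 2L^(seq_len(P_POINTS) - 1L)) + 1L]
}

#' riu2 encoding of the magnitude component
#'
#' Magnitudes are thresholded against `rho_m` (bit 1 iff `m >= rho_m`,
#' the threshold being the mean magnitude of the structure over the image),
#' then riu2-encoded like the sign component.
#'
#' @param magnitudes Length-8 nonnegative vector.
#' @param rho_m Nonnegative threshold.
#' @return Integer code in `0..9`.
#' @export
encode_magnitude_riu2 <- function(magnitudes, rho_m) {
  stopifnot(length(magnitudes) == P_POINTS)
  bits <- as.integer(magnitudes >= rho_m)
  riu2_code_table[sum(bits * 2L^(seq_len(P_POINTS) - 1L)) + 1L]
}

#' Center-pixel code
#'
#' @param C Center value.
#' @param rho_I Global image mean.
#' @return 1 when `C >= rho_I`, else 0.
#' @export
encode_center <- function(C, rho_I) as.integer(C >= rho_I)

# Interpolated shift of the interior block: value of `image` at
# (rows + dy, cols + dx) for the constant fractional offset (dy, dx),
# |dy|, |dx| <= 3, computed as a weighted sum of four integer-shifted
# submatrices. Near-integer offsets are snapped so indices stay in bounds.
interp_shift_block <- function(image, rows, cols, dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  if (fy < 1e-9) { fy <- 0 } else if (fy > 1 - 1e-9) { y0 <- y0 + 1; fy <- 0 }
  if (fx < 1e-9) { fx <- 0 } else if (fx > 1 - 1e-9) { x0 <- x0 + 1; fx <- 0 }
  blk <- function(oy, ox) image[rows + oy, cols + ox, drop = FALSE]
  out <- (1 - fy) * (1 - fx) * blk(y0, x0)
  if (fx > 0) out <- out + (1 - fy) * fx * blk(y0, x0 + 1)
  if (fy > 0) out <- out + fy * (1 - fx) * blk(y0 + 1, x0)
  if (fy > 0 && fx > 0) out <- out + fy * fx * blk(y0 + 1, x0 + 1)
  out
}

#' OMTLBP_SMC texture descriptor of a grayscale image
#'
#' Computes, for every interior pixel (3-pixel border excluded) and each of
#' the three fused structures, the joint (sign code, magnitude code, center
#' bit) triple and accumulates it into a 10 x 10 x 2 histogram per
#' structure. The three 200-bin histograms are concatenated (structures 1,
#' 2, 3; within each, sign slowest, then magnitude, then center) into the
#' 600-dimensional texture feature vector.
#'
#' The magnitude threshold `rho_m` is the image-level mean magnitude of each
#' structure; the center threshold `rho_I` is the global image mean.
#'
#' @param image Numeric grayscale matrix, at least 7 x 7 (typically the
#'   `gray` plane of [render_image()], values in `[0, 1]`).
#' @param normalize L1-normalize the histogram (sum 1). Unnormalized, the
#'   histogram sums to `3 * number of interior pixels`.
#' @param r1_mode Radius-1 sampling mode, see [sample_oriented()].
#' @return Numeric vector of length 600 with attribute `"normalized"`.
#' @export
#' @examples
#' img <- matrix(runif(16 * 16), 16, 16)
#' d <- omtlbp_describe(img)
#' length(d)  # 600
omtlbp_describe <- function(image, normalize = TRUE,
                            r1_mode = c("circle", "integer8")) {
  r1_mode <- match.arg(r1_mode)
  if (!is.matrix(image) || nrow(image) < 7 || ncol(image) < 7) {
    stop("image must be a numeric matrix of at least 7 x 7 pixels")
  }
  rows <- 4:(nrow(image) - 3)
  cols <- 4:(ncol(image) - 3)
  n_int <- length(rows) * length(cols)
  # fused rings as interior-block matrices: ring v, direction k
  ring_block <- function(v, k) {
    off <- omtlbp_offsets(v, k, r1_mode)
    acc <- 0
    for (i in seq_len(nrow(off))) {
      acc <- acc + interp_shift_block(image, rows, cols, off[i, 1], off[i, 2])
    }
    acc / nrow(off)
  }
  P1 <- lapply(1:8, function(k) ring_block(1L, k))
  P2 <- lapply(1:8, function(k) ring_block(2L, k))
  P3 <- lapply(1:8, function(k) ring_block(3L, k))
  U <- list(P1,
            lapply(1:8, function(k) (P1[[k]] + P2[[k]]) / 2),
            lapply(1:8, function(k) (P2[[k]] + P3[[k]]) / 2))
  C <- image[rows, cols, drop = FALSE]
  cbit <- as.integer(C >= mean(image))
  pow2 <- 2L^(0:7)
  hist <- numeric(600)
  for (v in 1:3) {
    Q <- lapply(U[[v]], function(u) u - C)
    mags <- lapply(Q, abs)
    rho_m <- mean(vapply(mags, mean, numeric(1)))
    sidx <- 0L; midx <- 0L
    for (k in 1:8) {
      sidx <- sidx + as.integer(Q[[k]] >= 0) * pow2[k]
      midx <- midx + as.integer(mags[[k]] >= rho_m) * pow2[k]
    }
    s_code <- riu2_code_table[sidx + 1L]
    m_code <- riu2_code_table[midx + 1L]
    bin <- s_code * 20L + m_code * 2L + cbit + 1L   # s slowest, then m, then c
    hist[(v - 1L) * 200L + seq_len(200L)] <- tabulate(bin, nbins = 200L)
  }
  if (normalize) hist <- hist / sum(hist)
  structure(hist, normalized = normalize, interior_pixels = n_int)
}
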