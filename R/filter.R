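# Butterworth band-pass design and zero-phase application.
#
# No DSP package is assumed: the design follows the classical route —
# analog low-pass prototype poles, low-pass -> band-pass transformation,
# bilinear transform with frequency prewarping — and matches the standard
# scipy/MATLAB butter() coefficients (cross-checked in the test suite).

#' Band-pass filter specification
#'
#' Defaults encode the conventional EEG analysis band: order-4 Butterworth,
#' 4-45 Hz, applied forward-backward (zero phase, so the effective magnitude
#' response is squared and no group delay is introduced).
#'
#' @param low_cut,high_cut Band edges in Hz.
#' @param order Butterworth prototype order (the band-pass filter has twice
#'   this many poles).
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_cut = 4, high_cut = 45, order = 4, zero_phase = TRUE) {
  if (!(low_cut > 0 && high_cut > low_cut)) {
    stop("need 0 < low_cut < high_cut")
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Digital Butterworth band-pass (b, a) for band [low, high] Hz at rate fs.
butter_bandpass <- function(low, high, fs, order = 4L) {
  if (high >= fs / 2) {
    stop(sprintf("high_cut %g Hz is at or above the Nyquist limit fs/2 = %g Hz",
                 high, fs / 2))
  }
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)    # prewarped analog edge frequencies
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p_lp <- exp(1i * theta)           # unit-circle left-half-plane prototype poles
  # low-pass -> band-pass: each pole splits into a conjugate pair
  plp <- p_lp * bw / 2
  disc <- sqrt(plp^2 - w0^2)
  p_bp <- c(plp + disc, plp - disc)
  z_bp <- rep(0 + 0i, order)        # 'order' zeros at s = 0
  k_bp <- bw^order
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  pz <- (fs2 + p_bp) / (fs2 - p_bp)
  zz <- (fs2 + z_bp) / (fs2 - z_bp)
  kz <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  zz <- c(zz, rep(-1 + 0i, length(pz) - length(zz)))   # zeros at z = -1
  b <- Re(kz * poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

# Monic polynomial coefficients (descending powers) from its roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

#' Magnitude response of the configured band-pass filter
#'
#' Evaluates the filter's frequency response on the unit circle. In
#' zero-phase mode the forward-backward application squares the magnitude,
#' which is what this reports.
#'
#' @param fspec A [filter_spec()].
#' @param fs Sampling rate (Hz) the filter would be applied at.
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @return Data frame with `freq`, `mag` (linear) and `db` columns.
#' @export
filter_response <- function(fspec, fs, freqs) {
  ba <- butter_bandpass(fspec$low_cut, fspec$high_cut, fs, fspec$order)
  w <- 2 * pi * freqs / fs
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(ba$b) - 1))
    abs(sum(ba$b * z) / sum(ba$a * z))
  }, numeric(1))
  if (fspec$zero_phase) H <- H^2
  data.frame(freq = freqs, mag = H, db = 20 * log10(pmax(H, .Machine$double.xmin)))
}

# Forward(-backward) IIR filtering with odd-reflection edge padding.
apply_iir <- function(x, b, a, zero_phase = TRUE) {
  npad <- 3L * (length(b) - 1L)     # enough to absorb the IIR transient
  if (length(x) <= npad) {
    stop(sprintf("signal too short to filter: need > %d samples", npad))
  }
  left <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, by = -1L, length.out = npad)]
  xp <- c(left, x, right)
  y <- iir_filter(b, a, xp)
  if (zero_phase) y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1L):(npad + length(x))]
}

#' Band-pass filter an EEG trial
#'
#' Each channel is filtered independently with the Butterworth band-pass of
#' `spec`, forward-backward when `zero_phase` (the default), after
#' odd-reflection padding at both ends to suppress edge transients. Shape,
#' sampling rate and metadata are preserved; the applied filter is recorded
#' in `trial$meta$filters`.
#'
#' @param trial An [eeg_trial()].
#' @param spec A [filter_spec()]; `high_cut` must be below `trial$fs / 2`.
#' @return The filtered [eeg_trial()].
#' @export
#' @examples
#' tr <- generate_trial(synthetic_spec(), 0, trial_seed = 7)
#' filt <- bandpass_filter(tr, filter_spec())
bandpass_filter <- function(trial, spec = filter_spec()) {
  stopifnot_trial(trial)
  stopifnot(inherits(spec, "filter_spec"))
  ba <- butter_bandpass(spec$low_cut, spec$high_cut, trial$fs, spec$order)
  out <- trial
  for (i in seq_len(nrow(trial$samples))) {
    out$samples[i, ] <- apply_iir(trial$samples[i, ], ba$b, ba$a, spec$zero_phase)
  }
  out$meta$filters <- c(trial$meta$filters, list(unclass(spec)))
  out
}

#' Restrict a trial to named channels
#'
#' @param trial An [eeg_trial()].
#' @param names Channel labels to keep, in the requested output order.
#' @return The trial restricted to those channels.
#' @export
select_channels <- function(trial, names) {
  stopifnot_trial(trial)
  missing <- setdiff(names, trial$channel_names)
  if (length(missing) > 0) {
    stop(sprintf("unknown channel name(s): %s", paste(missing, collapse = ", ")))
  }
  idx <- match(names, trial$channel_names)
  out <- trial
  out$samples <- trial$samples[idx, , drop = FALSE]
  out$channel_names <- trial$channel_names[idx]
  out
}

#' Rank channels by signal variance
#'
#' Convenience helper for picking a channel subset when a dataset preset
#' does not fix one. This is a heuristic, not a canonical selection
#' algorithm: subsets remain plain configuration.
#'
#' @param trial An [eeg_trial()].
#' @return Channel names sorted by decreasing variance.
#' @export
rank_channels_by_variance <- function(trial) {
  stopifnot_trial(trial)
  v <- apply(trial$samples, 1, stats::var)
  trial$channel_names[order(v, decreasing = TRUE)]
}
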