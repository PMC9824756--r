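# Synthetic EEG with class-conditional band-power signatures.
#
# Each channel is a 1/f^alpha noise floor (white Gaussian noise shaped in the
# frequency domain) plus, for each of the class's oscillation bands, an
# amplitude-modulated sinusoid with per-channel random carrier frequency,
# phase, and slow burst envelope. Optional artifacts (50 Hz line, <1 Hz
# drift) exercise the band-pass filter. Everything is a pure function of
# (spec, seeds).

#' Specification of a synthetic EEG dataset
#'
#' @param n_classes Number of emotion classes.
#' @param channels Number of EEG channels per trial.
#' @param fs Sampling rate (Hz).
#' @param duration Trial duration (seconds).
#' @param class_bands List of length `n_classes`; element `c` is a numeric
#'   matrix with columns `low`, `high`, `power` — each row an oscillation
#'   band (Hz) for class `c` with its amplitude relative to the unit-RMS
#'   noise floor. Defaults place the three classes in well separated theta
#'   (5-7 Hz), alpha (10-13 Hz) and beta (22-30 Hz) bands.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param noise_scale RMS of the background noise (0 disables it).
#' @param line_noise,drift Add a 50 Hz mains component / a 0.3 Hz baseline
#'   drift, both outside the 4-45 Hz analysis band.
#' @param seed Integer master seed; dataset generation is a pure function of
#'   the spec (including this seed).
#' @return A `synthetic_spec` object.
#' @export
#' @examples
#' spec <- synthetic_spec()
#' tr <- generate_trial(spec, class_id = 1, trial_seed = 42)
synthetic_spec <- function(n_classes = 3, channels = 8, fs = 200, duration = 10,
                           class_bands = NULL, noise_exponent = 1.0,
                           noise_scale = 1.0, line_noise = FALSE, drift = FALSE,
                           seed = 1L) {
  if (is.null(class_bands)) {
    defaults <- list(c(5, 7), c(10, 13), c(22, 30), c(32, 40), c(14, 18))
    if (n_classes > length(defaults)) {
      stop("provide `class_bands` explicitly for more than 5 classes")
    }
    class_bands <- lapply(seq_len(n_classes), function(c) {
      cbind(low = defaults[[c]][1], high = defaults[[c]][2], power = 1.5)
    })
  }
  if (length(class_bands) != n_classes) {
    stop("`class_bands` must have one entry per class")
  }
  class_bands <- lapply(class_bands, function(b) {
    b <- matrix(as.numeric(b), ncol = 3,
                dimnames = list(NULL, c("low", "high", "power")))
    bad <- b[, "low"] <= 0 | b[, "high"] >= fs / 2 | b[, "low"] >= b[, "high"]
    if (any(bad)) {
      stop(sprintf("class band [%g, %g] Hz outside (0, fs/2) = (0, %g)",
                   b[which(bad)[1], "low"], b[which(bad)[1], "high"], fs / 2))
    }
    b
  })
  structure(
    list(n_classes = as.integer(n_classes), channels = as.integer(channels),
         fs = fs, duration = duration, class_bands = class_bands,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         line_noise = isTRUE(line_noise), drift = isTRUE(drift),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Named synthetic presets mirroring benchmark dataset geometries
#'
#' `"default"` is the small test geometry (8 channels, 200 Hz, 10 s);
#' `"deap_like"` mirrors the 32-channel, 128 Hz, 63 s layout of a common
#' video-stimulus emotion benchmark.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_preset <- function(name = c("default", "deap_like"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    default   = list(),
    deap_like = list(channels = 32, fs = 128, duration = 63))
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

# Run expr with a private RNG stream; the global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# 1/f^alpha noise, length n, unit RMS (zero vector when the spectrum is flat
# zero). Shaped in the frequency domain from white Gaussian noise.
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w / stats::sd(w))
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                 # DC kept at weight of bin 1
  f <- pmin(f, n - f + 1)                   # fold to two-sided frequencies
  W <- W * f^(-alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate one labeled synthetic EEG trial
#'
#' @param spec A [synthetic_spec()].
#' @param class_id 0-based class index, `< spec$n_classes`.
#' @param trial_seed Integer seed for this trial; same `(spec, class_id,
#'   trial_seed)` reproduces the trial bit-identically.
#' @return An [eeg_trial()] with `label = class_id`.
#' @export
generate_trial <- function(spec, class_id, trial_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (class_id < 0 || class_id >= spec$n_classes) {
    stop(sprintf("class_id %d out of range [0, %d)", class_id, spec$n_classes))
  }
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1) / spec$fs
  bands <- spec$class_bands[[class_id + 1L]]
  samples <- with_seed(trial_seed, {
    do.call(rbind, lapply(seq_len(spec$channels), function(ch) {
      x <- if (spec$noise_scale > 0) {
        spec$noise_scale * pink_noise(n, spec$noise_exponent)
      } else numeric(n)
      for (b in seq_len(nrow(bands))) {
        if (bands[b, "power"] <= 0) next
        f0 <- stats::runif(1, bands[b, "low"], bands[b, "high"])
        phase <- stats::runif(1, 0, 2 * pi)
        amp <- bands[b, "power"] * stats::runif(1, 0.8, 1.2)
        f_env <- stats::runif(1, 0.1, 0.5)   # slow burst envelope
        env <- 0.5 * (1 + sin(2 * pi * f_env * t + stats::runif(1, 0, 2 * pi)))
        x <- x + amp * env * sin(2 * pi * f0 * t + phase)
      }
      if (spec$line_noise) x <- x + 0.8 * sin(2 * pi * 50 * t)
      if (spec$drift) x <- x + 2.0 * sin(2 * pi * 0.3 * t)
      x
    }))
  })
  tr <- eeg_trial(samples, fs = spec$fs, label = class_id,
                  trial_id = sprintf("c%d_seed%d", class_id, trial_seed))
  tr$meta$trial_seed <- as.integer(trial_seed)
  tr
}

#' Generate a balanced labeled synthetic dataset
#'
#' Trial seeds are derived deterministically from `spec$seed` so the whole
#' dataset is a pure function of `(spec, trials_per_class)` and no two trials
#' share a seed.
#'
#' @param spec A [synthetic_spec()].
#' @param trials_per_class Trials to generate for each class (>= 1).
#' @return List of [eeg_trial()], `n_classes * trials_per_class` long,
#'   grouped by class.
#' @export
generate_dataset <- function(spec, trials_per_class) {
  stopifnot(inherits(spec, "synthetic_spec"), trials_per_class >= 1)
  out <- vector("list", spec$n_classes * trials_per_class)
  i <- 0L
  for (cls in seq_len(spec$n_classes) - 1L) {
    for (k in seq_len(trials_per_class)) {
      i <- i + 1L
      # double arithmetic: keeps the derived seed < 2^31 without int overflow
      seed <- as.integer((spec$seed %% 65011) * 32768 + cls * 4096 + k)
      tr <- generate_trial(spec, cls, trial_seed = seed)
      tr$trial_id <- sprintf("c%d_t%03d", cls, k)
      out[[i]] <- tr
    }
  }
  out
}
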