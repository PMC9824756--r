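# Trial I/O: package-native text container + manifest, generic EDF reading.
#
# Native layout: <dir>/manifest.csv plus one "<trial_id>.eegtxt" per trial.
# Each trial file is a TSV: one "#key=value" header line (fs, subject, label),
# then one row per channel ("name\tv1\tv2..."). Doubles are printed with
# "%.17g" so write -> read -> write is a byte-identical fixed point.

fmt_dbl <- function(x) sprintf("%.17g", x)

#' Write EEG trials to a native directory container
#'
#' Creates `path` (a directory) holding one plain-text matrix file per trial
#' plus a `manifest.csv` with columns `trial_id, subject_id, label, fs, seed,
#' file`. [read_trials()] inverts it exactly: samples, sampling rate, labels
#' and channel names round-trip bit-identically.
#'
#' @param trials List of [eeg_trial()] objects (may be empty).
#' @param path Output directory; created if missing.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (!all(vapply(trials, is_eeg_trial, logical(1)))) {
    stop("`trials` must be a list of eeg_trial objects")
  }
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", path))
  rows <- character(0)
  for (tr in trials) {
    file <- paste0(tr$trial_id, ".eegtxt")
    dest <- file.path(path, file)
    hdr <- sprintf("#fs=%s subject=%s label=%s", fmt_dbl(tr$fs), tr$subject_id,
                   if (is.na(tr$label)) "NA" else tr$label)
    body <- vapply(seq_len(nrow(tr$samples)), function(i) {
      paste(c(tr$channel_names[i], fmt_dbl(tr$samples[i, ])), collapse = "\t")
    }, character(1))
    con <- file(dest, open = "wb")  # "wb": fixed \n line endings on any OS
    on.exit(close(con), add = TRUE)
    writeLines(c(hdr, body), con, sep = "\n")
    close(con)
    on.exit()
    seed <- tr$meta$trial_seed
    rows <- c(rows, sprintf("%s,%s,%s,%s,%s,%s", tr$trial_id, tr$subject_id,
                            if (is.na(tr$label)) "" else tr$label,
                            fmt_dbl(tr$fs),
                            if (is.null(seed)) "" else seed, file))
  }
  con <- file(file.path(path, "manifest.csv"), open = "wb")
  writeLines(c("trial_id,subject_id,label,fs,seed,file", rows), con, sep = "\n")
  close(con)
  invisible(path)
}

read_native_trial <- function(dest) {
  lines <- readLines(dest)
  if (length(lines) < 2L || !startsWith(lines[1L], "#")) {
    stop(sprintf("malformed native trial file '%s'", dest))
  }
  kv <- strsplit(sub("^#", "", lines[1L]), " ", fixed = TRUE)[[1L]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  fs <- as.numeric(vals[keys == "fs"])
  label <- vals[keys == "label"]
  label <- if (identical(label, "NA")) NA_integer_ else as.integer(label)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  names <- vapply(parts, `[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  eeg_trial(mat, fs = fs, channel_names = names, label = label,
            subject_id = vals[keys == "subject"],
            trial_id = sub("\\.eegtxt$", "", basename(dest)))
}

#' Read EEG trials from disk
#'
#' @param path For `"native"`, a directory written by [write_trials()]; for
#'   `"edf"`, one EDF file.
#' @param format One of `"native"`, `"edf"`, `"deap_mat"`, `"seed_mat"`.
#'   The MATLAB adapters for the DEAP/SEED benchmark layouts need an external
#'   `.mat` reader and raise an informative error when none is installed.
#' @return List of [eeg_trial()] objects, labels populated when the source
#'   provides them (`NA` otherwise, with a warning for a native manifest that
#'   lacks the label column).
#' @export
read_trials <- function(path, format = c("native", "edf", "deap_mat", "seed_mat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("path '%s' does not exist", path))
  switch(format,
    native = {
      mf <- file.path(path, "manifest.csv")
      if (!file.exists(mf)) stop(sprintf("no manifest.csv in '%s'", mf))
      man <- utils::read.csv(mf, colClasses = "character")
      if (!"label" %in% names(man)) {
        warning(sprintf("manifest '%s' has no label column; labels set to NA", mf))
        man$label <- NA_character_
      }
      trials <- lapply(seq_len(nrow(man)), function(i) {
        tr <- read_native_trial(file.path(path, man$file[i]))
        lab <- man$label[i]
        tr$label <- if (is.na(lab) || !nzchar(lab)) NA_integer_ else as.integer(lab)
        seed <- man$seed[i]
        if (!is.na(seed) && nzchar(seed)) tr$meta$trial_seed <- as.integer(seed)
        tr
      })
      trials
    },
    edf = list(read_edf(path)),
    deap_mat = ,
    seed_mat = stop(sprintf(
      "format '%s' needs a MATLAB .mat reader (e.g. the R.matlab package), %s",
      format, "which is not installed; convert to 'native' or 'edf' instead"))
  )
}

# Minimal EDF reader: fixed-width ASCII header, int16 little-endian records,
# digital-to-physical linear scaling. Annotation channels are not handled.
read_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- rawToChar(readBin(con, "raw", n))
    trimws(x)
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)  # patient, recording, start date/time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop(sprintf("malformed EDF header in '%s'", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(spr)) || any(is.na(pmin))) {
    stop(sprintf("malformed EDF signal headers in '%s'", path))
  }
  seek(con, header_bytes)
  if (length(unique(spr)) != 1L) {
    stop(sprintf("EDF '%s' mixes sampling rates across channels; unsupported", path))
  }
  fs <- spr[1L] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, endian = "little")
      phys <- (dig - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s]) + pmin[s]
      sig[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  eeg_trial(sig, fs = fs, channel_names = make.unique(labels),
            trial_id = sub("\\.[^.]*$", "", basename(path)))
}
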