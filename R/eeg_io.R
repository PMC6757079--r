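#' Construct and validate a raw EEG recording
#'
#' The basic container of the pipeline: a channels-by-samples numeric matrix
#' in microvolts plus its sampling rate.  All downstream stages (rhythm
#' extraction, windowing) operate on this object or on its band-filtered
#' sibling [rhythm_signal].
#'
#' @param data numeric matrix, `n_channels x n_samples`, microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one unique name per channel.
#'   Defaults to `CH1 ... CHn`.
#' @param trial_id identifier string carried through the pipeline.
#' @return An object of class `raw_eeg` with fields `data`, `fs`,
#'   `channel_names`, `trial_id`.
#' @examples
#' x <- raw_eeg(matrix(rnorm(512), nrow = 2), fs = 256)
#' n_channels(x); n_samples(x)
#' @export
raw_eeg <- function(data, fs, channel_names = NULL, trial_id = "trial") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("`data` must have at least one channel and one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length (", length(channel_names),
         ") must equal the number of channels (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(data))
    stop("non-finite sample in channel '", channel_names[idx[1L]],
         "' at sample index ", idx[2L])
  }
  storage.mode(data) <- "double"
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = channel_names, trial_id = as.character(trial_id)),
    class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg '%s'> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' @rdname raw_eeg
#' @param x a `raw_eeg` or `rhythm_signal` object.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname raw_eeg
#' @export
n_samples <- function(x) ncol(x$data)

# ---------------------------------------------------------------------------
# Plain matrix format: one comment header line carrying metadata, then one
# whitespace-delimited row of samples per channel.  Dependency-free, diffable,
# and bit-exact on round-trip -- the format used for all text fixtures.
# ---------------------------------------------------------------------------

#' Read an EEG recording from disk
#'
#' Two on-disk representations are supported: EDF (16-bit European Data
#' Format, the clinical interchange standard) and a plain-text matrix format
#' (`# fs=<Hz> channels=<comma-separated names>` header line followed by one
#' numeric row per channel).  The matrix format round-trips bit-exactly; EDF
#' quantizes to 16 bits over the per-channel physical range.
#'
#' @param path file to read.
#' @param format `"edf"` or `"matrix"`; default guesses from the extension.
#' @return A [raw_eeg] object; channel order as stored in the file.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") read_edf(path) else read_matrix_recording(path)
}

#' Write an EEG recording to disk
#'
#' @param x a [raw_eeg] (or [rhythm_signal]) object.
#' @param path output file.
#' @param format `"edf"` or `"matrix"` (see [read_recording()]).
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") write_edf(x, path) else write_matrix_recording(x, path)
  invisible(path)
}

read_matrix_recording <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#\\s*fs=", header))
    stop("missing sampling-rate header ('# fs=... channels=...') in '", path, "'")
  fs <- as.numeric(sub("^#\\s*fs=([0-9.eE+-]+).*$", "\\1", header))
  if (!is.finite(fs)) stop("cannot parse sampling rate from header of '", path, "'")
  ch <- sub("^.*channels=([^ ]*).*$", "\\1", header)
  channel_names <- if (identical(ch, header)) NULL else strsplit(ch, ",")[[1L]]
  trial_id <- if (grepl("trial_id=", header))
    sub("^.*trial_id=([^ ]*).*$", "\\1", header)
  else sub("\\.[^.]*$", "", basename(path))
  dat <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(dat) <- NULL
  raw_eeg(dat, fs = fs, channel_names = channel_names, trial_id = trial_id)
}

write_matrix_recording <- function(x, path) {
  header <- sprintf("# fs=%.10g channels=%s trial_id=%s",
                    x$fs, paste(x$channel_names, collapse = ","), x$trial_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(x$data, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format) support, written against the published
# header layout: 256-byte fixed header + 256 bytes per signal, then data
# records of little-endian int16 samples.  Physical range is set per channel
# from the data; 16-bit quantization is therefore (max-min)/65535 per channel.
# ---------------------------------------------------------------------------

edf_pad <- function(s, width) {
  s <- substr(format(s, width = width), 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

write_edf <- function(x, path) {
  nch <- nrow(x$data); N <- ncol(x$data)
  # choose samples-per-record: a divisor of N keeping each record <= 61440 bytes
  max_spr <- max(1L, (61440L %/% 2L) %/% nch)
  spr <- N
  if (spr > max_spr) {
    divs <- which(N %% seq_len(min(N, max_spr)) == 0L)
    spr <- max(divs)
  }
  nrec <- N %/% spr
  pmin <- apply(x$data, 1L, min); pmax <- apply(x$data, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),                                   # version
    edf_pad(x$trial_id, 80L),                           # patient id field
    edf_pad("rhythmeeg export", 80L),                   # recording id field
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),   # start date/time
    edf_pad(256L * (nch + 1L), 8L),                     # header bytes
    edf_pad("", 44L),                                   # reserved
    edf_pad(nrec, 8L),
    edf_pad(format(spr / x$fs, digits = 8), 8L),        # record duration (s)
    edf_pad(nch, 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(x$channel_names, 16L)                           # label
  field(rep("", nch), 80L)                              # transducer
  field(rep("uV", nch), 8L)                             # physical dimension
  field(format(pmin, digits = 8), 8L)
  field(format(pmax, digits = 8), 8L)
  field(rep(dmin, nch), 8L)
  field(rep(dmax, nch), 8L)
  field(rep("", nch), 80L)                              # prefiltering
  field(rep(spr, nch), 8L)
  field(rep("", nch), 32L)                              # reserved
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ci in seq_len(nch)) {
      dig <- round((x$data[ci, idx] - pmin[ci]) / scale[ci] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L)                       # version
  trial_id <- rd(80L)
  rd(80L); rd(8L); rd(8L); rd(8L); rd(44L)
  nrec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  nch <- as.integer(rd(4L))
  if (!isTRUE(nch >= 1L)) stop("'", path, "' is not a readable EDF file")
  rdn <- function(width) vapply(seq_len(nch), function(i) rd(width), "")
  labels <- rdn(16L); rdn(80L); rdn(8L)
  pmin <- as.numeric(rdn(8L)); pmax <- as.numeric(rdn(8L))
  dmin <- as.numeric(rdn(8L)); dmax <- as.numeric(rdn(8L))
  rdn(80L)
  spr <- as.integer(rdn(8L)); rdn(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  spr <- spr[1L]
  if (!is.finite(rec_dur) || rec_dur <= 0)
    stop("missing or invalid record duration (sampling rate) in '", path, "'")
  fs <- spr / rec_dur
  dat <- matrix(0, nrow = nch, ncol = nrec * spr)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ci in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                     endian = "little")
      dat[ci, idx] <- (dig - dmin[ci]) * scale[ci] + pmin[ci]
    }
  }
  raw_eeg(dat, fs = fs, channel_names = labels,
          trial_id = if (nzchar(trial_id)) trial_id else basename(path))
}

# ---------------------------------------------------------------------------
# Trial labels
# ---------------------------------------------------------------------------

#' Binarize a 1-9 affect rating
#'
#' Ratings at or below 3 map to the low class, at or above 7 to the high
#' class; the ambiguous middle (3, 7) is excluded from classification.  Both
#' boundaries are inclusive.
#'
#' @param score numeric vector of ratings in `[1, 9]`.
#' @param low,high class names for the two retained bins.
#' @return factor with levels `c(low, high, "excluded")`.
#' @export
binarize_rating <- function(score, low = "negative", high = "positive") {
  if (any(!is.finite(score) | score < 1 | score > 9))
    stop("ratings must be finite and lie in [1, 9]")
  cls <- ifelse(score <= 3, low, ifelse(score >= 7, high, "excluded"))
  factor(cls, levels = c(low, high, "excluded"))
}

#' Read per-trial valence/arousal ratings
#'
#' Expects a delimited text file (comma or tab, header row) with columns
#' `trial_id`, `valence`, `arousal`, ratings on the 1-9 self-assessment
#' scale.  Each rating is binarized with [binarize_rating()]: valence into
#' negative/positive, arousal into passive/active.
#'
#' @param path delimited text file.
#' @return data.frame of class `trial_labels` with columns `trial_id`,
#'   `score_valence`, `score_arousal`, `class_valence`, `class_arousal`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("trial_id", "valence", "arousal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("label file is missing column(s): ", paste(miss, collapse = ", "))
  trial_labels(df$trial_id, df$valence, df$arousal)
}

#' Assemble a trial-label table
#'
#' @param trial_id character vector of unique trial identifiers.
#' @param valence,arousal numeric ratings in `[1, 9]`.
#' @return see [read_labels()].
#' @export
trial_labels <- function(trial_id, valence, arousal) {
  trial_id <- as.character(trial_id)
  if (anyDuplicated(trial_id))
    stop("duplicate trial_id: ",
         paste(unique(trial_id[duplicated(trial_id)]), collapse = ", "))
  out <- data.frame(
    trial_id = trial_id,
    score_valence = as.numeric(valence),
    score_arousal = as.numeric(arousal),
    stringsAsFactors = FALSE)
  out$class_valence <- binarize_rating(out$score_valence, "negative", "positive")
  out$class_arousal <- binarize_rating(out$score_arousal, "passive", "active")
  class(out) <- c("trial_labels", "data.frame")
  out
}

#' Downsample a recording
#'
#' Applies a zero-phase 8th-order Butterworth low-pass at 80% of the target
#' Nyquist (forward-backward filtering, so no group delay and content above
#' `target_fs / 2` is attenuated by more than 40 dB), then decimates:
#' directly for integer rate ratios, via Fourier-domain resampling for
#' rational ones.
#'
#' @param x a [raw_eeg] object.
#' @param target_fs new sampling rate in Hz; must not exceed `x$fs`.
#' @return a [raw_eeg] at `target_fs` with
#'   `round(n_samples * target_fs / fs)` samples per channel.
#' @export
downsample <- function(x, target_fs) {
  stopifnot(inherits(x, "raw_eeg") || inherits(x, "rhythm_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("`target_fs` must be a single positive number")
  if (target_fs > x$fs)
    stop("upsampling is not supported (target_fs = ", target_fs,
         " > fs = ", x$fs, ")")
  if (target_fs == x$fs) return(x)
  N <- ncol(x$data)
  M <- as.integer(round(N * target_fs / x$fs))
  if (M < 1L) stop("recording too short to resample to ", target_fs, " Hz")
  q <- x$fs / target_fs
  integer_ratio <- abs(q - round(q)) < 1e-9
  out <- matrix(0, nrow = nrow(x$data), ncol = M)
  bf <- signal::butter(8, 0.8 * target_fs / x$fs, type = "low")
  for (ci in seq_len(nrow(x$data))) {
    y <- signal::filtfilt(bf, x$data[ci, ])
    if (integer_ratio) {
      y <- y[seq(1L, N, by = as.integer(round(q)))]
      if (length(y) > M) y <- y[seq_len(M)]
      if (length(y) < M) y <- c(y, rep(y[length(y)], M - length(y)))
    } else {
      y <- fft_resample(y, M)
    }
    out[ci, ] <- y
  }
  raw_eeg(out, fs = target_fs, channel_names = x$channel_names,
          trial_id = x$trial_id)
}

# Fourier-domain resampling to M samples (zero phase; input is expected to
# be band-limited below the new Nyquist already).
fft_resample <- function(x, M) {
  N <- length(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(M), imaginary = numeric(M))
  half <- (min(M, N) - 1L) %/% 2L
  Y[1L] <- X[1L]
  if (half >= 1L) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    Y[(M - half + 1L):M] <- X[(N - half + 1L):N]
  }
  Re(stats::fft(Y, inverse = TRUE)) / N
}

#' Optional artifact-removal hook
#'
#' Artifact removal / blind source separation (e.g. ICA in an external
#' toolbox) sits upstream of this pipeline; public preprocessed datasets are
#' distributed already cleaned.  The hook lets a caller slot a cleaning
#' function into [run_grid()]-style workflows; the default is a pass-through.
#'
#' @param x a [raw_eeg] object.
#' @param fn `function(raw_eeg) -> raw_eeg`, or `NULL` for pass-through.
#' @return the (possibly cleaned) recording.
#' @export
preprocess_hook <- function(x, fn = NULL) {
  if (is.null(fn)) return(x)
  out <- fn(x)
  if (!inherits(out, "raw_eeg"))
    stop("preprocessing hook must return a raw_eeg object")
  out
}

#' Load a directory of trials in the layout of the DEAP benchmark
#'
#' Optional adapter for a locally available copy of a DEAP-style affect
#' dataset (32 subjects x 40 one-minute music-video trials with 1-9
#' valence/arousal self-ratings).  The adapter expects a directory holding
#' `labels.csv` (columns `trial_id`, `valence`, `arousal`) and one recording
#' per trial named `<trial_id>.txt` (matrix format) or `<trial_id>.edf`.
#' The sampling rate is taken from each file's metadata and reported, never
#' assumed: published releases of such datasets differ in rate.
#'
#' @param path dataset directory.
#' @return list with elements `trials` (list of [raw_eeg]) and `labels`
#'   (a `trial_labels` data.frame), aligned by `trial_id`.
#' @export
load_deap_trial_set <- function(path) {
  if (!dir.exists(path))
    stop("DEAP-style dataset directory '", path, "' not found. ",
         "This adapter is optional: the core pipeline does not require it.")
  lab_path <- file.path(path, "labels.csv")
  if (!file.exists(lab_path))
    stop("dataset directory '", path, "' has no labels.csv; ",
         "this optional adapter needs the documented layout")
  labels <- read_labels(lab_path)
  trials <- lapply(labels$trial_id, function(id) {
    for (ext in c(".txt", ".edf")) {
      f <- file.path(path, paste0(id, ext))
      if (file.exists(f)) return(read_recording(f))
    }
    stop("no recording found for trial '", id, "' in '", path, "'")
  })
  list(trials = trials, labels = labels)
}
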