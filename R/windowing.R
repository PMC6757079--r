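#' Default time-scale grid
#'
#' Window lengths (seconds) at which rhythm signals are segmented:
#' 0.25, 0.5, 0.75, 1, 2, 3, 4, 5, 6 s.
#' @return numeric vector of seconds.
#' @export
default_time_scales <- function() c(0.25, 0.5, 0.75, 1, 2, 3, 4, 5, 6)

#' Segment a rhythm signal into a sequence of rectangular windows
#'
#' Cuts the signal into contiguous, non-overlapping windows of `tS` seconds
#' (`w = round(tS * sR)` samples) and flattens each window channel-major:
#' window `i` is `[CH1 samples, CH2 samples, ..., CHn samples]` of the
#' half-open sample range `[(i-1)w, iw)`.  A trailing remainder shorter than
#' one window is dropped.  The result is the `T x E` matrix the sequence
#' classifier consumes, with `E = n_channels * w` and
#' `T = floor(n_samples / w)`.
#'
#' @param x a [rhythm_signal] or [raw_eeg] object.
#' @param tS time scale in seconds (> 0).
#' @param pool optional integer mean-pooling factor applied within each
#'   channel's window samples to reduce `E`; 1 (default) keeps raw samples.
#' @return object of class `windowed_sequence`: `vectors` (`T x E` matrix),
#'   `tS`, `sR`, `n_channels`, `trial_id`, `band`.
#' @export
segment <- function(x, tS, pool = 1L) {
  stopifnot(inherits(x, "rhythm_signal") || inherits(x, "raw_eeg"))
  if (!is.numeric(tS) || length(tS) != 1L || tS <= 0)
    stop("`tS` must be a single positive number of seconds")
  sR <- x$fs
  w <- max(1L, as.integer(round(tS * sR)))
  n <- nrow(x$data); N <- ncol(x$data)
  if (N < w)
    stop("trial of ", N, " samples (", format(N / sR), " s) is shorter than ",
         "one window; time scale ", tS, " s needs at least ", w, " samples")
  T_ <- N %/% w
  pool <- as.integer(pool)
  if (pool < 1L || w %% pool != 0L)
    stop("`pool` must be a positive divisor of the window length (", w, ")")
  wp <- w %/% pool
  E <- n * wp
  vecs <- matrix(0, nrow = T_, ncol = E)
  for (i in seq_len(T_)) {
    block <- x$data[, ((i - 1L) * w + 1L):(i * w), drop = FALSE]
    if (pool > 1L) {
      block <- t(apply(block, 1L, function(ch)
        colMeans(matrix(ch, nrow = pool))))
    }
    vecs[i, ] <- as.numeric(t(block))  # channel-major: CH1 samples, CH2, ...
  }
  band <- if (inherits(x, "rhythm_signal")) x$band$name else "broadband"
  trial_id <- if (inherits(x, "rhythm_signal")) x$source_trial else x$trial_id
  structure(list(vectors = vecs, tS = tS, sR = sR, n_channels = n,
                 trial_id = trial_id, band = band),
            class = "windowed_sequence")
}

#' @export
print.windowed_sequence <- function(x, ...) {
  cat(sprintf("<windowed_sequence '%s'> band %s, tS = %g s: T = %d windows x E = %d features\n",
              x$trial_id, x$band, x$tS, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Windowing arithmetic for a set of time scales
#'
#' For each candidate scale, the number of windows `T = floor(duration / tS)`
#' and the flattened window length `E = n_channels * round(tS * sR)` that
#' [segment()] would produce; scales longer than the trial are flagged
#' infeasible rather than dropped.
#'
#' @param duration trial duration in seconds.
#' @param n_channels number of channels.
#' @param sR sampling rate in Hz.
#' @param scales numeric vector of time scales (default
#'   [default_time_scales()]).
#' @return data.frame with columns `tS`, `window_samples`, `T`, `E`,
#'   `feasible`.
#' @export
window_grid <- function(duration, n_channels, sR,
                        scales = default_time_scales()) {
  w <- pmax(1L, as.integer(round(scales * sR)))
  N <- as.integer(round(duration * sR))
  T_ <- N %/% w
  data.frame(tS = scales, window_samples = w, T = T_,
             E = as.integer(n_channels) * w,
             feasible = T_ >= 1L)
}
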