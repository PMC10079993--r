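#' Frequency band definitions
#'
#' Conventional EEG analysis bands: delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-45 and wide 1-45 Hz. All edges are configurable by
#' constructing bands with [band_definition()].
#'
#' @return Named list of `band_definition` objects.
#' @export
eeg_bands <- function() {
  list(wide  = band_definition("wide", 1, 45),
       delta = band_definition("delta", 1, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

#' Define an analysis frequency band
#'
#' @param name Band name.
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  abort_if(!(low_hz > 0 && low_hz < high_hz),
           "band edges must satisfy 0 < low_hz < high_hz")
  structure(list(name = name, low = low_hz, high = high_hz),
            class = "band_definition")
}

#' Resample a continuous EEG record
#'
#' Anti-aliased downsampling via polyphase resampling; upsampling is refused.
#'
#' @param record Channels x samples numeric matrix (or a single vector).
#' @param from_rate Original sampling rate in Hz.
#' @param to_rate Target sampling rate in Hz (must be <= `from_rate`).
#' @return Resampled record with `round(n * to_rate / from_rate)` samples.
#' @export
resample_eeg <- function(record, from_rate, to_rate) {
  abort_if(to_rate > from_rate, "upsampling is not supported")
  if (to_rate == from_rate) return(record)
  vec <- is.null(dim(record))
  if (vec) record <- matrix(record, nrow = 1)
  ratio <- to_rate / from_rate
  factor <- from_rate / to_rate
  down <- if (abs(factor - round(factor)) < 1e-9) {
    # integer decimation: FIR anti-aliasing preserves passband amplitude
    function(x) signal::decimate(x, round(factor), ftype = "fir")
  } else {
    frac <- MASS_fraction(ratio)
    function(x) signal::resample(x, frac$p, frac$q)
  }
  out <- t(apply(record, 1, down))
  n_out <- round(ncol(record) * ratio)
  out <- out[, seq_len(min(n_out, ncol(out))), drop = FALSE]
  rownames(out) <- rownames(record)
  if (vec) out[1, ] else out
}

# Small rational approximation p/q of a rate ratio.
MASS_fraction <- function(ratio, max_q = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_q)) {
    p <- round(ratio * q)
    if (p < 1) next
    e <- abs(p / q - ratio)
    if (e < err - 1e-12) { best <- c(p, q); err <- e }
    if (err == 0) break
  }
  list(p = best[1], q = best[2])
}

# Hamming-window FIR band-pass coefficients; transition width 25% of the low
# edge. Order capped so short records stay filterable.
design_fir_bandpass <- function(band, sampling_rate, n_samples = Inf) {
  nyq <- sampling_rate / 2
  abort_if(band$high >= nyq, sprintf(
    "band edge %g Hz is not below the Nyquist frequency %g Hz", band$high, nyq))
  trans <- 0.25 * band$low
  order <- ceiling(3.3 * sampling_rate / trans)
  order <- min(order, max(16, 2 * floor((n_samples - 1) / 2) - 2))
  if (order %% 2 == 1) order <- order + 1
  signal::fir1(order, c(band$low, band$high) / nyq, type = "pass")
}

# Zero-phase (forward-backward) FIR application via FFT: multiply by |B(f)|^2,
# with reflection padding to suppress edge transients. Exactly zero phase, so
# instantaneous-phase estimates downstream are unbiased.
fir_filtfilt <- function(x, b) {
  n <- length(x)
  pad <- min(length(b), n - 1L)
  xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[n] - rev(x[n - seq_len(pad)]))
  m <- length(xp)
  nfft <- stats::nextn(m + length(b), 2)
  B <- stats::fft(c(b, numeric(nfft - length(b))))
  X <- stats::fft(c(xp, numeric(nfft - m)))
  y <- Re(stats::fft(X * B * Conj(B), inverse = TRUE)) / nfft
  # forward+backward application cancels the group delay exactly (|B|^2 real)
  y[pad + seq_len(n)]
}

#' Band-pass filter a signal or continuous record (zero-phase)
#'
#' Hamming-window FIR applied forward and backward, so the passband incurs no
#' phase distortion -- a prerequisite for unbiased phase-lag-index estimates.
#' Filtering is intended for the continuous record, before epoching, so that
#' filter edge transients fall outside the analysis epochs.
#'
#' @param x Numeric vector, or channels x samples matrix.
#' @param band A [band_definition()] (or a band name from [eeg_bands()]).
#' @param sampling_rate Sampling rate of `x` in Hz.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, band, sampling_rate) {
  if (is.character(band)) {
    bands <- eeg_bands()
    abort_if(is.null(bands[[band]]), sprintf("unknown band '%s'", band))
    band <- bands[[band]]
  }
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  b <- design_fir_bandpass(band, sampling_rate, n)
  if (is.null(dim(x))) return(fir_filtfilt(x, b))
  out <- x
  for (ch in seq_len(nrow(x))) out[ch, ] <- fir_filtfilt(x[ch, ], b)
  out
}

#' Cut stimulus-locked epochs from a continuous record
#'
#' One epoch per target event, over a half-open window so the epoch length in
#' samples is exactly `(window[2] - window[1]) * sampling_rate`. The
#' pre-stimulus mean is subtracted per channel (baseline correction). Events
#' whose window exceeds the record bounds are dropped with a warning.
#'
#' @param record Channels x samples numeric matrix.
#' @param schedule An oddball schedule; only events labelled "target" are
#'   epoched.
#' @param window Length-2 numeric, seconds relative to stimulus onset.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Channel names (defaults to the record's rownames).
#' @param quiet Suppress the dropped-epoch warning.
#' @return An `epoch_set`: list with `data` (trials x channels x samples),
#'   `channel_names`, `sampling_rate`, `trial_labels`, `window`, `n_dropped`.
#' @export
epoch_record <- function(record, schedule, window = c(-0.2, 0.8),
                         sampling_rate = 250,
                         channel_names = rownames(record), quiet = FALSE) {
  abort_if(window[1] >= window[2], "`window` must be increasing")
  onsets <- schedule$onsets[schedule$labels == "target"]
  n_samp <- as.integer(round((window[2] - window[1]) * sampling_rate))
  pre <- as.integer(round(-window[1] * sampling_rate))
  n_ch <- nrow(record)
  keep <- onsets - pre >= 1L & onsets - pre + n_samp - 1L <= ncol(record)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet)
    warning(sprintf("%d epoch(s) dropped: window exceeds record bounds", n_dropped))
  onsets <- onsets[keep]
  data <- array(0, dim = c(length(onsets), n_ch, n_samp))
  for (i in seq_along(onsets)) {
    idx <- onsets[i] - pre + seq_len(n_samp) - 1L
    ep <- record[, idx, drop = FALSE]
    if (pre > 0) ep <- ep - rowMeans(ep[, seq_len(pre), drop = FALSE])
    data[i, , ] <- ep
  }
  structure(list(data = data,
                 channel_names = channel_names %||% paste0("ch", seq_len(n_ch)),
                 sampling_rate = sampling_rate,
                 trial_labels = rep("target", length(onsets)),
                 window = window, n_dropped = n_dropped),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz [%g, %g) s\n",
              d[1], d[2], d[3], x$sampling_rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Reject high-amplitude trials
#'
#' Removes every trial whose peak-to-peak amplitude on any channel exceeds the
#' limit; a simple stand-in for component-based artifact removal, adequate for
#' data without ocular/muscle components.
#'
#' @param epochs An `epoch_set`.
#' @param peak_to_peak_limit Rejection threshold in microvolt (> 0).
#' @return The `epoch_set` with offending trials removed; the indices of the
#'   removed trials are kept in `$rejected`.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_limit) {
  abort_if(!(peak_to_peak_limit > 0), "`peak_to_peak_limit` must be > 0")
  d <- epochs$data
  ptp <- apply(d, 1, function(tr) max(apply(tr, 1, function(ch) diff(range(ch)))))
  bad <- which(ptp > peak_to_peak_limit)
  if (length(bad) == dim(d)[1])
    stop(sprintf("all %d trials exceed the %g uV peak-to-peak limit",
                 dim(d)[1], peak_to_peak_limit), call. = FALSE)
  if (length(bad)) {
    epochs$data <- d[-bad, , , drop = FALSE]
    epochs$trial_labels <- epochs$trial_labels[-bad]
  }
  epochs$rejected <- bad
  epochs
}

#' Band-filter a subject's continuous record and re-epoch it
#'
#' Applies the zero-phase band-pass to the stored continuous record, then cuts
#' the same target-locked window, giving a narrow-band `epoch_set` ready for
#' phase extraction.
#'
#' @param epochs An `epoch_set` carrying `$record` and `$schedule` (as
#'   produced by [synthesize_subject()]).
#' @param band Band name or [band_definition()].
#' @return A band-filtered `epoch_set`.
#' @export
band_epochs <- function(epochs, band) {
  abort_if(is.null(epochs$record) || is.null(epochs$schedule),
           "epoch_set carries no continuous record; cannot band-filter")
  rec <- bandpass(epochs$record, band, epochs$sampling_rate)
  out <- epoch_record(rec, epochs$schedule, window = epochs$window,
                      sampling_rate = epochs$sampling_rate,
                      channel_names = epochs$channel_names, quiet = TRUE)
  out$subject_id <- epochs$subject_id
  out$group_label <- epochs$group_label
  out$band <- if (is.character(band)) band else band$name
  out
}
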