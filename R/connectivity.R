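#' Analytic signal of a real vector
#'
#' FFT construction: positive frequencies doubled, negative zeroed (DC and
#' Nyquist kept), giving instantaneous amplitude and phase for narrow-band
#' input.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-filtered epochs
#'
#' Per-trial, per-channel phase of the analytic (Hilbert) signal, in
#' (-pi, pi]. Input should be narrow-band for the phase to be meaningful.
#'
#' @param epochs A band-filtered `epoch_set`.
#' @return A `phase_series`: list with `phase` (trials x channels x samples),
#'   `channel_names` and `band`.
#' @export
instantaneous_phase <- function(epochs) {
  d <- epochs$data
  dims <- dim(d)
  ph <- array(0, dims)
  for (tr in seq_len(dims[1])) {
    for (ch in seq_len(dims[2])) {
      x <- d[tr, ch, ]
      abort_if(all(x == 0), sprintf(
        "channel %d of trial %d is identically zero: phase undefined", ch, tr))
      ph[tr, ch, ] <- Arg(analytic_signal(x))
    }
  }
  structure(list(phase = ph, channel_names = epochs$channel_names,
                 band = epochs$band %||% NA_character_),
            class = "phase_series")
}

#' Band-filter a subject's record and extract target-locked phase epochs
#'
#' The zero-phase band-pass and the Hilbert transform are both applied to the
#' continuous record, and the resulting instantaneous-phase series is then
#' cut around the target events. Computing the analytic signal before
#' epoching avoids the edge distortion a finite epoch imposes on the Hilbert
#' transform, which would otherwise corrupt a few percent of the phase
#' samples at the epoch boundaries.
#'
#' @param epochs An `epoch_set` carrying `$record` and `$schedule` (as
#'   produced by [synthesize_subject()]).
#' @param band Band name or [band_definition()].
#' @return A `phase_series` with dimensions trials x channels x samples.
#' @export
band_phase_series <- function(epochs, band) {
  abort_if(is.null(epochs$record) || is.null(epochs$schedule),
           "epoch_set carries no continuous record; cannot band-filter")
  fs <- epochs$sampling_rate
  rec <- bandpass(epochs$record, band, fs)
  phase_rec <- rec
  for (ch in seq_len(nrow(rec))) {
    abort_if(all(rec[ch, ] == 0), sprintf(
      "channel %d is identically zero after filtering: phase undefined", ch))
    phase_rec[ch, ] <- Arg(analytic_signal(rec[ch, ]))
  }
  window <- epochs$window
  onsets <- epochs$schedule$onsets[epochs$schedule$labels == "target"]
  n_samp <- as.integer(round((window[2] - window[1]) * fs))
  pre <- as.integer(round(-window[1] * fs))
  keep <- onsets - pre >= 1L & onsets - pre + n_samp - 1L <= ncol(rec)
  onsets <- onsets[keep]
  ph <- array(0, c(length(onsets), nrow(rec), n_samp))
  for (i in seq_along(onsets))
    ph[i, , ] <- phase_rec[, onsets[i] - pre + seq_len(n_samp) - 1L]
  structure(list(phase = ph, channel_names = epochs$channel_names,
                 band = if (is.character(band)) band else band$name),
            class = "phase_series")
}

#' Phase lag index of two phase series
#'
#' `| mean(sign(delta_phi)) |` over samples, where `delta_phi` is the phase
#' difference wrapped into (-pi, pi]: 1 for a perfectly consistent nonzero
#' lag, 0 for no consistent lag (including identical phases, since sign(0)
#' contributes 0). Insensitive to zero-lag (volume-conduction) coupling by
#' construction.
#'
#' @param phase_x,phase_y Equal-length numeric phase vectors (radians).
#' @return PLI value in [0, 1].
#' @export
pli_pair <- function(phase_x, phase_y) {
  abort_if(length(phase_x) != length(phase_y), "phase series lengths differ")
  abort_if(length(phase_x) < 2L, "phase series must have length >= 2")
  d <- wrap_phase(phase_x - phase_y)
  d[d == pi] <- 0  # a pi lag has no leading side; treat like a tie
  abs(mean(sign(d)))
}

#' Per-trial PLI matrices
#'
#' Vectorized over trials and pairs; `sign(sin(d))` equals the sign of the
#' phase difference wrapped into (-pi, pi] (with a lag of exactly pi counting
#' as a tie), so this is the same statistic as [pli_pair()].
#'
#' @param phases A `phase_series`.
#' @return Array trials x channels x channels of symmetric, zero-diagonal
#'   PLI matrices.
#' @export
pli_trial_matrices <- function(phases) {
  ph <- phases$phase
  dims <- dim(ph)
  abort_if(dims[1] < 1L, "need at least one trial")
  abort_if(dims[3] < 2L, "single-sample trials have no phase statistics")
  n_tr <- dims[1]; n_ch <- dims[2]; n_s <- dims[3]
  out <- array(0, c(n_tr, n_ch, n_ch))
  for (i in seq_len(n_ch - 1)) {
    rest <- (i + 1):n_ch
    base <- array(ph[, i, ], c(n_tr, n_s, length(rest)))
    d <- ph[, rest, , drop = FALSE] - aperm(base, c(1, 3, 2))
    out[, i, rest] <- abs(rowMeans(sign(sin(d)), dims = 2))
  }
  for (tr in seq_len(n_tr)) {
    m <- out[tr, , ]
    out[tr, , ] <- m + t(m)
  }
  out
}

#' Subject-level PLI connectivity matrix
#'
#' Computes one symmetric PLI matrix per trial (expectation over time samples
#' within the trial) and averages them arithmetically across trials.
#'
#' @param phases A `phase_series`.
#' @param level Provenance tag stored with the matrix.
#' @return A `connectivity_matrix`: list with `values` (channels x channels in
#'   [0, 1], symmetric, zero diagonal), `band`, `level`, `channel_names`.
#' @export
pli_matrix <- function(phases, level = "subject") {
  trials <- pli_trial_matrices(phases)
  vals <- apply(trials, c(2, 3), mean)
  dimnames(vals) <- list(phases$channel_names, phases$channel_names)
  connectivity_matrix(vals, band = phases$band, level = level)
}

#' Construct a connectivity matrix object
#'
#' @param values Symmetric numeric matrix with zero diagonal, entries in [0,1].
#' @param band Band tag.
#' @param level One of "trial", "subject", "group".
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, band = NA_character_, level = "subject") {
  abort_if(!isTRUE(all.equal(values, t(values), tolerance = 1e-8)),
           "connectivity matrix must be symmetric")
  abort_if(any(diag(values) != 0), "connectivity matrix diagonal must be zero")
  structure(list(values = values, band = band, level = level,
                 channel_names = rownames(values) %||%
                   paste0("ch", seq_len(nrow(values)))),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %dx%d, band=%s, level=%s, density=%.3f\n",
              nrow(x$values), ncol(x$values), x$band, x$level,
              mean(x$values[upper.tri(x$values)] > 0)))
  invisible(x)
}

#' Group-level mean connectivity matrix
#'
#' @param matrices List of subject-level `connectivity_matrix` objects.
#' @return A `connectivity_matrix` with `level = "group"`.
#' @export
group_mean_matrix <- function(matrices) {
  abort_if(!length(matrices), "empty matrix list")
  vals <- Reduce(`+`, lapply(matrices, function(m) m$values)) / length(matrices)
  connectivity_matrix(vals, band = matrices[[1]]$band, level = "group")
}

# Deterministic ranking of off-diagonal pairs: by value descending, ties by
# ascending (row, column) index.
ranked_pairs <- function(values, score) {
  n <- nrow(values)
  ut <- which(upper.tri(values), arr.ind = TRUE)
  ord <- order(-score[upper.tri(values)], ut[, 1], ut[, 2])
  ut[ord, , drop = FALSE]
}

#' Proportional (consistency) threshold
#'
#' Keeps the `floor(density * n_pairs)` strongest off-diagonal connections and
#' zeroes the rest. For a 22-node network at the default density 0.30 exactly
#' 69 of the 231 pairs survive. Ties are broken deterministically by ascending
#' (row, column) index.
#'
#' @param C A `connectivity_matrix`.
#' @param density Fraction of connections to retain, in (0, 1].
#' @return A thresholded `connectivity_matrix`.
#' @export
proportional_threshold <- function(C, density = 0.30) {
  abort_if(!(density > 0 && density <= 1), "`density` must be in (0, 1]")
  vals <- C$values
  n_keep <- floor(density * sum(upper.tri(vals)))
  pairs <- ranked_pairs(vals, vals)
  out <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  keep <- pairs[seq_len(n_keep), , drop = FALSE]
  out[keep] <- vals[keep]
  out <- out + t(out)
  res <- connectivity_matrix(out, band = C$band, level = C$level)
  res$density <- density
  res
}

#' Signed group-difference matrix with proportional retention
#'
#' `D = Ca - Cb`, keeping only the `retain` fraction of pairs with the largest
#' absolute difference; retained values keep their sign.
#'
#' @param Ca,Cb Group-level `connectivity_matrix` objects on the same montage
#'   and band.
#' @param retain Fraction of pairs to retain, in (0, 1].
#' @return A list with signed `values`, `band`, `channel_names`.
#' @export
difference_matrix <- function(Ca, Cb, retain = 0.30) {
  abort_if(!identical(Ca$channel_names, Cb$channel_names),
           "montage mismatch between the two matrices")
  abort_if(!identical(Ca$band, Cb$band), "band mismatch between the two matrices")
  abort_if(!(retain > 0 && retain <= 1), "`retain` must be in (0, 1]")
  D <- Ca$values - Cb$values
  n_keep <- floor(retain * sum(upper.tri(D)))
  pairs <- ranked_pairs(D, abs(D))
  out <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  keep <- pairs[seq_len(n_keep), , drop = FALSE]
  out[keep] <- D[keep]
  out <- out + t(out)
  list(values = out, band = Ca$band, channel_names = Ca$channel_names,
       retain = retain)
}

#' Write a connectivity matrix as TSV with channel-name headers
#'
#' @param C A `connectivity_matrix` (or difference-matrix list).
#' @param path Output file path; a JSON sidecar records band and level.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(C, path) {
  vals <- C$values
  dimnames(vals) <- list(C$channel_names, C$channel_names)
  utils::write.table(vals, path, sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(list(band = C$band, level = C$level %||% "difference"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
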