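#' Default 22-channel scalp montage
#'
#' The 22 electrodes of the international 10-20 placement retained for network
#' analysis (Cz serves as the recording reference and is not an analysis
#' channel).
#'
#' @return Character vector of 22 channel names, frontal to occipital.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5", "FC6",
    "C3", "C4", "CP1", "CP2", "CP5", "CP6", "Pz", "P3", "P4", "Oz",
    "O1", "O2")
}

#' Build an auditory oddball stimulus schedule
#'
#' Arranges rare target tones and frequent standard tones in pseudo-random
#' order with a uniformly distributed inter-stimulus interval, mirroring a
#' 30-target / 200-standard oddball session.
#'
#' @param n_target Number of target stimuli (>= 0).
#' @param n_standard Number of standard stimuli (>= 0).
#' @param isi_bounds_ms Length-2 numeric, inclusive bounds of the
#'   inter-stimulus interval in milliseconds.
#' @param sampling_rate Sampling rate in Hz used to express onsets in samples.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return An object of class `oddball_schedule`: a list with integer
#'   `onsets` (sample indices, strictly increasing), character `labels`
#'   ("target"/"standard"), `isi_bounds_ms` and `sampling_rate`.
#' @export
make_oddball_schedule <- function(n_target = 30L, n_standard = 200L,
                                  isi_bounds_ms = c(1000, 1500),
                                  sampling_rate = 250, seed = 1L) {
  abort_if(n_target < 0 || n_standard < 0, "stimulus counts must be >= 0")
  abort_if(length(isi_bounds_ms) != 2L || isi_bounds_ms[1] > isi_bounds_ms[2] ||
             isi_bounds_ms[1] <= 0, "invalid `isi_bounds_ms`")
  n <- as.integer(n_target) + as.integer(n_standard)
  labels <- rep(c("target", "standard"), c(n_target, n_standard))
  onsets <- integer(0)
  if (n > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    labels <- sample(labels)
    isi_s <- stats::runif(n, isi_bounds_ms[1], isi_bounds_ms[2]) / 1000
    onsets <- as.integer(round(cumsum(isi_s) * sampling_rate))
  }
  structure(list(onsets = onsets, labels = labels,
                 isi_bounds_ms = as.numeric(isi_bounds_ms),
                 sampling_rate = sampling_rate),
            class = "oddball_schedule")
}

# Save/restore the global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.oddball_schedule <- function(x, ...) {
  cat(sprintf("oddball schedule: %d events (%d target, %d standard), ISI %g-%g ms\n",
              length(x$onsets), sum(x$labels == "target"),
              sum(x$labels == "standard"),
              x$isi_bounds_ms[1], x$isi_bounds_ms[2]))
  invisible(x)
}
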