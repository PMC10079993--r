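#' Define a phase-coupling rule between two channels
#'
#' A rule makes the two channels of `pair` share one band-limited oscillator:
#' the second channel receives a copy whose instantaneous phase is offset by
#' `mean_lag` plus von Mises jitter. The jitter concentration controls how
#' consistently the lag is expressed, and therefore the phase-lag index the
#' pair achieves: kappa = 0 is uncoupled (uniform jitter), kappa = Inf is a
#' deterministic lag.
#'
#' @param pair Character length-2, channel names (must be montage members).
#' @param band Band name the shared oscillator occupies (see [eeg_bands()]).
#' @param mean_lag Mean phase lag in radians, in (-pi, pi].
#' @param kappa Von Mises jitter concentration, >= 0 (Inf allowed).
#' @return A `coupling_rule` list.
#' @export
coupling_rule <- function(pair, band = "theta", mean_lag = pi / 2, kappa = 4) {
  abort_if(length(pair) != 2L || !is.character(pair) || pair[1] == pair[2],
           "`pair` must name two distinct channels")
  abort_if(!(mean_lag > -pi && mean_lag <= pi), "`mean_lag` must lie in (-pi, pi]")
  abort_if(is.na(kappa) || kappa < 0, "`kappa` must be >= 0")
  structure(list(pair = pair, band = band, mean_lag = mean_lag, kappa = kappa),
            class = "coupling_rule")
}

#' Define a synthetic group's generative profile
#'
#' @param label Group name.
#' @param coupling_rules List of [coupling_rule()] objects.
#' @param erp_amplitude Peak amplitude (microvolt) of the parietal-maximal
#'   P300-like deflection added after each target tone.
#' @param noise_sd Standard deviation (microvolt) of the 1/f background noise.
#' @param band_powers Named numeric, relative oscillator amplitude per band.
#' @return A `group_profile` list.
#' @export
group_profile <- function(label, coupling_rules = list(), erp_amplitude = 6,
                          noise_sd = 8,
                          band_powers = c(delta = 1.2, theta = 1.5,
                                          alpha = 1.5, beta = 0.8,
                                          gamma = 0.5)) {
  abort_if(!is.character(label) || length(label) != 1L, "`label` must be one string")
  abort_if(noise_sd < 0 || erp_amplitude < 0, "amplitudes must be >= 0")
  abort_if(is.null(names(band_powers)) || any(band_powers < 0),
           "`band_powers` must be a named non-negative vector")
  structure(list(label = label, coupling_rules = coupling_rules,
                 erp_amplitude = erp_amplitude, noise_sd = noise_sd,
                 band_powers = band_powers),
            class = "group_profile")
}

#' Define a synthetic three-group oddball cohort
#'
#' @param groups List of [group_profile()] objects.
#' @param n_subjects_per_group Subjects per group (>= 1).
#' @param montage Ordered channel names; must contain exactly 22 unique names.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Cohort master seed; per-subject seeds are derived from it.
#' @param n_target,n_standard Oddball stimulus counts per subject.
#' @param isi_bounds_ms Inter-stimulus-interval bounds in ms.
#' @param window Epoch window in seconds relative to target onset,
#'   half-open `[window[1], window[2])`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, n_subjects_per_group = 15L,
                        montage = default_montage(), sampling_rate = 250,
                        seed = 1L, n_target = 30L, n_standard = 200L,
                        isi_bounds_ms = c(1000, 1500),
                        window = c(-0.2, 0.8)) {
  abort_if(length(montage) != 22L || anyDuplicated(montage) > 0,
           "`montage` must contain exactly 22 unique channel names")
  abort_if(n_subjects_per_group < 1, "`n_subjects_per_group` must be >= 1")
  abort_if(!length(groups) || !all(vapply(groups, inherits, TRUE, "group_profile")),
           "`groups` must be a list of group_profile objects")
  for (g in groups) {
    for (r in g$coupling_rules) {
      abort_if(!all(r$pair %in% montage),
               sprintf("coupling rule in group '%s' names unknown channel(s): %s",
                       g$label, paste(setdiff(r$pair, montage), collapse = ", ")))
    }
  }
  structure(list(groups = groups,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 montage = montage, sampling_rate = sampling_rate,
                 seed = as.integer(seed), n_target = as.integer(n_target),
                 n_standard = as.integer(n_standard),
                 isi_bounds_ms = isi_bounds_ms, window = window),
            class = "cohort_spec")
}

#' Default three-group cohort: chronic-pain-like, depression-like, control
#'
#' Encodes the study conditions the package simulates: a chronic-primary-pain
#' -like group with strongly enhanced Theta frontoparietal coupling
#' (prefrontal FP1/FP2 to parieto-occipital P3/P4/O1/O2), a control group with
#' moderate frontoparietal coupling plus mildly enhanced CP5-O2 and FC2-F4
#' links, and a depression-like group whose Theta coupling is globally
#' suppressed. All groups share an unchanged Alpha C3-C4 link so that not
#' every connection is discriminative.
#'
#' @param n_subjects_per_group Subjects per group.
#' @param seed Cohort master seed.
#' @param cpp_kappa,hc_kappa,dd_kappa Jitter concentrations of the Theta
#'   frontoparietal pairs in the pain-like, control and depression-like
#'   groups.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_subjects_per_group = 15L, seed = 1L,
                                cpp_kappa = 10, hc_kappa = 2, dd_kappa = 0.3) {
  fp_pairs <- list(c("FP1", "P3"), c("FP2", "O2"), c("FP1", "O1"), c("FP2", "P4"))
  hc_pairs <- list(c("CP5", "O2"), c("FC2", "F4"))
  theta_rules <- function(k_fp, k_hc) {
    c(lapply(fp_pairs, coupling_rule, band = "theta", mean_lag = pi / 2, kappa = k_fp),
      lapply(hc_pairs, coupling_rule, band = "theta", mean_lag = pi / 2, kappa = k_hc))
  }
  shared <- list(coupling_rule(c("C3", "C4"), band = "alpha",
                               mean_lag = pi / 3, kappa = 3))
  groups <- list(
    group_profile("cpp", c(theta_rules(cpp_kappa, 1), shared)),
    group_profile("dd",  c(theta_rules(dd_kappa, dd_kappa), shared)),
    group_profile("hc",  c(theta_rules(hc_kappa, 6), shared))
  )
  cohort_spec(groups, n_subjects_per_group = n_subjects_per_group, seed = seed)
}

#' Strongly separable three-group benchmark cohort
#'
#' A cohort whose groups carry deterministic (infinite-concentration) Theta
#' coupling on disjoint channel pairs -- frontoparietal for the pain-like
#' group, central/bilateral-frontal for the depression-like group,
#' centro-parietal/occipital for controls -- over a low-noise background.
#' Designed as a learnability benchmark: each group's per-trial PLI matrices
#' have a clear positive signature, so a working classifier must separate
#' them well above chance. It is not the study-conditions generator (that is
#' [default_cohort_spec()]).
#'
#' @param n_subjects_per_group Subjects per group (default 8).
#' @param seed Cohort master seed.
#' @return A [cohort_spec()].
#' @export
separable_cohort_spec <- function(n_subjects_per_group = 8L, seed = 1L) {
  mk <- function(pairs) lapply(pairs, coupling_rule, band = "theta",
                               mean_lag = pi / 2, kappa = Inf)
  groups <- list(
    group_profile("cpp", mk(list(c("FP1", "P3"), c("FP2", "P4"),
                                 c("F3", "O1"), c("F4", "O2"))),
                  erp_amplitude = 2, noise_sd = 2),
    group_profile("dd", mk(list(c("C3", "C4"), c("CP1", "CP2"),
                                c("F7", "F8"))),
                  erp_amplitude = 2, noise_sd = 2),
    group_profile("hc", mk(list(c("CP5", "O2"), c("FC2", "F4"),
                                c("Pz", "Oz"))),
                  erp_amplitude = 2, noise_sd = 2))
  cohort_spec(groups, n_subjects_per_group = n_subjects_per_group, seed = seed)
}

# Pink (1/f) noise via direct spectral draw; per-channel, sd-calibrated.
pink_noise <- function(n_channels, n_samples, sd_uv) {
  if (sd_uv == 0) return(matrix(0, n_channels, n_samples))
  n <- n_samples
  freqs <- seq(0, n - 1) / n           # cycles/sample
  f <- pmin(freqs, 1 - freqs)          # two-sided
  scale <- 1 / sqrt(pmax(f, 2 / n))    # flatten below ~2 bins to avoid DC blowup
  scale[1] <- 0
  out <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * scale
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    out[ch, ] <- x / stats::sd(x) * sd_uv
  }
  out
}

# Raised-cosine one-sided band mask over FFT bins.
band_mask <- function(n_samples, low_hz, high_hz, fs) {
  n <- n_samples
  mask <- numeric(n)
  half <- seq_len(floor(n / 2) + 1L)
  fh <- (half - 1) / n * fs
  trans <- 0.15 * (high_hz - low_hz)
  mask[half] <- ifelse(fh < low_hz - trans | fh > high_hz + trans, 0,
                ifelse(fh < low_hz + trans,
                       0.5 * (1 + sin(pi * (fh - low_hz) / (2 * trans))),
                ifelse(fh > high_hz - trans,
                       0.5 * (1 + sin(pi * (high_hz - fh) / (2 * trans))), 1)))
  mask
}

# Band-limited analytic signal (complex) drawn directly in the frequency
# domain (one-sided spectrum), with unit rms of its real part.
narrowband_analytic <- function(n_samples, low_hz, high_hz, fs,
                                mask = band_mask(n_samples, low_hz, high_hz, fs)) {
  n <- n_samples
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * mask
  a <- stats::fft(z, inverse = TRUE) / n      # one-sided spectrum -> analytic
  a / stats::sd(Re(a))
}

# Independent multi-band "background rhythm" of one channel: all requested
# bands drawn in a single spectral pass. Component variances add, so this
# equals the sum of independent per-band oscillators with rms `amps`.
background_rhythm <- function(n_samples, masks, amps) {
  n <- n_samples
  combined <- numeric(n)
  for (b in seq_along(masks)) {
    if (amps[b] == 0) next
    m <- masks[[b]]
    # Re(ifft(Z * m))/n has variance sum(m^2)/n^2 for unit-normal Z parts
    combined <- combined + m * (amps[b] * n / sqrt(sum(m^2)))
  }
  if (all(combined == 0)) return(numeric(n))
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * combined
  Re(stats::fft(z, inverse = TRUE)) / n
}

# Piecewise-constant phase-offset process: one von Mises draw per block.
phase_offset_process <- function(n_samples, block_len, mean_lag, kappa) {
  n_blocks <- ceiling(n_samples / block_len)
  draws <- rvonmises(n_blocks, mu = mean_lag, kappa = kappa)
  rep(draws, each = block_len)[seq_len(n_samples)]
}

# P300 template: Gaussian-windowed half-sine, peak ~300 ms post stimulus.
p300_template <- function(fs) {
  t <- seq(0, 0.6, by = 1 / fs)
  sin(pi * t / 0.6) * exp(-(t - 0.3)^2 / (2 * 0.09^2))
}

# Parietal-maximal topography weights for the P300 deflection.
p300_topography <- function(montage) {
  w <- rep(0.2, length(montage))
  names(w) <- montage
  w[grepl("^P|^O", montage)] <- 1.0
  w[grepl("^CP", montage)] <- 0.8
  w[montage %in% c("C3", "C4")] <- 0.5
  w[grepl("^FC", montage)] <- 0.3
  w
}

#' Synthesize one subject's oddball EEG and epoch it around targets
#'
#' Builds a continuous multi-channel record as 1/f background noise plus
#' band-limited oscillators (channels named in a coupling rule share the
#' rule's oscillator, phase-offset by the mean lag plus von Mises jitter)
#' plus a parietal-maximal P300-like deflection after each target tone, then
#' cuts baseline-corrected epochs around the target stimuli.
#'
#' @param profile A [group_profile()].
#' @param schedule An [make_oddball_schedule()] schedule.
#' @param spec The enclosing [cohort_spec()] (supplies montage, rates, window).
#' @param subject_seed Integer seed for this subject's record.
#' @param subject_id Subject identifier stored with the epochs.
#' @return An `epoch_set` (see [epoch_record()]) with the continuous record in
#'   `$record` and the schedule in `$schedule`.
#' @export
synthesize_subject <- function(profile, schedule, spec, subject_seed,
                               subject_id = profile$label) {
  montage <- spec$montage
  fs <- spec$sampling_rate
  for (r in profile$coupling_rules) {
    abort_if(!all(r$pair %in% montage),
             sprintf("coupling rule names unknown channel(s): %s",
                     paste(setdiff(r$pair, montage), collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(subject_seed))

  n_samples <- max(schedule$onsets, 0L) + as.integer(ceiling((spec$window[2] + 1) * fs))
  # pad to a 5-smooth length so the spectral synthesis FFTs stay O(n log n)
  n_samples <- stats::nextn(n_samples, c(2, 3, 5))
  rec <- pink_noise(length(montage), n_samples, profile$noise_sd)
  rownames(rec) <- montage

  bands <- eeg_bands()
  osc_base_rms <- 3  # microvolt rms at band_power 1
  block_len <- max(1L, as.integer(round(fs / 4)))  # 0.25 s jitter blocks

  band_names <- names(profile$band_powers)
  masks <- stats::setNames(lapply(band_names, function(bn) {
    if (is.null(bands[[bn]])) return(NULL)
    band_mask(n_samples, bands[[bn]]$low, bands[[bn]]$high, fs)
  }), band_names)

  coupled <- matrix(FALSE, length(montage), length(band_names),
                    dimnames = list(montage, band_names))
  for (r in profile$coupling_rules) {
    band <- bands[[r$band]]
    abort_if(is.null(band), sprintf("unknown band '%s' in coupling rule", r$band))
    amp <- osc_base_rms * profile$band_powers[[r$band]]
    if (is.na(amp)) amp <- osc_base_rms
    m <- if (!is.null(masks[[r$band]])) masks[[r$band]]
         else band_mask(n_samples, band$low, band$high, fs)
    a <- narrowband_analytic(n_samples, band$low, band$high, fs, mask = m) * amp
    theta <- phase_offset_process(n_samples, block_len, r$mean_lag, r$kappa)
    rec[r$pair[1], ] <- rec[r$pair[1], ] + Re(a)
    rec[r$pair[2], ] <- rec[r$pair[2], ] + Re(a * exp(-1i * theta))
    if (r$band %in% colnames(coupled)) coupled[r$pair, r$band] <- TRUE
  }

  amps_all <- osc_base_rms * as.numeric(profile$band_powers)
  usable <- !vapply(masks, is.null, TRUE)
  for (ch in montage) {
    amps <- ifelse(usable & !coupled[ch, ], amps_all, 0)
    if (all(amps == 0)) next
    rec[ch, ] <- rec[ch, ] + background_rhythm(n_samples, masks[usable],
                                               amps[usable])
  }

  if (profile$erp_amplitude > 0) {
    tmpl <- p300_template(fs) * profile$erp_amplitude
    topo <- p300_topography(montage)
    erp <- numeric(n_samples)
    for (on in schedule$onsets[schedule$labels == "target"]) {
      idx <- on + seq_along(tmpl) - 1L
      keep <- idx <= n_samples
      if (any(keep)) erp[idx[keep]] <- erp[idx[keep]] + tmpl[keep]
    }
    rec <- rec + outer(topo, erp)
  }

  epochs <- epoch_record(rec, schedule, window = spec$window, sampling_rate = fs,
                         channel_names = montage, quiet = TRUE)
  epochs$subject_id <- subject_id
  epochs$group_label <- profile$label
  epochs$record <- rec
  epochs$schedule <- schedule
  epochs$seed <- as.integer(subject_seed)
  epochs
}

#' Generate a full synthetic cohort
#'
#' One epoch set per subject per group, each from its own derived seed, so any
#' subject can be regenerated bit-for-bit from the manifest alone.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given the cohort container
#'   (manifest + float32 epoch files) is written there.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param keep_records Keep each subject's continuous record in memory
#'   (needed for band-specific filtering before epoching).
#' @return A `cohort` list: `subjects` (list of epoch sets), `spec`, and a
#'   `manifest` data.frame (group, subject_id, seed).
#' @export
generate_cohort <- function(spec, dir = NULL, overwrite = FALSE,
                            keep_records = TRUE) {
  plan <- cohort_plan(spec)
  subjects <- list()
  for (i in seq_len(nrow(plan))) {
    es <- synthesize_planned_subject(spec, plan[i, ])
    if (!keep_records) es$record <- NULL
    subjects[[plan$subject_id[i]]] <- es
  }
  manifest <- plan[, c("group", "subject_id", "seed")]
  cohort <- structure(list(subjects = subjects, spec = spec, manifest = manifest),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, overwrite = overwrite)
  cohort
}

#' Deterministic per-subject generation plan of a cohort
#'
#' Derives each subject's record and schedule seeds from the cohort master
#' seed, so individual subjects can be (re)generated in isolation.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns group_index, group, subject_id, seed,
#'   schedule_seed.
#' @export
cohort_plan <- function(spec) {
  rows <- list()
  for (gi in seq_along(spec$groups)) {
    label <- spec$groups[[gi]]$label
    for (si in seq_len(spec$n_subjects_per_group)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_index = gi, group = label,
        subject_id = sprintf("%s_%02d", label, si),
        seed = derive_seed(spec$seed, paste0("subject_", label), si),
        schedule_seed = derive_seed(spec$seed, paste0("schedule_", label), si),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Synthesize one subject from a cohort_plan row.
synthesize_planned_subject <- function(spec, plan_row) {
  profile <- spec$groups[[plan_row$group_index]]
  schedule <- make_oddball_schedule(spec$n_target, spec$n_standard,
                                    spec$isi_bounds_ms, spec$sampling_rate,
                                    seed = plan_row$schedule_seed)
  synthesize_subject(profile, schedule, spec, plan_row$seed,
                     subject_id = plan_row$subject_id)
}

#' Write a cohort container to disk
#'
#' Layout: `manifest.json` (montage, rates, seeds, group map) plus one
#' little-endian float32 file per subject in trial-major (trial, channel,
#' sample) order, each with a JSON sidecar describing shape and ordering.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop(sprintf("output directory '%s' is non-empty; use overwrite = TRUE", dir),
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort$spec
  manifest <- list(
    package = "plinet", montage = spec$montage,
    sampling_rate = spec$sampling_rate, window = spec$window,
    n_target = spec$n_target, n_standard = spec$n_standard,
    isi_bounds_ms = spec$isi_bounds_ms, seed = spec$seed,
    subjects = lapply(seq_len(nrow(cohort$manifest)), function(i) {
      as.list(cohort$manifest[i, ])
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (sid in names(cohort$subjects)) {
    es <- cohort$subjects[[sid]]
    d <- es$data
    con <- file(file.path(dir, paste0(sid, ".bin")), "wb")
    writeBin(as.numeric(aperm(d, c(3, 2, 1))), con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(
      list(subject_id = sid, group = es$group_label,
           shape = dim(d), order = c("trial", "channel", "sample"),
           dtype = "float32le", window = es$window,
           sampling_rate = es$sampling_rate,
           trial_labels = es$trial_labels, seed = es$seed),
      file.path(dir, paste0(sid, ".json")), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort container from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `cohort` list (epoch sets carry no continuous records).
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  abort_if(!file.exists(mf_path), sprintf("no manifest.json under '%s'", dir))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  montage <- mf$montage
  subjects <- list()
  man <- mf$subjects
  if (is.data.frame(man)) man <- split(man, seq_len(nrow(man)))
  manifest <- NULL
  for (entry in man) {
    sid <- entry$subject_id[[1]]
    side <- jsonlite::read_json(file.path(dir, paste0(sid, ".json")),
                                simplifyVector = TRUE)
    shape <- as.integer(side$shape)
    con <- file(file.path(dir, paste0(sid, ".bin")), "rb")
    raw <- readBin(con, what = "numeric", n = prod(shape), size = 4,
                   endian = "little")
    close(con)
    d <- aperm(array(raw, dim = rev(shape)), c(3, 2, 1))
    subjects[[sid]] <- structure(
      list(data = d, channel_names = montage,
           sampling_rate = side$sampling_rate,
           trial_labels = side$trial_labels,
           subject_id = sid, group_label = side$group[[1]],
           window = side$window, seed = side$seed),
      class = "epoch_set")
    manifest <- rbind(manifest,
                      data.frame(group = side$group[[1]], subject_id = sid,
                                 seed = side$seed, stringsAsFactors = FALSE))
  }
  structure(list(subjects = subjects, spec = NULL, manifest = manifest,
                 montage = montage, sampling_rate = mf$sampling_rate,
                 seed = mf$seed),
            class = "cohort")
}
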