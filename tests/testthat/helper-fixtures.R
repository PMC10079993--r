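# Shared small fixtures built in code at test time.

# A minimal one-group cohort spec for cheap synthesis.
tiny_spec <- function(profile, n_target = 30, n_standard = 0, seed = 11) {
  cohort_spec(list(profile), n_subjects_per_group = 1, seed = seed,
              n_target = n_target, n_standard = n_standard)
}

# Synthesize one subject with the given profile and return theta-band phases.
theta_phases <- function(profile, n_target = 30, subject_seed = 42,
                         schedule_seed = 5) {
  sp <- tiny_spec(profile, n_target = n_target)
  sch <- make_oddball_schedule(n_target, 0, sampling_rate = sp$sampling_rate,
                               seed = schedule_seed)
  es <- synthesize_subject(profile, sch, sp, subject_seed)
  band_phase_series(es, "theta")
}

# A deterministic symmetric 22x22 "connectivity" matrix with distinct values.
fake_connectivity <- function(seed = 1, n = 22, names = default_montage()) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(names[seq_len(n)], names[seq_len(n)])
  connectivity_matrix(m)
}

# Separable toy classification samples: one block entry per class.
toy_samples <- function(n_subjects = 24, n_trials = 10, seed = 9,
                        signal = 0.6, noise = 0.1) {
  set.seed(seed)
  subs <- sprintf("s%02d", seq_len(n_subjects))
  grp <- rep(c("a", "b", "c"), length.out = n_subjects)
  names(grp) <- subs
  samples <- list()
  for (i in seq_len(n_subjects)) {
    g <- match(grp[i], c("a", "b", "c"))
    a <- array(0, c(n_trials, 22, 22))
    for (t in seq_len(n_trials)) {
      m <- matrix(rnorm(484, mean = 0.3, sd = noise), 22)
      m[g, g + 5] <- m[g + 5, g] <- 0.3 + signal + rnorm(1, sd = noise)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      a[t, , ] <- m
    }
    samples[[subs[i]]] <- a
  }
  list(samples = samples, groups = grp, subjects = subs)
}
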