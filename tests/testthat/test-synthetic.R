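test_that("default synthesis yields 30 x 22 x 250 baseline-corrected epochs", {
  profile <- group_profile("g")
  sp <- cohort_spec(list(profile), 1, seed = 2)
  sch <- make_oddball_schedule(sp$n_target, sp$n_standard, seed = 3)
  es <- synthesize_subject(profile, sch, sp, 7)
  expect_equal(dim(es$data), c(30, 22, 250))
  expect_true(all(is.finite(es$data)))
  # pre-stimulus mean per channel/trial is removed
  pre <- es$data[, , 1:50]
  expect_lt(max(abs(apply(pre, c(1, 2), mean))), 1e-9)
})

test_that("an infinitely concentrated pi/2 lag drives the pair's theta PLI to 1", {
  profile <- group_profile(
    "locked",
    list(coupling_rule(c("FP1", "P3"), "theta", pi / 2, Inf)),
    erp_amplitude = 0, noise_sd = 0.05,
    band_powers = c(theta = 1.5))   # isolate the band: no cross-band leakage
  ph <- theta_phases(profile)
  v <- pli_matrix(ph)$values
  expect_equal(v["FP1", "P3"], 1, tolerance = 0.02)
})

test_that("uncoupled-noise PLI shrinks as the epoch lengthens", {
  # positive bias of PLI on short epochs: with independent channels the mean
  # |sign| statistic decreases as more decorrelated samples enter the mean
  profile <- group_profile("noise", erp_amplitude = 0, noise_sd = 8)
  sp <- cohort_spec(list(profile), 1, seed = 5, n_target = 200, n_standard = 0,
                    window = c(-0.2, 1.8))
  sch <- make_oddball_schedule(200, 0, c(2200, 2600), seed = 6)
  es <- synthesize_subject(profile, sch, sp, 9)
  rec <- bandpass(es$record, "theta", sp$sampling_rate)
  short <- epoch_record(rec, sch, c(-0.2, 0.8), sp$sampling_rate,
                        sp$montage, quiet = TRUE)
  long <- epoch_record(rec, sch, c(-0.2, 1.8), sp$sampling_rate,
                       sp$montage, quiet = TRUE)
  short$band <- long$band <- "theta"
  mean_offdiag <- function(ep) {
    v <- pli_matrix(instantaneous_phase(ep))$values
    mean(v[upper.tri(v)])
  }
  expect_gt(dim(short$data)[1], 199)  # >= 200 replicate epochs enter the mean
  expect_gt(mean_offdiag(short), mean_offdiag(long))
})

test_that("achieved PLI is non-decreasing in jitter concentration", {
  kappas <- c(0, 0.5, 2, 8, Inf)
  plis <- vapply(seq_along(kappas), function(i) {
    profile <- group_profile(
      "k", list(coupling_rule(c("FP1", "P3"), "theta", pi / 2, kappas[i])),
      erp_amplitude = 0, noise_sd = 2)
    ph <- theta_phases(profile, n_target = 100, subject_seed = 20 + i,
                       schedule_seed = 30 + i)
    pli_matrix(ph)$values["FP1", "P3"]
  }, numeric(1))
  expect_true(all(diff(plis) > -0.02))  # monotone up to Monte-Carlo jitter
  expect_gt(plis[5] - plis[1], 0.3)
})

test_that("cohort generation is manifest-driven and exactly regenerable", {
  spec <- cohort_spec(list(group_profile("a"), group_profile("b"),
                           group_profile("c")),
                      n_subjects_per_group = 1, seed = 4, n_target = 5,
                      n_standard = 5)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$manifest), 3)
  expect_setequal(co$manifest$group, c("a", "b", "c"))
  co2 <- generate_cohort(spec)
  expect_identical(co$subjects[[1]]$data, co2$subjects[[1]]$data)
  # per-subject regeneration from the plan alone
  plan <- cohort_plan(spec)
  es <- plinet:::synthesize_planned_subject(spec, plan[2, ])
  expect_identical(es$data, co$subjects[[plan$subject_id[2]]]$data)
})

test_that("cohort container round-trips through disk at float32 precision", {
  spec <- cohort_spec(list(group_profile("a"), group_profile("b")),
                      n_subjects_per_group = 1, seed = 8, n_target = 4,
                      n_standard = 0)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, overwrite = TRUE)
  expect_error(write_cohort(co, dir), "non-empty")
  back <- read_cohort(dir)
  expect_setequal(names(back$subjects), names(co$subjects))
  for (sid in names(co$subjects)) {
    expect_equal(back$subjects[[sid]]$data, co$subjects[[sid]]$data,
                 tolerance = 1e-6)
    expect_equal(back$subjects[[sid]]$group_label, co$subjects[[sid]]$group_label)
  }
})

test_that("coupling rules naming unknown channels are rejected", {
  expect_error(
    cohort_spec(list(group_profile("bad", list(coupling_rule(c("FP1", "XX"))))),
                n_subjects_per_group = 1),
    "unknown channel")
  expect_error(cohort_spec(list(group_profile("g")), montage = c("A", "B")),
               "22 unique")
})
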