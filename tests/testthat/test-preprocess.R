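test_that("resampling scales length and preserves in-band sinusoids", {
  t1k <- seq(0, 10 - 1e-3, by = 1e-3)
  x <- sin(2 * pi * 6 * t1k)
  y <- resample_eeg(x, 1000, 250)
  expect_length(y, 2500)
  # amplitude of the 6 Hz tone preserved within 2% (interior samples)
  interior <- y[200:2300]
  expect_equal(max(abs(interior)), 1, tolerance = 0.02)
  expect_identical(resample_eeg(x, 1000, 1000), x)
  expect_error(resample_eeg(x, 250, 1000), "upsampling")
})

test_that("theta band-pass passes 6 Hz and suppresses 50 Hz", {
  fs <- 250
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  gain <- function(f) {
    y <- bandpass(sin(2 * pi * f * t), "theta", fs)
    interior <- y[(2 * fs):((10 * fs))]
    max(abs(interior))
  }
  expect_gte(gain(6), 0.9)
  expect_lt(20 * log10(gain(50)), -20)
  expect_equal(bandpass(numeric(1000), "theta", fs), numeric(1000))
  bad <- band_definition("toohigh", 100, 130)
  expect_error(bandpass(sin(t), bad, fs), "Nyquist")
})

test_that("band-pass filtering is near-idempotent for band-centred tones", {
  fs <- 250
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 6 * t)
  once <- bandpass(x, "theta", fs)
  twice <- bandpass(once, "theta", fs)
  interior <- (2 * fs):(10 * fs)
  expect_equal(twice[interior], once[interior], tolerance = 0.02)
})

test_that("epoching cuts the stated window, drops boundary events, zeroes baselines", {
  fs <- 250
  rec <- matrix(rnorm(22 * 5000), 22)
  rownames(rec) <- default_montage()
  onsets <- as.integer(seq(300, 4500, length.out = 30))
  sch <- list(onsets = onsets, labels = rep("target", 30))
  ep <- epoch_record(rec, sch, c(-0.2, 0.8), fs)
  expect_equal(dim(ep$data), c(30, 22, 250))
  pre <- apply(ep$data[, , 1:50], c(1, 2), mean)
  expect_lt(max(abs(pre)), 1e-9)

  sch_bad <- list(onsets = c(10L, onsets), labels = rep("target", 31))
  expect_warning(ep2 <- epoch_record(rec, sch_bad, c(-0.2, 0.8), fs), "dropped")
  expect_equal(dim(ep2$data)[1], 30)
  expect_equal(ep2$n_dropped, 1)
  # conservation: emitted + dropped = scheduled targets
  expect_equal(dim(ep2$data)[1] + ep2$n_dropped, 31)
})

test_that("artifact rejection removes exactly the over-limit trials", {
  fs <- 250
  rec <- matrix(rnorm(22 * 5000, sd = 10), 22)
  rownames(rec) <- default_montage()
  sch <- list(onsets = as.integer(seq(300, 4500, length.out = 20)),
              labels = rep("target", 20))
  ep <- epoch_record(rec, sch, c(-0.2, 0.8), fs)
  ep$data[7, 3, 100] <- 500  # one spiked trial
  kept <- reject_artifacts(ep, 200)
  expect_equal(kept$rejected, 7L)
  expect_equal(dim(kept$data)[1], 19)
  expect_identical(reject_artifacts(ep, Inf)$data, ep$data)
  # brute-force rejection count over all trials agrees
  brute <- sum(vapply(seq_len(dim(ep$data)[1]), function(tr) {
    any(apply(ep$data[tr, , ], 1, function(ch) diff(range(ch))) > 200)
  }, TRUE))
  expect_equal(length(kept$rejected), brute)
  expect_error(reject_artifacts(ep, 1e-6), "peak-to-peak")
})
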