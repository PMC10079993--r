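test_that("analytic phase behaves like a phase", {
  fs <- 250
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  ep <- structure(list(
    data = array(c(cos(2 * pi * 6 * t), sin(2 * pi * 6 * t)),
                 c(1, 2, length(t))) * 0, channel_names = c("a", "b"),
    sampling_rate = fs, window = c(0, 1), band = "theta"),
    class = "epoch_set")
  ep$data[1, 1, ] <- cos(2 * pi * 6 * t)
  ep$data[1, 2, ] <- sin(2 * pi * 6 * t)
  ph <- instantaneous_phase(ep)
  expect_true(all(ph$phase > -pi & ph$phase <= pi))
  # unwrapped slope of the cosine's phase ~ 2*pi*6 rad/s (interior samples)
  interior <- 26:225
  unwrapped <- cumsum(c(ph$phase[1, 1, interior[1]],
                        plinet:::wrap_phase(diff(ph$phase[1, 1, interior]))))
  slope <- coef(lm(unwrapped ~ t[interior]))[2]
  expect_equal(as.numeric(slope), 2 * pi * 6, tolerance = 0.01 * 2 * pi * 6)
  # cos leads sin by a constant pi/2
  d <- plinet:::wrap_phase(ph$phase[1, 1, interior] - ph$phase[1, 2, interior])
  expect_equal(mean(d), pi / 2, tolerance = 0.02)
  ep$data[1, 2, ] <- 0
  expect_error(instantaneous_phase(ep), "zero")
})

test_that("pli_pair matches its closed forms and the sign-count oracle", {
  phi <- runif(250, -pi, pi)
  expect_equal(pli_pair(phi, phi), 0)
  expect_equal(pli_pair(phi, plinet:::wrap_phase(phi - pi / 2)), 1)
  expect_error(pli_pair(phi, phi[-1]), "length")
  set.seed(14)
  for (rep in 1:5) {
    px <- runif(250, -pi, pi); py <- runif(250, -pi, pi)
    expect_equal(pli_pair(px, py), oracle_pli(px, py))
  }
  # invariance to a common phase offset
  px <- runif(100, -pi, pi); py <- runif(100, -pi, pi)
  expect_equal(pli_pair(px, py),
               pli_pair(plinet:::wrap_phase(px + 1.3),
                        plinet:::wrap_phase(py + 1.3)))
})

test_that("trial PLI matrices agree with the pairwise oracle on a 4x50 fixture", {
  set.seed(21)
  ph <- array(runif(3 * 4 * 50, -pi, pi), c(3, 4, 50))
  ps <- structure(list(phase = ph, channel_names = paste0("c", 1:4),
                       band = "x"), class = "phase_series")
  tm <- pli_trial_matrices(ps)
  for (tr in 1:3) for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(tm[tr, i, j], oracle_pli(ph[tr, i, ], ph[tr, j, ]))
    expect_equal(tm[tr, i, j], tm[tr, j, i])
  }
  expect_true(all(apply(tm, 1, diag) == 0))
})

test_that("subject matrix is the element-wise mean of trial matrices", {
  set.seed(22)
  ph <- array(runif(5 * 4 * 60, -pi, pi), c(5, 4, 60))
  ps <- structure(list(phase = ph, channel_names = paste0("c", 1:4),
                       band = "x"), class = "phase_series")
  subject <- pli_matrix(ps)$values
  tm <- pli_trial_matrices(ps)
  manual <- matrix(0, 4, 4)
  for (tr in 1:5) manual <- manual + tm[tr, , ]
  expect_equal(unname(subject), manual / 5)
  # identical channels give zero off-diagonals
  ph_id <- ph; for (c in 2:4) ph_id[, c, ] <- ph_id[, 1, ]
  ps_id <- structure(list(phase = ph_id, channel_names = paste0("c", 1:4),
                          band = "x"), class = "phase_series")
  expect_true(all(pli_matrix(ps_id)$values == 0))
})

test_that("phase-shuffled surrogates lose the coupled PLI", {
  set.seed(30)
  n <- 200
  base <- cumsum(rnorm(n, sd = 0.3))
  px <- plinet:::wrap_phase(base)
  py <- plinet:::wrap_phase(base - pi / 2 + rnorm(n, sd = 0.2))
  coupled <- pli_pair(px, py)
  surrogate <- replicate(100, pli_pair(px, sample(py)))
  expect_gt(coupled, quantile(surrogate, 0.99))
})

test_that("proportional threshold keeps exactly floor(density * pairs) edges", {
  C <- fake_connectivity(seed = 5)
  thr <- proportional_threshold(C, 0.30)
  expect_equal(sum(thr$values[upper.tri(thr$values)] > 0), 69)
  expect_equal(thr$values, t(thr$values))
  # kept edges are the strongest ones
  kept <- C$values[upper.tri(C$values)][thr$values[upper.tri(thr$values)] > 0]
  dropped <- C$values[upper.tri(C$values)][thr$values[upper.tri(thr$values)] == 0]
  expect_gt(min(kept), max(dropped))
  expect_equal(proportional_threshold(C, 1)$values, C$values)
  expect_error(proportional_threshold(C, 0), "density")
})

test_that("all-equal weights break ties by ascending (row, column) index", {
  m <- matrix(0.5, 6, 6); diag(m) <- 0
  dimnames(m) <- list(letters[1:6], letters[1:6])
  C <- connectivity_matrix(m)
  thr <- proportional_threshold(C, 0.30)   # floor(0.3 * 15) = 4 edges
  kept <- which(thr$values != 0 & upper.tri(thr$values), arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), , drop = FALSE]
  expect_equal(unname(kept),
               cbind(c(1, 1, 1, 1), c(2, 3, 4, 5)))
  # deterministic across calls
  expect_identical(thr$values, proportional_threshold(C, 0.30)$values)
})

test_that("difference matrices are signed, sparse and antisymmetric in arguments", {
  Ca <- fake_connectivity(seed = 7)
  Cb <- fake_connectivity(seed = 8)
  D <- difference_matrix(Ca, Cb, 0.30)
  expect_equal(sum(D$values[upper.tri(D$values)] != 0), 69)
  expect_true(any(D$values < 0))
  D0 <- difference_matrix(Ca, Ca)
  expect_true(all(D0$values == 0))
  Dba <- difference_matrix(Cb, Ca, 0.30)
  expect_equal(D$values, -Dba$values)
  Cc <- fake_connectivity(seed = 9, n = 5, names = letters[1:5])
  expect_error(difference_matrix(Ca, Cc), "montage")
})
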