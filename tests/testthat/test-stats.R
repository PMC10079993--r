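test_that("strength table enumerates subject x channel row means", {
  mats <- lapply(1:15, function(i) fake_connectivity(seed = i))
  groups <- rep(c("cpp", "dd", "hc"), each = 5)
  tbl <- node_strength_table(mats, groups, band = "theta")
  expect_equal(nrow(tbl), 15 * 22)
  expect_true(all(tbl$value >= 0 & tbl$value <= 1))
  # row means equal an explicit per-row loop
  m1 <- mats[[1]]$values
  manual <- vapply(seq_len(22), function(i) sum(m1[i, -i]) / 21, 0)
  expect_equal(tbl$value[tbl$subject == "s1"], manual)
  # constant matrix c -> every value c
  cm <- matrix(0.4, 22, 22); diag(cm) <- 0
  dimnames(cm) <- list(default_montage(), default_montage())
  tbl_c <- node_strength_table(list(connectivity_matrix(cm), mats[[1]]),
                               c("a", "b"))
  expect_true(all(abs(tbl_c$value[tbl_c$group == "a"] - 0.4 * 21 / 21) < 1e-12))
  # per-subject-mean variant collapses channels
  tbl_m <- node_strength_table(mats, groups, per_subject_mean = TRUE)
  expect_equal(nrow(tbl_m), 15)
  expect_equal(tbl_m$value[1], mean(manual))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # textbook 3 x 5 fixture, decomposed by hand
  vals <- c(6.2, 5.9, 6.5, 6.1, 6.3,
            7.1, 7.4, 6.9, 7.2, 7.0,
            5.1, 5.3, 4.9, 5.2, 5.0)
  grp <- rep(c("a", "b", "c"), each = 5)
  obs <- data.frame(value = vals, group = grp)
  res <- one_way_anova(obs)
  grand <- mean(vals)
  means <- tapply(vals, grp, mean)
  ss_b <- 5 * sum((means - grand)^2)
  ss_w <- sum((vals - rep(means, each = 5))^2)
  expect_equal(res$ss_between, ss_b)
  expect_equal(res$ms_between, ss_b / 2)
  expect_equal(res$F, (ss_b / 2) / (ss_w / 12))
  expect_equal(res$p, pf(res$F, 2, 12, lower.tail = FALSE))
})

test_that("ANOVA edge cases: identical groups, two-group t^2 identity, degeneracy", {
  v <- c(1, 2, 3, 4)
  obs0 <- data.frame(value = rep(v, 3), group = rep(c("a", "b", "c"), each = 4))
  expect_equal(one_way_anova(obs0)$F, 0)

  set.seed(50)
  x <- rnorm(10); y <- rnorm(12, mean = 0.5)
  obs2 <- data.frame(value = c(x, y), group = rep(c("a", "b"), c(10, 12)))
  res2 <- one_way_anova(obs2)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2)

  obs_d <- data.frame(value = rep(c(1, 2), each = 3),
                      group = rep(c("a", "b"), each = 3))
  res_d <- one_way_anova(obs_d)
  expect_true(res_d$degenerate)
  expect_lte(res_d$p, .Machine$double.xmin)
})

test_that("Tukey post-hoc ordering follows group separation", {
  obs0 <- data.frame(value = rep(c(1, 2, 3, 4), 3),
                     group = rep(c("a", "b", "c"), each = 4))
  tk0 <- tukey_hsd(obs0)
  expect_true(all(tk0$p_adj > 0.99))

  set.seed(51)
  sep <- data.frame(
    value = c(rnorm(8), rnorm(8), rnorm(8, mean = 10)),
    group = rep(c("a", "b", "c"), each = 8))
  tk <- tukey_hsd(sep)
  p <- setNames(tk$p_adj, tk$pair)
  expect_lt(max(p["c-a"], p["c-b"]), p["b-a"])

  # with equal n, smaller pairwise p goes with larger mean difference
  set.seed(52)
  g <- data.frame(value = c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 3)),
                  group = rep(c("a", "b", "c"), each = 10))
  tk2 <- tukey_hsd(g)
  ord_p <- order(tk2$p_adj)
  ord_d <- order(-abs(tk2$diff))
  expect_equal(ord_p, ord_d)
})

test_that("null calibration p-values are uniform on the subject-mean unit", {
  ps <- null_anova_calibration(n_sim = 60, n_subjects_per_group = 4,
                               n_trials = 6, n_samples = 60, seed = 77)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
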