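test_that("pli-variant layer trace reproduces the published widths", {
  s <- architecture_spec("pli")
  expect_equal(s$input_width, 22L)
  expect_equal(s$w_after_pool1, 11L)   # 22 -> 11 after the halved pooling
  expect_equal(s$w_after_sep, 12L)     # even separable kernel gains one
  expect_equal(s$w_after_pool2, 1L)
  tbl <- count_parameters(build_model(s, seed = 1))
  expect_equal(tbl$params,
               c(1000L, 16L, 352L, 32L, 0L, 0L, 0L, 352L, 256L, 32L, 0L, 0L,
                 0L, 51L, 0L))
  expect_equal(attr(tbl, "total"), 2091L)
})

test_that("eeg-variant trace follows the compact-CNN conventions", {
  s <- architecture_spec("eeg")
  expect_equal(s$input_width, 250L)
  expect_equal(s$pool1_width, 4L)
  expect_equal(s$w_after_pool1, 62L)
  m <- build_model(s, seed = 1)
  x <- array(rnorm(2 * 22 * 250), c(2, 22, 250))
  fw <- forward_cnn(m, x)
  expect_equal(dim(fw$logp), c(2, 3))
  expect_error(architecture_spec("pli", pool1_width = 40), "trace")
})

test_that("outputs are normalized log-probabilities", {
  m <- build_model(architecture_spec("pli"), seed = 3)
  x <- array(rnorm(5 * 22 * 22), c(5, 22, 22))
  fw <- forward_cnn(m, x)
  expect_equal(rowSums(exp(fw$logp)), rep(1, 5), tolerance = 1e-6)
})

test_that("NLL loss matches its closed forms and a weighted hand computation", {
  uniform <- matrix(log(1 / 3), 4, 3)
  expect_equal(nll_loss(uniform, c(1, 2, 3, 1))$loss, log(3))
  perfect <- matrix(-50, 2, 3)
  perfect[cbind(1:2, c(2, 3))] <- 0
  expect_equal(nll_loss(perfect, c(2, 3))$loss, 0)
  # weighted batch evaluated by hand: l_n = -w_yn * x_nyn, mean by sum(w)
  lp <- matrix(log(c(0.7, 0.2, 0.1,
                     0.1, 0.6, 0.3,
                     0.2, 0.2, 0.6)), 3, 3, byrow = TRUE)
  w <- c(1, 2, 1)
  y <- c(1, 2, 3)
  manual <- -(1 * log(0.7) + 2 * log(0.6) + 1 * log(0.6)) / (1 + 2 + 1)
  expect_equal(nll_loss(lp, y, w)$loss, manual)
  expect_error(nll_loss(lp, c(0, 1, 2)), "labels")
})

test_that("Adam: zero-gradient fixpoint, exact bias correction, quadratic descent", {
  cfg <- train_config(learning_rate = 0.1, weight_decay = 0)
  params <- list(w = matrix(c(1, -2), 1))
  st <- adam_init(params)
  up <- adam_step(params, list(w = matrix(0, 1, 2)), st, cfg)
  expect_equal(up$params$w, params$w)
  # first step with constant gradient g: m_hat == g exactly
  g <- matrix(c(0.3, -0.7), 1)
  st2 <- adam_init(params)
  up2 <- adam_step(params, list(w = g), st2, cfg)
  expect_equal(up2$state$m$w / (1 - cfg$beta1), g)
  step <- params$w - up2$params$w
  expect_equal(sign(step), sign(g))
  # 100 steps on f(x) = x^2 from x = 3
  p <- list(x = 3)
  s <- adam_init(p)
  for (i in 1:100) {
    up <- adam_step(p, list(x = 2 * p$x), s, cfg)
    p <- up$params; s <- up$state
  }
  expect_lt(p$x^2, 1e-3 * 9)
  expect_error(adam_step(p, list(x = NaN), s, cfg), "non-finite")
})

test_that("weight decay is decoupled and max-norm constrains the spatial filters", {
  cfg <- train_config(learning_rate = 0.01, weight_decay = 0.5)
  params <- list(dw_W = matrix(c(3, 4, 0, 0.1), 2))
  st <- adam_init(params)
  up <- adam_step(params, list(dw_W = matrix(0, 2, 2)), st, cfg,
                  max_norm = 1.0)
  expect_equal(sqrt(colSums(up$params$dw_W^2))[1], 1.0)     # renormalized
  expect_lt(sqrt(colSums(up$params$dw_W^2))[2], 1.0)        # untouched, decayed
  # zero gradient, no constraint: pure multiplicative shrinkage
  up2 <- adam_step(params, list(dw_W = matrix(0, 2, 2)), st, cfg)
  expect_equal(up2$params$dw_W, params$dw_W * (1 - 0.01 * 0.5))
})

test_that("fold assignment is subject-exclusive and group-balanced", {
  subs <- sprintf("s%02d", 1:30)
  grp <- rep(c("cpp", "dd", "hc"), 10)
  fa <- assign_folds(subs, grp, k = 10, seed = 5)
  counts <- table(fa$group, fa$fold)
  expect_true(all(counts == 1))   # divisible case: exactly 1 per group per fold
  expect_equal(anyDuplicated(fa$subject), 0)

  # 67 subjects (23/22/22): per-fold group counts differ by at most 1
  subs2 <- sprintf("t%02d", 1:67)
  grp2 <- rep(c("cpp", "dd", "hc"), c(23, 22, 22))
  fa2 <- assign_folds(subs2, grp2, k = 10, seed = 6)
  counts2 <- table(fa2$group, fa2$fold)
  expect_lte(max(counts2) - min(counts2), 1)
  totals <- table(fa2$fold)
  expect_lte(max(totals) - min(totals), 1)

  sp <- split_folds(fa, test_fold = 3)
  expect_length(intersect(sp$test, c(sp$train, sp$validation)), 0)
  expect_length(intersect(sp$validation, sp$train), 0)
  expect_setequal(c(sp$test, sp$validation, sp$train), subs)
  expect_error(assign_folds(subs[1:5], grp[1:5], k = 10), "folds")
})

test_that("training logs per-epoch curves and is bitwise reproducible", {
  toy <- toy_samples(n_subjects = 12, n_trials = 4)
  folds <- assign_folds(toy$subjects, toy$groups, k = 10, seed = 2)
  cfg <- train_config(epochs = 2, seed = 42)
  arch <- architecture_spec("pli")
  tr1 <- train_cnn(toy$samples, toy$groups, folds, arch, cfg)
  expect_equal(nrow(tr1$history), 2)
  expect_named(tr1$history, c("epoch", "train_loss", "train_acc",
                              "val_loss", "val_acc"))
  tr2 <- train_cnn(toy$samples, toy$groups, folds, arch, cfg)
  expect_identical(tr1$model$params, tr2$model$params)
  expect_identical(tr1$history, tr2$history)
})

test_that("evaluation metrics match hand-worked confusion-matrix values", {
  # confusion [[2,1,0],[0,3,0],[1,0,3]] worked by hand
  truth <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  pred  <- c(1, 1, 2, 2, 2, 2, 1, 3, 3, 3)
  ev <- evaluate_predictions(pred, truth, n_classes = 3)
  expect_equal(unname(ev$confusion),
               rbind(c(2, 1, 0), c(0, 3, 0), c(1, 0, 3)))
  p1 <- 2 / 3; r1 <- 2 / 3; f1_1 <- 2 * p1 * r1 / (p1 + r1)
  p2 <- 3 / 4; r2 <- 1;     f1_2 <- 2 * p2 * r2 / (p2 + r2)
  p3 <- 1;     r3 <- 3 / 4; f1_3 <- 2 * p3 * r3 / (p3 + r3)
  expect_equal(unname(ev$f1), c(f1_1, f1_2, f1_3))
  expect_equal(ev$macro_f1, mean(c(f1_1, f1_2, f1_3)))
  expect_equal(ev$accuracy, 0.8)

  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  all_one <- evaluate_predictions(rep(1, 9), rep(1:3, 3))
  expect_equal(all_one$accuracy, 1 / 3)

  expect_warning(ev2 <- evaluate_predictions(c(1, 2, 1), c(1, 2, 2),
                                             n_classes = 3),
                 "absent")
  expect_false(is.na(ev2$macro_f1))
})
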