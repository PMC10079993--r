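#' Subject-exclusive, group-balanced fold assignment
#'
#' Every subject's trials live in exactly one fold, and each group's subjects
#' are dealt round-robin over the folds so per-fold group counts differ by at
#' most one. Deterministic for a fixed seed.
#'
#' @param subjects Character vector of subject identifiers.
#' @param groups Group label per subject.
#' @param k Number of folds (default 10).
#' @param seed Shuffling seed.
#' @return A `fold_assignment`: data.frame (subject, group, fold in 1..k).
#' @export
assign_folds <- function(subjects, groups, k = 10L, seed = 1L) {
  abort_if(length(subjects) < k, sprintf(
    "cannot make %d folds from %d subjects", k, length(subjects)))
  abort_if(anyDuplicated(subjects) > 0, "duplicated subject identifiers")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(subjects))
  offset <- 0L
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    # rotate the starting fold so groups with < k subjects still cover all folds
    offset <- (offset + length(idx)) %% k
  }
  structure(data.frame(subject = subjects, group = groups, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("fold_assignment", "data.frame"), k = k)
}

#' Split folds into test / validation / training roles (1 : 2 : 7)
#'
#' @param assignment A [assign_folds()] result.
#' @param test_fold Index of the test fold.
#' @return List of subject-id vectors `test`, `validation`, `train`.
#' @export
split_folds <- function(assignment, test_fold = 1L) {
  k <- attr(assignment, "k")
  abort_if(test_fold < 1 || test_fold > k, "test_fold out of range")
  val_folds <- ((test_fold + c(0L, 1L)) %% k) + 1L
  roles <- list(test = assignment$subject[assignment$fold == test_fold],
                validation = assignment$subject[assignment$fold %in% val_folds],
                train = assignment$subject[!assignment$fold %in% c(test_fold, val_folds)])
  abort_if(!length(roles$train) || !length(roles$validation) || !length(roles$test),
           "empty split: too few subjects for a 1:2:7 fold division")
  roles
}

# Assemble a labelled sample tensor from a per-subject sample list.
# samples: named list subject -> array [n_i, H, W]; groups: subject -> label.
stack_samples <- function(samples, groups, subject_filter = NULL) {
  ids <- names(samples)
  if (!is.null(subject_filter)) ids <- intersect(ids, subject_filter)
  abort_if(!length(ids), "empty split: no subjects selected")
  lab_levels <- sort(unique(unname(groups)))
  xs <- list(); ys <- integer(0); subj <- character(0)
  for (sid in ids) {
    a <- samples[[sid]]
    xs[[sid]] <- a
    ys <- c(ys, rep(match(groups[[sid]], lab_levels), dim(a)[1]))
    subj <- c(subj, rep(sid, dim(a)[1]))
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], 0L))
  d <- dim(xs[[1]])
  x <- array(0, c(n, d[2], d[3]))
  at <- 1L
  for (sid in ids) {
    ni <- dim(xs[[sid]])[1]
    x[at:(at + ni - 1L), , ] <- xs[[sid]]
    at <- at + ni
  }
  list(x = x, y = ys, subject = subj, levels = lab_levels)
}

#' Train the compact CNN
#'
#' Mini-batch Adam training with decoupled weight decay, max-norm constraint
#' on the depthwise spatial filters, dropout active only in training, and
#' per-epoch train/validation loss and accuracy logging. The returned model
#' is the checkpoint with the best validation accuracy (ties resolved to the
#' earliest epoch). Bitwise reproducible for a fixed `(seed, config)`.
#'
#' @param samples Named list: subject id -> array `[trials, channels, width]`
#'   (band-filtered epochs for the eeg variant, per-trial PLI matrices for
#'   the pli variant).
#' @param groups Named vector/list: subject id -> group label.
#' @param folds A [assign_folds()] assignment.
#' @param arch An [architecture_spec()].
#' @param config A [train_config()].
#' @param test_fold Which fold is held out as the test set.
#' @param verbose Print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return A `train_result`: `model` (best checkpoint), `history` data.frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc), `splits`, `levels`,
#'   `best_epoch`.
#' @export
train_cnn <- function(samples, groups, folds, arch, config = train_config(),
                      test_fold = 1L, verbose = 0L) {
  splits <- split_folds(folds, test_fold)
  train_set <- stack_samples(samples, groups, splits$train)
  val_set <- stack_samples(samples, groups, splits$validation)
  # subject exclusivity asserted structurally on every run
  abort_if(length(intersect(splits$test, splits$train)) > 0 ||
             length(intersect(splits$test, splits$validation)) > 0,
           "subject leakage between test and train/validation splits")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  model <- build_model(arch, seed = config$seed)
  state <- adam_init(model$params)
  n_train <- dim(train_set$x)[1]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(acc = -Inf, params = model$params, bn = model$bn, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n_train)   # each dataset is disordered before training
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n_train, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_train)]
      xb <- train_set$x[idx, , , drop = FALSE]
      yb <- train_set$y[idx]
      fw <- forward_cnn(model, xb, training = TRUE)
      model <- fw$model
      ls <- nll_loss(fw$logp, yb, config$class_weights)
      grads <- backward_cnn(model, fw$cache, ls$dlogp)
      upd <- adam_step(model$params, grads, state, config,
                       max_norm = arch$max_norm)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + ls$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(fw$logp) == yb)
    }
    val_fw <- forward_cnn(model, val_set$x, training = FALSE)
    val_ls <- nll_loss(val_fw$logp, val_set$y, config$class_weights)
    val_acc <- mean(max.col(val_fw$logp) == val_set$y)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n_train,
      train_acc = ep_correct / n_train, val_loss = val_ls$loss,
      val_acc = val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params, bn = model$bn,
                   epoch = epoch)
    }
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, ep_loss / n_train, ep_correct / n_train,
                      val_ls$loss, val_acc))
  }
  final_model <- model
  model$params <- best$params
  model$bn <- best$bn
  structure(list(model = model, final_model = final_model, history = history,
                 splits = splits, levels = train_set$levels,
                 best_epoch = best$epoch, config = config, arch = arch),
            class = "train_result")
}

#' Evaluate a trained model on held-out subjects
#'
#' @param model A `cnn_model`.
#' @param samples,groups As in [train_cnn()].
#' @param subject_filter Subject ids of the evaluation split (e.g.
#'   `result$splits$test`).
#' @param levels Class-label ordering used during training.
#' @return An `evaluation_report`: `accuracy`, `confusion` matrix, per-class
#'   `precision`/`recall`/`f1`, `macro_f1`, `predictions`.
#' @export
evaluate_model <- function(model, samples, groups, subject_filter = NULL,
                           levels = NULL) {
  set_ <- stack_samples(samples, groups, subject_filter)
  if (!is.null(levels)) {
    set_$y <- match(unname(unlist(groups))[match(set_$subject, names(groups))], levels)
    set_$levels <- levels
  }
  fw <- forward_cnn(model, set_$x, training = FALSE)
  pred <- max.col(fw$logp)
  evaluate_predictions(pred, set_$y, n_classes = length(set_$levels),
                       class_names = set_$levels)
}

#' Classification metrics from predictions
#'
#' Accuracy, per-class precision/recall/F1 (`F1 = 2PR/(P+R)`), and Macro-F1,
#' the unweighted mean of the per-class F1 values. A class absent from the
#' true labels has undefined F1 and is excluded from the macro mean with a
#' warning.
#'
#' @param pred,truth Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param class_names Optional class names.
#' @return An `evaluation_report` list.
#' @export
evaluate_predictions <- function(pred, truth, n_classes = max(truth, pred),
                                 class_names = NULL) {
  cls <- seq_len(n_classes)
  confusion <- table(factor(truth, levels = cls), factor(pred, levels = cls))
  confusion <- unclass(as.matrix(confusion))
  if (!is.null(class_names)) dimnames(confusion) <- list(true = class_names,
                                                         predicted = class_names)
  tp <- diag(confusion)
  precision <- tp / pmax(colSums(confusion), 0)
  recall <- tp / pmax(rowSums(confusion), 0)
  f1 <- 2 * precision * recall / (precision + recall)
  f1[is.nan(f1)] <- 0        # P + R = 0 with the class present: F1 = 0
  absent <- rowSums(confusion) == 0
  if (any(absent)) {
    warning(sprintf("class(es) %s absent from the true labels; excluded from Macro-F1",
                    paste(cls[absent], collapse = ", ")))
    f1[absent] <- NA_real_
  }
  structure(list(accuracy = mean(pred == truth), confusion = confusion,
                 precision = precision, recall = recall, f1 = f1,
                 macro_f1 = mean(f1, na.rm = TRUE),
                 predictions = pred, truth = truth),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f, Macro-F1 %.3f\n", x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}
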