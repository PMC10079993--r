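#' Training hyperparameter configuration
#'
#' Defaults: batch size 32, Adam with learning rate 1e-4, beta1 0.9,
#' beta2 0.999, epsilon 1e-8, decoupled weight decay 0.2, 1000 epochs,
#' uniform class weights.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size (alpha).
#' @param beta1,beta2 Exponential decay rates of the first and second moment
#'   estimates, in (0, 1).
#' @param eps Numerical stabilizer added to `sqrt(v_hat)`.
#' @param weight_decay Decoupled weight-decay coefficient (lambda), applied to
#'   convolution and classifier weights (not to normalization parameters or
#'   biases).
#' @param epochs Number of training epochs.
#' @param class_weights Optional per-class loss weights.
#' @param seed Training seed (weight init, shuffling, dropout).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0.2, epochs = 1000L,
                         class_weights = NULL, seed = 1L) {
  abort_if(!(beta1 > 0 && beta1 < 1 && beta2 > 0 && beta2 < 1),
           "beta1 and beta2 must lie in (0, 1)")
  abort_if(batch_size < 1 || learning_rate <= 0 || eps <= 0 ||
             weight_decay < 0 || epochs < 1, "invalid training configuration")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, weight_decay = weight_decay,
                 epochs = as.integer(epochs), class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Parameters subject to weight decay and (for dw_W) the max-norm constraint.
DECAYED_PARAMS <- c("conv1_K", "dw_W", "sep_K", "pw_W", "cls_W")

#' Initialize Adam optimizer state
#'
#' @param params Named list of parameter arrays.
#' @return An `optimizer_state` with zeroed first/second moments and t = 0.
#' @export
adam_init <- function(params) {
  structure(list(m = lapply(params, function(x) x * 0),
                 v = lapply(params, function(x) x * 0),
                 t = 0L),
            class = "optimizer_state")
}

#' One Adam update with decoupled weight decay and max-norm constraint
#'
#' First/second moment updates `m <- b1 m + (1-b1) g`,
#' `v <- b2 v + (1-b2) g^2`, bias corrections `m_hat = m/(1-b1^t)`,
#' `v_hat = v/(1-b2^t)`, then the decoupled update
#' `theta <- (1 - alpha*lambda) theta - alpha * m_hat / (sqrt(v_hat) + eps)`
#' for weight parameters (normalization parameters and biases skip the decay
#' term). After the step, each depthwise spatial filter is renormalized to
#' the spec's max-norm bound.
#'
#' @param params Named list of parameters.
#' @param grads Named list of gradients (same shapes).
#' @param state An `optimizer_state`.
#' @param config A [train_config()].
#' @param max_norm Optional max-norm bound applied to the columns of `dw_W`.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, config, max_norm = NULL) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - config$beta1^t
  bc2 <- 1 - config$beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    abort_if(is.null(g), sprintf("missing gradient for parameter '%s'", nm))
    abort_if(any(!is.finite(g)), sprintf("non-finite gradient in parameter '%s'", nm))
    state$m[[nm]] <- config$beta1 * state$m[[nm]] + (1 - config$beta1) * g
    state$v[[nm]] <- config$beta2 * state$v[[nm]] + (1 - config$beta2) * g^2
    m_hat <- state$m[[nm]] / bc1
    v_hat <- state$v[[nm]] / bc2
    decay <- if (nm %in% DECAYED_PARAMS) config$learning_rate * config$weight_decay else 0
    params[[nm]] <- (1 - decay) * params[[nm]] -
      config$learning_rate * m_hat / (sqrt(v_hat) + config$eps)
  }
  if (!is.null(max_norm) && "dw_W" %in% names(params)) {
    W <- params$dw_W
    nrm <- sqrt(colSums(W^2))
    over <- nrm > max_norm
    if (any(over)) W[, over] <- sweep(W[, over, drop = FALSE], 2,
                                      max_norm / nrm[over], `*`)
    params$dw_W <- W
  }
  list(params = params, state = state)
}
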