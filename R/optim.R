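# Small hand-rolled first-order optimisers over named lists of parameter
# arrays. Parameter lists are flat: list(name = matrix/vector, ...); gradient
# lists mirror them exactly.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

#' Training settings for the network optimisers
#'
#' Defaults follow the pattern-analysis protocol: Adam with learning rate
#' 0.001, at most 100 epochs, early stopping with patience 10 on a 20%
#' validation split. The classifier uses SGD with learning rate 0.01 and a
#' step decay instead (see [train_classifier()]).
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate positive step size.
#' @param max_epochs maximum number of full-batch epochs.
#' @param patience epochs without validation improvement before stopping;
#'   must not exceed `max_epochs`.
#' @param validation_fraction fraction of units held out for validation,
#'   in (0, 1).
#' @param momentum heavy-ball momentum for SGD (ignored by Adam).
#' @param seed integer seed controlling initialisation and splits.
#' @return object of class `train_settings`.
#' @export
train_settings <- function(optimizer = c("adam", "sgd"), learning_rate = 0.001,
                           max_epochs = 100, patience = 10,
                           validation_fraction = 0.2, momentum = 0.9,
                           seed = 1L) {
  optimizer <- match.arg(optimizer)
  momentum <- check_scalar(momentum, "momentum", 0)
  learning_rate <- check_scalar(learning_rate, "learning_rate", 0, strict = TRUE)
  max_epochs <- check_count(max_epochs, "max_epochs")
  patience <- check_count(patience, "patience")
  if (patience > max_epochs) {
    abort("`patience` must not exceed `max_epochs`.",
          class = "wpinjury_invalid_config")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must lie in (0, 1).",
          class = "wpinjury_invalid_config")
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 max_epochs = max_epochs, patience = patience,
                 validation_fraction = validation_fraction,
                 momentum = momentum,
                 seed = check_count(seed, "seed", min = -2147483647)),
            class = "train_settings")
}
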