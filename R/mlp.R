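#' Logistic sigmoid activation
#'
#' @param z numeric input (vectorized).
#' @return `1 / (1 + exp(-z))`.
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a sigmoid multilayer-perceptron baseline
#'
#' One hidden layer of sigmoid units and a linear output layer, with no
#' direct input-to-output connection.  Weights are drawn uniformly from a
#' small symmetric range; output biases start at the per-row target mean,
#' mirroring the WNN initialization so the two models differ only in
#' their hidden-layer activation.
#'
#' @param x training feature matrix (inputs x samples).
#' @param y training target matrix (outputs x samples).
#' @param n_hidden number of hidden sigmoid units.
#' @param seed integer seed for the random weights.
#' @param weight_range half-width of the uniform weight initialization.
#' @return an `mlp_params` object (fields `W1`, `b1`, `W2`, `b2`).
#' @export
mlp_init <- function(x, y, n_hidden = 5, seed = 1, weight_range = 0.1) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y), n_hidden >= 1)
  k <- nrow(x); j <- nrow(y)
  params <- with_seed(seed, list(
    W1 = matrix(runif(n_hidden * k, -weight_range, weight_range), n_hidden, k),
    b1 = runif(n_hidden, -weight_range, weight_range),
    W2 = matrix(runif(j * n_hidden, -weight_range, weight_range), j, n_hidden),
    b2 = rowMeans(y)
  ))
  structure(c(params, list(n_in = k, n_hidden = as.integer(n_hidden),
                           n_out = j)),
            class = "mlp_params")
}

#' Forward pass of the MLP baseline
#'
#' @param params an `mlp_params` object.
#' @param x feature matrix (inputs x samples) or a single feature vector.
#' @return prediction matrix (outputs x samples).
#' @export
mlp_forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != params$n_in) stop("input dimension mismatch")
  A <- sigmoid(params$W1 %*% x + params$b1)
  params$W2 %*% A + params$b2
}

#' @export
predict.mlp_params <- function(object, x, ...) mlp_forward(object, x)

#' Analytic gradients of the MLP cost
#'
#' @inheritParams mlp_forward
#' @param y target matrix (outputs x samples).
#' @return list of gradients with the same shapes as the parameters.
#' @export
mlp_gradients <- function(params, x, y) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- ncol(x)
  A <- sigmoid(params$W1 %*% x + params$b1)
  R <- params$W2 %*% A + params$b2 - y
  s <- 2 / n
  dA <- crossprod(params$W2, R) * A * (1 - A)   # n_hidden x samples
  list(W1 = s * (dA %*% t(x)),
       b1 = s * rowSums(dA),
       W2 = s * (R %*% t(A)),
       b2 = s * rowSums(R))
}

#' Train the MLP baseline under the same budget as the WNN
#'
#' Same cost function, full-batch gradient descent with momentum, and
#' stopping rule as [wnn_train()], so comparisons between the two models
#' are budget-matched (same hidden-layer size and epoch cap).
#'
#' @param x training features (inputs x samples).
#' @param y training targets (outputs x samples).
#' @param config a [training_config()].
#' @return list with the trained `params`, per-epoch cost `trace`, and
#'   `stop_reason`.
#' @export
mlp_baseline <- function(x, y, config = training_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  params <- mlp_init(x, y, n_hidden = config$n_hidden, seed = config$seed)
  fields <- c("W1", "b1", "W2", "b2")
  fit <- .gd_momentum(
    params, fields,
    grad_fn = function(p) mlp_gradients(p, x, y),
    cost_fn = function(p) wnn_cost(y, mlp_forward(p, x)),
    config = config
  )
  class(fit$params) <- "mlp_params"
  fit$params[c("n_in", "n_hidden", "n_out")] <-
    params[c("n_in", "n_hidden", "n_out")]
  fit
}
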