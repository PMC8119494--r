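#' Mexican-hat mother wavelet
#'
#' The real-valued, symmetric Mexican-hat wavelet
#' `psi(z) = (1 - z^2) exp(-z^2 / 2)` (negative second derivative of a
#' Gaussian): unit value at 0, zero crossings at +/- 1, and zero mean.
#'
#' @param z numeric input (unitless, vectorized).
#' @return wavelet values, same shape as `z`.
#' @export
mexican_hat <- function(z) (1 - z^2) * exp(-z^2 / 2)

#' First derivative of the Mexican-hat wavelet
#'
#' `psi'(z) = z (z^2 - 3) exp(-z^2 / 2)`, used in backpropagation through
#' the wavelon product.
#'
#' @inheritParams mexican_hat
#' @return derivative values.
#' @export
mexican_hat_deriv <- function(z) z * (z^2 - 3) * exp(-z^2 / 2)

#' Translated and dilated wavelon input
#'
#' @param x input value(s).
#' @param xi translation parameter.
#' @param sigma dilation parameter (non-zero).
#' @return `(x - xi) / sigma`.
#' @export
wavelon_input <- function(x, xi, sigma) {
  if (any(sigma == 0)) stop("dilation must be non-zero")
  (x - xi) / sigma
}

#' Multidimensional wavelon activation
#'
#' A wavelon's activation for one input vector is the product over all
#' input dimensions of the Mexican-hat wavelet applied to the translated,
#' dilated inputs.
#'
#' @param x input feature vector.
#' @param xi translations, one per input.
#' @param sigma dilations, one per input (non-zero).
#' @return scalar activation.
#' @export
wavelon_activation <- function(x, xi, sigma) {
  stopifnot(length(x) == length(xi), length(x) == length(sigma))
  prod(mexican_hat(wavelon_input(x, xi, sigma)))
}

#' Training configuration for the gradient-descent-with-momentum loop
#'
#' @param E_max maximum number of training epochs (default 50).
#' @param L_min cost floor at which training stops (default 1e-5).
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param momentum momentum coefficient in `[0, 1)` (default 0.9).
#' @param seed integer seed for weight initialization.
#' @param n_hidden number of hidden-layer nodes (default 5).
#' @return a `training_config` list.
#' @export
training_config <- function(E_max = 50, L_min = 1e-5, learning_rate = 0.01,
                            momentum = 0.9, seed = 1, n_hidden = 5) {
  stopifnot(E_max >= 1, L_min > 0, learning_rate > 0,
            momentum >= 0, momentum < 1, n_hidden >= 1)
  structure(list(E_max = as.integer(E_max), L_min = L_min,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed), n_hidden = as.integer(n_hidden)),
            class = "training_config")
}

#' Heuristic initialization of WNN parameters
#'
#' Translations are set to the midpoint of each input's training-sample
#' range and dilations proportionally to that range (capped at 1 and
#' floored at `dilation_floor`), so every training input falls inside the
#' active support of its wavelons.  Direct and hidden-to-output weights
#' are drawn uniformly from a small symmetric range; output biases are
#' initialized to the per-row mean of the targets.
#'
#' @param x training feature matrix (inputs x samples).
#' @param y training target matrix (outputs x samples).
#' @param n_hidden number of wavelons.
#' @param seed integer seed for the random weights.
#' @param weight_range half-width of the uniform weight initialization.
#' @param dilation_scale multiple of the input range used as dilation
#'   (default 0.5, placing the range within the wavelet's `[-2, 2]` core).
#' @param dilation_floor lower bound protecting constant input rows.
#' @return a `wnn_params` object (fields `w_direct`, `w_hidden`, `xi`,
#'   `sigma`, `b`).
#' @export
wnn_init <- function(x, y, n_hidden = 5, seed = 1, weight_range = 0.1,
                     dilation_scale = 0.5, dilation_floor = 1e-3) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y), ncol(x) >= 1, n_hidden >= 1)
  k <- nrow(x); j <- nrow(y)
  M <- apply(x, 1, max)
  N <- apply(x, 1, min)
  if (any(M == N))
    warning("constant input row(s); dilation floored at `dilation_floor`")
  sig <- pmin(pmax(dilation_scale * (M - N), dilation_floor), 1)
  params <- with_seed(seed, list(
    w_direct = matrix(runif(k * j, -weight_range, weight_range), k, j),
    w_hidden = matrix(runif(n_hidden * j, -weight_range, weight_range),
                      n_hidden, j),
    xi = matrix(0.5 * (N + M), k, n_hidden),
    sigma = matrix(sig, k, n_hidden),
    b = rowMeans(y)
  ))
  structure(c(params, list(n_in = k, n_hidden = as.integer(n_hidden),
                           n_out = j)),
            class = "wnn_params")
}

# hidden-layer activation matrix (n_hidden x n) for a batch x (k x n)
.wnn_hidden <- function(params, x) {
  n <- ncol(x)
  H <- matrix(0, params$n_hidden, n)
  for (i in seq_len(params$n_hidden)) {
    P <- mexican_hat((x - params$xi[, i]) / params$sigma[, i])
    acc <- rep(1, n)
    for (r in seq_len(nrow(P))) acc <- acc * P[r, ]
    H[i, ] <- acc
  }
  H
}

#' Forward pass of the wavelet neural network
#'
#' Each output is the weighted sum of the wavelon activations plus a
#' direct linear term on the inputs plus a bias:
#' `yhat_j = sum_i psi_i(x) w_ij + sum_k x_k w_kj + b_j`.
#'
#' @param params a `wnn_params` object.
#' @param x feature matrix (inputs x samples) or a single feature vector.
#' @return prediction matrix (outputs x samples).
#' @export
wnn_forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != params$n_in) stop("input dimension mismatch")
  H <- .wnn_hidden(params, x)
  crossprod(params$w_hidden, H) + crossprod(params$w_direct, x) + params$b
}

#' @export
predict.wnn_params <- function(object, x, ...) wnn_forward(object, x)

#' Training cost (mean per-sample sum of squared errors)
#'
#' `L = (1/n) * sum_p ||y_p - yhat_p||^2`: squared errors summed over
#' output coordinates within a sample, averaged over samples.
#'
#' @param y target matrix (outputs x samples).
#' @param y_hat prediction matrix, same shape.
#' @return scalar cost.
#' @export
wnn_cost <- function(y, y_hat) {
  if (!all(dim(y) == dim(y_hat))) stop("shape mismatch between y and y_hat")
  sum((y - y_hat)^2) / ncol(y)
}

# column-wise product over all rows except one: E[r, c] = prod(P[-r, c])
.prod_except_self <- function(P) {
  k <- nrow(P)
  if (k == 1) return(matrix(1, 1, ncol(P)))
  down <- apply(P, 2, cumprod)                     # prefix products
  up <- apply(P[k:1, , drop = FALSE], 2, cumprod)[k:1, , drop = FALSE]
  E <- matrix(1, k, ncol(P))
  E[1, ] <- up[2, ]
  E[k, ] <- down[k - 1, ]
  if (k > 2) for (r in 2:(k - 1)) E[r, ] <- down[r - 1, ] * up[r + 1, ]
  E
}

#' Analytic gradients of the WNN cost
#'
#' Exact gradients of the training cost with respect to every parameter
#' (direct weights, hidden weights, biases, and the wavelon translations
#' and dilations through the activation product).
#'
#' @param params a `wnn_params` object.
#' @param x feature matrix (inputs x samples).
#' @param y target matrix (outputs x samples).
#' @return list of gradients with the same shapes as the parameters.
#' @export
wnn_gradients <- function(params, x, y) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- ncol(x)
  H <- .wnn_hidden(params, x)
  y_hat <- crossprod(params$w_hidden, H) + crossprod(params$w_direct, x) +
    params$b
  R <- y_hat - y                 # outputs x samples
  s <- 2 / n
  dH <- params$w_hidden %*% R * s   # n_hidden x samples
  g_xi <- matrix(0, params$n_in, params$n_hidden)
  g_sigma <- matrix(0, params$n_in, params$n_hidden)
  for (i in seq_len(params$n_hidden)) {
    Z <- (x - params$xi[, i]) / params$sigma[, i]
    P <- mexican_hat(Z)
    G <- mexican_hat_deriv(Z) * .prod_except_self(P)  # dH_i/dZ, k x n
    W <- G * matrix(dH[i, ], params$n_in, n, byrow = TRUE)
    g_xi[, i] <- -rowSums(W) / params$sigma[, i]
    g_sigma[, i] <- -rowSums(W * Z) / params$sigma[, i]
  }
  list(w_direct = s * (x %*% t(R)),
       w_hidden = s * (H %*% t(R)),
       xi = g_xi,
       sigma = g_sigma,
       b = s * rowSums(R))
}

# shared full-batch gradient-descent-with-momentum loop; `fields` names
# the trainable arrays inside `params`
.gd_momentum <- function(params, fields, grad_fn, cost_fn, config) {
  vel <- lapply(params[fields], function(p) p * 0)
  trace <- numeric(0)
  stop_reason <- "epoch_cap"
  for (E in seq_len(config$E_max)) {
    L <- cost_fn(params)
    trace[E] <- L
    if (!is.finite(L)) {
      cond <- simpleError("training diverged: non-finite cost")
      cond$trace <- trace
      stop(cond)
    }
    if (L <= config$L_min) {
      stop_reason <- "cost_floor"
      break
    }
    g <- grad_fn(params)
    for (f in fields) {
      vel[[f]] <- config$momentum * vel[[f]] - config$learning_rate * g[[f]]
      params[[f]] <- params[[f]] + vel[[f]]
    }
  }
  list(params = params,
       trace = data.frame(epoch = seq_along(trace), cost = trace),
       stop_reason = stop_reason)
}

#' Train a WNN by gradient descent with momentum
#'
#' Full-batch training: each epoch computes the analytic gradient over
#' all training samples and applies a momentum update
#' (`v <- momentum * v - lr * grad; param <- param + v`).  Training stops
#' when the cost reaches `L_min` or after `E_max` epochs.
#'
#' @param params initial `wnn_params`, typically from [wnn_init()].
#' @param x training features (22 x n).
#' @param y training targets (66 x n).
#' @param config a [training_config()].
#' @return list with the trained `params`, a per-epoch cost `trace`, and
#'   the `stop_reason` (`"cost_floor"` or `"epoch_cap"`).
#' @export
wnn_train <- function(params, x, y, config = training_config()) {
  fields <- c("w_direct", "w_hidden", "xi", "sigma", "b")
  fit <- .gd_momentum(
    params, fields,
    grad_fn = function(p) wnn_gradients(p, x, y),
    cost_fn = function(p) wnn_cost(y, wnn_forward(p, x)),
    config = config
  )
  class(fit$params) <- "wnn_params"
  fit$params[c("n_in", "n_hidden", "n_out")] <-
    params[c("n_in", "n_hidden", "n_out")]
  fit
}

#' Prediction risk on held-out samples
#'
#' Mean per-sample sum of squared errors of a fitted model on a test set
#' — the quantity minimized when selecting the hidden-layer size.
#'
#' @param model a fitted `wnn_params` or `mlp_params` object.
#' @param x_test,y_test held-out features and targets.
#' @return scalar prediction risk.
#' @export
prediction_risk <- function(model, x_test, y_test) {
  if (is.null(dim(x_test)) || ncol(as.matrix(x_test)) == 0)
    stop("test set must be nonempty")
  wnn_cost(as.matrix(y_test), predict(model, as.matrix(x_test)))
}

#' Select the hidden-layer size by minimum prediction risk
#'
#' Trains one network per candidate size on a fixed 70/30 split of the
#' provided data (deterministic per seed) and returns the candidate with
#' the smallest prediction risk on the held-out part; ties break toward
#' fewer nodes.
#'
#' @param x feature matrix (inputs x samples).
#' @param y target matrix (outputs x samples).
#' @param candidates integer vector of hidden-node counts to try.
#' @param config a [training_config()]; its seed fixes both the split
#'   and the per-candidate initialization.
#' @return list with the chosen `n_hidden` and the `risk` per candidate.
#' @export
select_hidden_nodes <- function(x, y, candidates,
                                config = training_config()) {
  if (length(candidates) == 0) stop("`candidates` must be nonempty")
  n <- ncol(x)
  split <- with_seed(config$seed, sample(n))
  n_train <- round(0.7 * n)
  tr <- split[seq_len(n_train)]
  te <- split[-seq_len(n_train)]
  risk <- vapply(candidates, function(h) {
    p0 <- wnn_init(x[, tr, drop = FALSE], y[, tr, drop = FALSE],
                   n_hidden = h, seed = config$seed + h)
    fit <- wnn_train(p0, x[, tr, drop = FALSE], y[, tr, drop = FALSE], config)
    prediction_risk(fit$params, x[, te, drop = FALSE], y[, te, drop = FALSE])
  }, numeric(1))
  ord <- order(risk, candidates)
  list(n_hidden = candidates[ord[1]],
       risk = stats::setNames(risk, candidates))
}
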