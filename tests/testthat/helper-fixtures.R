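# shared fixtures built in code

# one normalized default cycle (noiseless, unfiltered) plus its schedule
default_cycle <- function(seed = 2) {
  cohort <- generate_cohort(1, 1, seed = seed, noise_sd = 0)
  preprocess_cohort(cohort, filter = FALSE)[[1]]
}

# a synthetic gait_cycle with fully controlled channels and events
manual_cycle <- function(f = NULL, f_prime = NULL, theta = NULL,
                         events = c(t_IC = 0, t_ITO = 60, t_NTO = 60,
                                    t_NIC = 100)) {
  grid <- 0:100
  if (is.null(f)) f <- vgrf_waveform(pmin(grid, 100))
  if (is.null(f_prime)) f_prime <- vgrf_waveform((grid + 50) %% 100)
  if (is.null(theta)) theta <- list(a = sin(grid / 16), k = cos(grid / 21),
                                    h = grid / 50)
  structure(list(phase = grid, f = f, f_prime = f_prime,
                 theta_a = theta$a, theta_k = theta$k, theta_h = theta$h,
                 events = events, mode = "IC_to_NIC",
                 subject_id = 1L, trial_id = 1L),
            class = "gait_cycle")
}

# a small random teacher WNN for oracle and recovery tests
random_wnn <- function(seed, n_in = 3, n_hidden = 2, n_out = 2,
                       weight_scale = 0.5) {
  p <- with_seed(seed, list(
    w_direct = matrix(runif(n_in * n_out, -weight_scale, weight_scale),
                      n_in, n_out),
    w_hidden = matrix(runif(n_hidden * n_out, -1, 1), n_hidden, n_out),
    xi = matrix(runif(n_in * n_hidden, -0.5, 0.5), n_in, n_hidden),
    sigma = matrix(runif(n_in * n_hidden, 0.5, 1.5), n_in, n_hidden),
    b = rnorm(n_out, 0, 0.5),
    n_in = n_in, n_hidden = as.integer(n_hidden), n_out = n_out))
  class(p) <- "wnn_params"
  p
}

# brute-force triple-loop forward pass, kept independent of wnn_forward
naive_forward <- function(p, x) {
  n <- ncol(x)
  out <- matrix(0, p$n_out, n)
  for (s in seq_len(n)) {
    for (j in seq_len(p$n_out)) {
      acc <- p$b[j]
      for (i in seq_len(p$n_hidden)) {
        prod_k <- 1
        for (k in seq_len(p$n_in)) {
          z <- (x[k, s] - p$xi[k, i]) / p$sigma[k, i]
          prod_k <- prod_k * (1 - z^2) * exp(-z^2 / 2)
        }
        acc <- acc + prod_k * p$w_hidden[i, j]
      }
      for (k in seq_len(p$n_in)) acc <- acc + x[k, s] * p$w_direct[k, j]
      out[j, s] <- acc
    }
  }
  out
}

# central finite-difference gradient for one parameter field
numeric_gradient <- function(params, x, y, field, h = 1e-6) {
  arr <- params[[field]]
  out <- arr
  for (i in seq_along(arr)) {
    pp <- params; pp[[field]][i] <- arr[i] + h
    pm <- params; pm[[field]][i] <- arr[i] - h
    out[i] <- (wnn_cost(y, wnn_forward(pp, x)) -
                 wnn_cost(y, wnn_forward(pm, x))) / (2 * h)
  }
  out
}
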