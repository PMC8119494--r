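test_that("Mexican-hat wavelet identities hold", {
  expect_equal(mexican_hat(0), 1)
  expect_equal(mexican_hat(1), 0)
  expect_equal(mexican_hat(-1), 0)
  expect_equal(mexican_hat(2), -3 * exp(-2))
  z <- seq(-4, 4, by = 0.37)
  expect_equal(mexican_hat(z), mexican_hat(-z))  # even symmetry
  # zero mean: numeric integral over a wide support vanishes
  expect_lt(abs(integrate(mexican_hat, -8, 8)$value), 1e-8)
  # derivative identity psi'(z) = z (z^2 - 3) exp(-z^2/2)
  h <- 1e-6
  num <- (mexican_hat(z + h) - mexican_hat(z - h)) / (2 * h)
  expect_equal(mexican_hat_deriv(z), num, tolerance = 1e-8)
})

test_that("wavelon input and activation follow the translate-dilate-product rule", {
  expect_equal(wavelon_input(0.7, 0.7, 0.5), 0)
  expect_equal(wavelon_input(1.2, 0.7, 0.5), 1)
  expect_equal(wavelon_input(0.2, 0.7, 0.01), -50)
  expect_error(wavelon_input(1, 0, 0), "non-zero")
  # all centred inputs activate at 1; any z = +/-1 annihilates
  expect_equal(wavelon_activation(rep(2, 5), rep(2, 5), rep(1, 5)), 1)
  expect_equal(wavelon_activation(c(0, 1), c(0, 0), c(1, 1)), 0)
  # scalar power oracle for 22 equal inputs at z = 0.5
  expect_equal(wavelon_activation(rep(0.5, 22), rep(0, 22), rep(1, 22)),
               (0.75 * exp(-0.125))^22)
})

test_that("forward pass equals the naive triple-loop oracle", {
  for (seed in 1:100) {
    p <- random_wnn(seed, n_in = sample(2:5, 1), n_hidden = sample(1:4, 1),
                    n_out = sample(1:3, 1))
    x <- with_seed(seed + 1000, matrix(runif(p$n_in * 4, -1, 1), p$n_in, 4))
    expect_equal(wnn_forward(p, x), naive_forward(p, x), tolerance = 1e-12)
  }
})

test_that("degenerate weight settings reduce the forward pass to its parts", {
  p <- random_wnn(1)
  p$w_direct[] <- 0; p$w_hidden[] <- 0; p$b <- c(3, -1)
  x <- matrix(runif(6), 3, 2)
  expect_equal(wnn_forward(p, x), matrix(c(3, -1), 2, 2))  # bias passthrough
  p$w_direct[2, 1] <- 1  # single linear path input 2 -> output 1
  expect_equal(wnn_forward(p, x)[1, ], x[2, ] + 3)
})

test_that("heuristic initialization follows the input-range rule", {
  x <- rbind(seq(0.2, 1.2, length.out = 6), seq(-1, 1, length.out = 6))
  y <- matrix(5, 3, 6)
  p <- wnn_init(x, y, n_hidden = 4, seed = 1)
  expect_equal(p$xi[1, ], rep(0.7, 4))   # midpoint of [0.2, 1.2]
  expect_equal(p$xi[2, ], rep(0, 4))
  expect_equal(p$sigma[1, ], rep(0.5, 4))  # half the input range, capped at 1
  expect_equal(p$sigma[2, ], rep(1, 4))
  expect_equal(unname(p$b), rep(5, 3))   # mean of constant targets
  expect_true(all(p$sigma > 0))
  # determinism under a fixed seed
  expect_equal(p, wnn_init(x, y, n_hidden = 4, seed = 1))
  # constant input row warns and floors the dilation
  xc <- rbind(x, 0.3)
  expect_warning(pc <- wnn_init(xc, y, n_hidden = 2, seed = 1), "constant")
  expect_equal(pc$sigma[3, ], rep(1e-3, 2))
})

test_that("cost is the mean per-sample sum of squared errors", {
  y <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(wnn_cost(y, y), 0)
  expect_equal(wnn_cost(matrix(0), matrix(2)), 4)
  # two samples with per-sample squared errors 1 and 3
  expect_equal(wnn_cost(matrix(c(0, 0), 1), matrix(c(1, sqrt(3)), 1)), 2)
  expect_error(wnn_cost(y, matrix(0, 3, 2)), "shape")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:10) {
    p <- random_wnn(seed, n_in = 3, n_hidden = 2, n_out = 2)
    x <- with_seed(seed + 50, matrix(runif(3 * 6, -1, 1), 3, 6))
    y <- with_seed(seed + 90, matrix(rnorm(2 * 6), 2, 6))
    g <- wnn_gradients(p, x, y)
    for (field in c("w_direct", "w_hidden", "xi", "sigma", "b")) {
      num <- numeric_gradient(p, x, y, field)
      denom <- max(abs(num), 1e-8)
      expect_lt(max(abs(g[[field]] - num)) / denom, 1e-5)
    }
  }
  # gradient of the bias is twice the mean residual of that output
  p <- random_wnn(3)
  x <- matrix(runif(9, -1, 1), 3, 3)
  y <- wnn_forward(p, x) + 1
  g <- wnn_gradients(p, x, y)
  expect_equal(g$b, rep(-2, 2), tolerance = 1e-12)
  # at an exact fit every gradient vanishes
  g0 <- wnn_gradients(p, x, wnn_forward(p, x))
  expect_true(all(vapply(g0, function(a) max(abs(a)), 1) < 1e-14))
})

test_that("training honours the stopping rules and reduces the cost", {
  x <- with_seed(1, matrix(runif(22 * 60, -0.5, 0.5), 22, 60))
  A <- with_seed(2, matrix(rnorm(66 * 22, 0, 0.2), 66, 22))
  y <- A %*% x
  p0 <- wnn_init(x, y, n_hidden = 3, seed = 1)
  # lr = 0 cannot move the parameters
  frozen <- wnn_train(p0, x, y, training_config(learning_rate = 1e-12))
  expect_equal(frozen$params$w_direct, p0$w_direct, tolerance = 1e-9)
  expect_equal(nrow(frozen$trace), 50)
  expect_lt(diff(range(frozen$trace$cost)), 1e-6)
  expect_equal(frozen$stop_reason, "epoch_cap")
  # linear-only target: convex least squares reached within 50 epochs
  fit <- wnn_train(p0, x, y, training_config(E_max = 50, learning_rate = 0.5,
                                             momentum = 0.8))
  expect_lt(tail(fit$trace$cost, 1), fit$trace$cost[1])
  expect_lt(tail(fit$trace$cost, 1), 1e-3)
  # a cost floor above the initial cost stops at epoch one
  floor_fit <- wnn_train(p0, x, y,
                         training_config(L_min = fit$trace$cost[1] * 10))
  expect_equal(nrow(floor_fit$trace), 1)
  expect_equal(floor_fit$stop_reason, "cost_floor")
  # with momentum 0 and a small step, per-epoch cost is non-increasing
  mono <- wnn_train(p0, x, y, training_config(E_max = 30,
                                              learning_rate = 0.01,
                                              momentum = 0))
  expect_true(all(diff(mono$trace$cost) <= 1e-12))
})

test_that("prediction risk shares the cost functional on held-out data", {
  p <- random_wnn(5)
  x <- matrix(runif(12, -1, 1), 3, 4)
  y <- wnn_forward(p, x)
  expect_equal(prediction_risk(p, x, y), 0)
  # constant unit error on every coordinate of 66 outputs sums to 66
  p66 <- random_wnn(6, n_in = 3, n_hidden = 2, n_out = 66)
  y66 <- wnn_forward(p66, x)
  expect_equal(prediction_risk(p66, x, y66 + 1), 66)
  expect_equal(prediction_risk(p, x, y + 0.3), wnn_cost(y + 0.3, wnn_forward(p, x)))
})

test_that("hidden-node selection minimizes prediction risk deterministically", {
  teacher <- random_wnn(11, n_in = 3, n_hidden = 3, n_out = 2)
  x <- with_seed(12, matrix(runif(3 * 120, -1.5, 1.5), 3, 120))
  y <- wnn_forward(teacher, x) + with_seed(13, matrix(rnorm(240, 0, 0.05), 2))
  cfg <- training_config(E_max = 300, learning_rate = 0.02, seed = 7)
  expect_equal(select_hidden_nodes(x, y, 5, cfg)$n_hidden, 5)
  sel1 <- select_hidden_nodes(x, y, c(1, 3, 5), cfg)
  sel2 <- select_hidden_nodes(x, y, c(1, 3, 5), cfg)
  expect_identical(sel1, sel2)
  expect_equal(unname(sel1$risk[as.character(sel1$n_hidden)]),
               min(sel1$risk))
})

test_that("fitted parameters survive a JSON round trip exactly", {
  p <- random_wnn(21)
  f <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, f)
  p2 <- read_params_json(f)
  expect_s3_class(p2, "wnn_params")
  x <- matrix(runif(9, -1, 1), 3, 3)
  expect_equal(wnn_forward(p2, x), wnn_forward(p, x), tolerance = 1e-12)
  expect_equal(p2$sigma, p$sigma)
})
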