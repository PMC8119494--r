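test_that("split plans partition 70/30 per sequence, deterministically", {
  plans <- make_splits(300)
  expect_length(plans, 3)
  for (pl in plans) {
    expect_length(pl$train_idx, 210)
    expect_length(pl$test_idx, 90)
    expect_length(intersect(pl$train_idx, pl$test_idx), 0)
    expect_setequal(c(pl$train_idx, pl$test_idx), 1:300)
  }
  small <- make_splits(10)
  expect_length(small[[1]]$train_idx, 7)
  expect_length(small[[1]]$test_idx, 3)
  expect_identical(make_splits(300), plans)
  expect_error(make_splits(5), "at least 10")
})

test_that("spline reconstruction passes knots and recovers cubics", {
  sched <- build_event_schedule(manual_cycle())
  const <- reconstruct_profile(rep(10, 22), sched)
  expect_equal(const, rep(10, 101))
  cubic <- function(t) 0.001 * t^3 - 0.05 * t^2 + t + 2
  prof <- reconstruct_profile(cubic(sched$t), sched)
  expect_equal(prof, cubic(0:100), tolerance = 1e-9)
  vals <- sin(sched$t / 9)
  prof2 <- reconstruct_profile(vals, sched)
  expect_equal(prof2[sched$t + 1], vals)  # interpolation at every knot
  bad <- sched; bad$t[2] <- bad$t[1]
  expect_error(reconstruct_profile(vals, bad), "duplicate")
})

test_that("profile scoring computes RMSE, range-NRMSE and correlation", {
  truth <- seq(0, 50, length.out = 101)
  expect_equal(unname(score_profiles(truth, truth)), c(0, 0, 1))
  sc <- score_profiles(truth + 1, truth)
  expect_equal(unname(sc), c(1, 2, 1))
  zt <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(score_profiles(-zt, zt)[["rho"]], -1)
  expect_error(score_profiles(truth, rep(3, 101)), "constant")
  expect_true(is.na(score_profiles(rep(3, 101), truth)[["rho"]]))
})

test_that("scores are invariant to sample ordering within a split", {
  co <- generate_cohort(4, 3, seed = 21, noise_sd = 0)
  cycles <- preprocess_cohort(co, filter = FALSE)
  gi <- suppressWarnings(gi_transform(cycles))
  p <- suppressWarnings(wnn_init(gi$x, gi$y, n_hidden = 3, seed = 1))
  y_hat <- predict(p, gi$x)
  sc <- gaitWNN:::.score_all_samples(y_hat, cycles, gi$schedules)
  perm <- rev(seq_along(cycles))
  sc_perm <- gaitWNN:::.score_all_samples(y_hat[, perm], cycles[perm],
                                          gi$schedules[perm])
  a <- sc[order(sc$sample, sc$joint), c("rmse", "nrmse", "rho")]
  b <- sc_perm
  b$sample <- perm[b$sample]
  b <- b[order(b$sample, b$joint), c("rmse", "nrmse", "rho")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("reconstruction of ground-truth samples sets a small noise floor", {
  # bypass the network: spline through the true angle samples alone
  cyc <- default_cycle()
  sched <- build_event_schedule(cyc)
  targs <- extract_targets(cyc, sched)
  for (jn in 1:3) {
    truth <- cyc[[c("theta_a", "theta_k", "theta_h")[jn]]]
    est <- reconstruct_profile(targs[(jn - 1) * 22 + 1:22], sched)
    expect_lt(sqrt(mean((est - truth)^2)), 0.75)
  }
})

test_that("the experiment report selects the least-RMSE sequence and scopes", {
  co <- generate_cohort(6, 3, seed = 31, noise_sd = 0)
  rep <- suppressWarnings(
    run_experiment(co, training_config(E_max = 25, n_hidden = 3, seed = 5),
                   include_mlp = TRUE, filter = FALSE))
  expect_s3_class(rep, "gait_eval_report")
  expect_setequal(unique(rep$summary$model), c("wnn", "mlp"))
  expect_setequal(unique(rep$summary$scope), c("all", "in_sample", "out_sample"))
  for (model in c("wnn", "mlp")) {
    sub <- rep$summary[rep$summary$model == model & rep$summary$scope == "all", ]
    means <- tapply(sub$rmse_mean, sub$sequence, mean)
    expect_equal(unname(rep$chosen_sequence[[model]]),
                 as.integer(names(means)[which.min(means)]))
  }
  expect_true(all(rep$summary$rmse_mean >= 0))
  expect_true(all(abs(rep$summary$rho_mean) <= 1 + 1e-12))
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  payload <- jsonlite::read_json(f)
  expect_equal(length(payload$summary), nrow(rep$summary))
})
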