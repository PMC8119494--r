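test_that("primary event resolution mixes measured and predefined indexes", {
  cyc <- manual_cycle()
  main <- resolve_main_events(cyc)
  expect_equal(nrow(main), 9)
  # shared toe-off split into pre/post events around the measured instant
  expect_setequal(main$t, c(0, 10, 30, 50, 59, 61, 73, 87, 100))
  expect_error(resolve_main_events(cyc, c(OTO = 10, HR = 30, OIC = 50)),
               "FA")
})

test_that("common-event splitting shifts one percent each way", {
  expect_equal(unname(split_common_event(60)), c(59, 61))
  expect_equal(unname(split_common_event(50)), c(49, 51))
  expect_error(split_common_event(100), "boundary")
  expect_error(split_common_event(0), "boundary")
})

test_that("intermediate step sizes and indexes follow the interval rule", {
  expect_equal(intermediate_step_size(10, 30, 2), 20 / 3)
  expect_equal(intermediate_step_size(0, 10, 1), 5)
  expect_error(intermediate_step_size(30, 30, 2), "width")
  # nearest-integer snapping with round-half-up ties
  expect_equal(resolve_intermediate_events(10, 30, 2), c(17, 23))
  expect_equal(resolve_intermediate_events(73, 87, 3), c(77, 80, 84))
  expect_equal(resolve_intermediate_events(0, 10, 1), 5)
})

test_that("the full schedule has 22 unique increasing events, 9 main + 13 intermediate", {
  sched <- build_event_schedule(manual_cycle())
  expect_equal(nrow(sched), 22)
  expect_equal(sum(sched$kind == "main"), 9)
  expect_equal(sum(sched$kind == "intermediate"), 13)
  expect_true(all(diff(sched$t) > 0))
  expect_false(anyDuplicated(sched$t) > 0)
  expect_equal(sched$m, 1:22)
  expect_equal(sched$leg, rep(c("stance", "swing"), c(11, 11)))
  # primary events sit in their reserved feature slots
  expect_equal(sched$m[sched$kind == "main"], c(1, 3, 6, 9, 11, 12, 15, 19, 22))
  # default geometry reproduces the reference schedule
  expect_equal(sched$t, c(0, 5, 10, 17, 23, 30, 37, 43, 50, 55, 59,
                          61, 65, 69, 73, 77, 80, 84, 87, 91, 96, 100))
})

test_that("schedules stay valid over randomized measured event positions", {
  for (seed in 1:25) {
    ev <- with_seed(seed, {
      toe <- runif(1, 56, 64)
      c(t_IC = 0, t_ITO = toe, t_NTO = toe, t_NIC = 100)
    })
    sched <- build_event_schedule(manual_cycle(events = ev))
    expect_equal(nrow(sched), 22)
    expect_true(all(diff(sched$t) > 0))
    expect_true(all(sched$t >= 0 & sched$t <= 100))
  }
})

test_that("duplicate indexes are shifted +1 until unique", {
  sched <- build_event_schedule(manual_cycle())
  dup <- sched
  dup$t[4] <- dup$t[5]  # manufacture a collision
  fixed <- dedupe_indexes(dup)
  expect_false(anyDuplicated(fixed$t) > 0)
  expect_true(all(diff(fixed$t) > 0))
  # untouched schedule passes through unchanged
  expect_identical(dedupe_indexes(sched), sched)
  # stepping the rule by hand on a toy triple (45, 45, 46): the second
  # entry moves to 46, colliding with the third, which then moves to 47
  toy <- data.frame(m = 1:3, t = c(45L, 45L, 46L))
  expect_equal(dedupe_indexes(toy)$t, c(45, 46, 47))
})

test_that("feature extraction reads stance from f and negated swing from f'", {
  cyc <- manual_cycle()
  sched <- build_event_schedule(cyc)
  feats <- extract_features(cyc, sched)
  expect_length(feats, 22)
  # brute-force indexing oracle
  expect_equal(unname(feats[1:11]), cyc$f[sched$t[1:11] + 1])
  expect_equal(unname(feats[12:22]), -cyc$f_prime[sched$t[12:22] + 1])
  # swing-block features are strictly negative when f' is positive there
  expect_true(all(feats[12:22] < 0))
  # all-zero channels give a zero feature vector
  z <- manual_cycle(f = rep(0, 101), f_prime = rep(0, 101))
  expect_equal(unname(extract_features(z, sched)), rep(0, 22))
})

test_that("target extraction concatenates ankle, knee, hip blocks", {
  cyc <- manual_cycle()
  sched <- build_event_schedule(cyc)
  targs <- extract_targets(cyc, sched)
  expect_length(targs, 66)
  expect_equal(unname(targs[23:44]), cyc$theta_k[sched$t + 1])
  const <- manual_cycle(theta = list(a = rep(1, 101), k = rep(2, 101),
                                     h = rep(3, 101)))
  expect_equal(unname(extract_targets(const, sched)),
               rep(c(1, 2, 3), each = 22))
})

test_that("matrix assembly preserves sample count and rejects ragged input", {
  cyc <- manual_cycle()
  sched <- build_event_schedule(cyc)
  f <- extract_features(cyc, sched)
  y <- extract_targets(cyc, sched)
  m1 <- assemble_matrices(list(f), list(y))
  expect_equal(dim(m1$x), c(22, 1))
  expect_equal(dim(m1$y), c(66, 1))
  m3 <- assemble_matrices(rep(list(f), 3), rep(list(y), 3))
  expect_equal(dim(m3$x), c(22, 3))
  expect_error(assemble_matrices(list(), list()), "no samples")
  expect_error(assemble_matrices(list(f[1:10]), list(y)), "22")
})

test_that("gi round trip through CSV/JSON is exact", {
  co <- generate_cohort(2, 2, seed = 5)
  gi <- gi_transform(preprocess_cohort(co, filter = FALSE))
  d <- withr::local_tempdir()
  write_gi(gi, d)
  gi2 <- read_gi(d)
  expect_equal(unname(gi$x), unname(gi2$x))
  expect_equal(unname(gi$y), unname(gi2$y))
  expect_equal(gi$schedules[[3]]$t, gi2$schedules[[3]]$t)
  expect_equal(gi$schedules[[3]]$label, gi2$schedules[[3]]$label)
})
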