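#' Build the three random train/test split sequences
#'
#' Shuffles the sample indexes independently for each sequence and
#' partitions them 70/30 (training size `round(0.7 * n)`), as in the
#' repeatability protocol: the network is trained and tested on three
#' independently drawn sample groupings.
#'
#' @param n number of samples (>= 10).
#' @param seeds integer seed per sequence (length gives the number of
#'   sequences; default 3).
#' @return list of split plans, each with `sequence_id`, `train_idx`,
#'   `test_idx` and `seed`.
#' @export
make_splits <- function(n, seeds = c(101, 202, 303)) {
  if (n < 10) stop("need at least 10 samples to split 70/30")
  n_train <- round(0.7 * n)
  lapply(seq_along(seeds), function(s) {
    perm <- with_seed(seeds[s], sample(n))
    list(sequence_id = s,
         train_idx = sort(perm[seq_len(n_train)]),
         test_idx = sort(perm[-seq_len(n_train)]),
         seed = seeds[s])
  })
}

#' Reconstruct a full angle profile from its 22 event samples
#'
#' Fits a cubic spline through the (event index, angle) knots and
#' evaluates it on the 101-point phase grid.  The spline passes through
#' every knot exactly.
#'
#' @param values 22 angle values (degrees), one per scheduled event.
#' @param schedule the `gi_schedule` giving the knot abscissae.
#' @return numeric profile of length 101 (phases 0..100%).
#' @export
reconstruct_profile <- function(values, schedule) {
  t <- schedule$t
  if (length(values) != length(t)) stop("values/schedule length mismatch")
  if (anyDuplicated(t)) stop("duplicate knot abscissae in schedule")
  stats::spline(t, values, xout = 0:100, method = "fmm")$y
}

#' Score an estimated profile against ground truth
#'
#' @param est estimated profile (degrees).
#' @param truth ground-truth profile, same length.
#' @return named vector: `rmse` (degrees), `nrmse` (% of the truth
#'   range), and `rho` (Pearson correlation; `NA` if the estimate is
#'   constant).  Errors if the truth is constant (NRMSE undefined).
#' @export
score_profiles <- function(est, truth) {
  if (length(est) != length(truth)) stop("profiles differ in length")
  rng <- max(truth) - min(truth)
  if (rng == 0) stop("constant ground truth: NRMSE undefined")
  rmse <- sqrt(mean((est - truth)^2))
  rho <- if (stats::sd(est) == 0) NA_real_ else stats::cor(est, truth)
  c(rmse = rmse, nrmse = rmse / rng * 100, rho = rho)
}

# score one model's predictions for every sample of a cohort;
# returns a long data frame: sample, joint, rmse, nrmse, rho
.score_all_samples <- function(y_hat, cycles, schedules) {
  joints <- c(ankle = "theta_a", knee = "theta_k", hip = "theta_h")
  out <- vector("list", length(cycles) * 3)
  k <- 1L
  for (p in seq_along(cycles)) {
    for (jn in seq_along(joints)) {
      rows <- (jn - 1) * 22 + 1:22
      est <- reconstruct_profile(y_hat[rows, p], schedules[[p]])
      truth <- cycles[[p]][[joints[jn]]]
      sc <- score_profiles(est, truth)
      out[[k]] <- data.frame(sample = p, joint = names(joints)[jn],
                             rmse = sc[["rmse"]], nrmse = sc[["nrmse"]],
                             rho = sc[["rho"]])
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

.aggregate_scores <- function(scores, train_idx, test_idx) {
  scope_map <- rep(NA_character_, max(scores$sample))
  scope_map[train_idx] <- "in_sample"
  scope_map[test_idx] <- "out_sample"
  scores$scope <- scope_map[scores$sample]
  agg <- function(sub) {
    data.frame(rmse_mean = mean(sub$rmse), rmse_sd = stats::sd(sub$rmse),
               nrmse_mean = mean(sub$nrmse), nrmse_sd = stats::sd(sub$nrmse),
               rho_mean = mean(sub$rho, na.rm = TRUE))
  }
  res <- list()
  for (scope in c("all", "in_sample", "out_sample")) {
    sub_scope <- if (scope == "all") scores else scores[scores$scope == scope, ]
    for (joint in c("ankle", "knee", "hip")) {
      sub <- sub_scope[sub_scope$joint == joint, ]
      res[[length(res) + 1L]] <- cbind(data.frame(scope = scope,
                                                  joint = joint), agg(sub))
    }
  }
  do.call(rbind, res)
}

# fit one model on one split and score all samples of the cohort
.fit_sequence <- function(gi, cycles, plan, config, model) {
  x_tr <- gi$x[, plan$train_idx, drop = FALSE]
  y_tr <- gi$y[, plan$train_idx, drop = FALSE]
  seq_config <- config
  seq_config$seed <- config$seed + plan$sequence_id
  fit <- if (model == "wnn") {
    p0 <- wnn_init(x_tr, y_tr, n_hidden = seq_config$n_hidden,
                   seed = seq_config$seed)
    wnn_train(p0, x_tr, y_tr, seq_config)
  } else {
    mlp_baseline(x_tr, y_tr, seq_config)
  }
  y_hat <- predict(fit$params, gi$x)
  scores <- .score_all_samples(y_hat, cycles, gi$schedules)
  summary <- .aggregate_scores(scores, plan$train_idx, plan$test_idx)
  summary <- cbind(data.frame(model = model,
                              sequence = plan$sequence_id), summary)
  list(summary = summary, fit = fit, scores = scores)
}

#' Run the full estimation experiment on a cohort
#'
#' Preprocesses the cohort, applies gait-intervals feature selection,
#' then for each of the three split sequences trains the WNN (and
#' optionally the MLP baseline) on the training samples, predicts all
#' samples, reconstructs per-joint angle profiles by spline
#' interpolation, and scores them against the measured ground-truth
#' profiles.  Accuracies are aggregated as mean +/- SD per joint over
#' all samples, in-sample (training) and out-sample (held-out) scopes;
#' the sequence with the least mean RMSE is selected per model.
#'
#' @param cohort a `gait_cohort` (or list of `gait_trial`s).
#' @param config a [training_config()].
#' @param split_seeds integer seeds for the split sequences.
#' @param include_mlp also train the budget-matched MLP baseline.
#' @param predefined pre-defined primary event map.
#' @param filter low-pass filter the raw trials before normalization.
#' @return a `gait_eval_report`: `summary` (long data frame of mean/SD
#'   accuracies per model, sequence, scope and joint), `chosen_sequence`
#'   per model, per-fit `traces`, and the split plans.
#' @export
run_experiment <- function(cohort, config = training_config(),
                           split_seeds = c(101, 202, 303),
                           include_mlp = TRUE,
                           predefined = default_predefined_events(),
                           filter = TRUE) {
  cycles <- preprocess_cohort(cohort, filter = filter)
  gi <- gi_transform(cycles, predefined = predefined)
  plans <- make_splits(ncol(gi$x), seeds = split_seeds)
  models <- if (include_mlp) c("wnn", "mlp") else "wnn"
  fits <- list()
  summaries <- list()
  for (model in models) {
    for (plan in plans) {
      res <- tryCatch(
        .fit_sequence(gi, cycles, plan, config, model),
        error = function(e) stop(sprintf("sequence %d (%s): %s",
                                         plan$sequence_id, model,
                                         conditionMessage(e)), call. = FALSE)
      )
      key <- sprintf("%s_seq%d", model, plan$sequence_id)
      fits[[key]] <- res$fit
      summaries[[key]] <- res$summary
    }
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  chosen <- vapply(models, function(model) {
    sub <- summary[summary$model == model & summary$scope == "all", ]
    means <- tapply(sub$rmse_mean, sub$sequence, mean)
    as.integer(names(means)[which.min(means)])
  }, integer(1))
  structure(list(summary = summary,
                 chosen_sequence = chosen,
                 traces = lapply(fits, `[[`, "trace"),
                 stop_reasons = vapply(fits, `[[`, "", "stop_reason"),
                 plans = plans,
                 config = config),
            class = "gait_eval_report")
}

#' @export
print.gait_eval_report <- function(x, ...) {
  cat("Joint-angle estimation report\n")
  for (model in unique(x$summary$model)) {
    seq_id <- x$chosen_sequence[[model]]
    cat(sprintf("\n%s (chosen sequence %d, least mean RMSE):\n",
                toupper(model), seq_id))
    sub <- x$summary[x$summary$model == model & x$summary$sequence == seq_id, ]
    for (scope in c("all", "in_sample", "out_sample")) {
      ss <- sub[sub$scope == scope, ]
      cat(sprintf("  %-10s %s\n", scope, paste(sprintf(
        "%s %.2f+/-%.2f deg (NRMSE %.1f%%, rho %.3f)", ss$joint,
        ss$rmse_mean, ss$rmse_sd, ss$nrmse_mean, ss$rho_mean),
        collapse = "; ")))
    }
  }
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' @param report a `gait_eval_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    schema_version = "1.0",
    chosen_sequence = as.list(report$chosen_sequence),
    summary = report$summary,
    stop_reasons = as.list(report$stop_reasons)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
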