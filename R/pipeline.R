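#' Derive a stage seed from the master seed
#'
#' One master seed fans out to fixed-offset sub-seeds for the generator,
#' training initialization and the three split sequences, so each
#' pipeline stage is independently reproducible.  All derived seeds stay
#' below 2^31.
#'
#' @param master integer master seed.
#' @param stage one of `"generator"`, `"training"`, `"split1"`,
#'   `"split2"`, `"split3"`.
#' @return the derived seed (numeric).
#' @export
derive_seed <- function(master, stage) {
  offsets <- c(generator = 0L, training = 17L, split1 = 101L,
               split2 = 202L, split3 = 303L)
  if (!stage %in% names(offsets)) stop("unknown pipeline stage")
  (as.numeric(master) + offsets[[stage]]) %% 2147483647

}

#' Simulate a cohort and write it to disk
#'
#' @param out_dir output directory.
#' @param n_subjects,trials_per_subject cohort size (default 30 x 10,
#'   i.e. 300 gait samples).
#' @param seed master seed.
#' @param noise_sd vGRF noise level in body-weight units.
#' @return the cohort, invisibly.
#' @export
cmd_simulate <- function(out_dir, n_subjects = 30, trials_per_subject = 10,
                         seed = 1, noise_sd = 0.02) {
  cohort <- generate_cohort(n_subjects, trials_per_subject,
                            seed = derive_seed(seed, "generator"),
                            noise_sd = noise_sd)
  write_cohort(cohort, out_dir)
  message(sprintf("wrote %d trials to %s", length(cohort), out_dir))
  invisible(cohort)
}

#' Extract gait-interval features from a cohort on disk
#'
#' @param cohort_dir directory written by [cmd_simulate()].
#' @param out_dir output directory for the matrices and schedules.
#' @param mode cycle partition convention.
#' @return the GI result, invisibly.
#' @export
cmd_features <- function(cohort_dir, out_dir, mode = "IC_to_NIC") {
  cohort <- read_cohort(cohort_dir)
  cycles <- preprocess_cohort(cohort, mode = mode)
  gi <- gi_transform(cycles)
  write_gi(gi, out_dir)
  message(sprintf("wrote %d x %d features and %d x %d targets to %s",
                  nrow(gi$x), ncol(gi$x), nrow(gi$y), ncol(gi$y), out_dir))
  invisible(gi)
}

#' Train a network on GI matrices on disk
#'
#' @param gi_dir directory written by [cmd_features()].
#' @param out_path output JSON path for the fitted parameters.
#' @param model `"wnn"` or `"mlp"`.
#' @param seed master seed.
#' @param n_hidden,epochs training budget (defaults 5 nodes, 50 epochs).
#' @return the fit, invisibly.
#' @export
cmd_train <- function(gi_dir, out_path, model = c("wnn", "mlp"), seed = 1,
                      n_hidden = 5, epochs = 50) {
  model <- match.arg(model)
  gi <- read_gi(gi_dir)
  config <- training_config(E_max = epochs, n_hidden = n_hidden,
                            seed = derive_seed(seed, "training"))
  fit <- if (model == "wnn") {
    p0 <- wnn_init(gi$x, gi$y, n_hidden = n_hidden, seed = config$seed)
    wnn_train(p0, gi$x, gi$y, config)
  } else {
    mlp_baseline(gi$x, gi$y, config)
  }
  write_params_json(fit$params, out_path)
  message(sprintf("%s trained for %d epochs (final cost %.4g, %s)",
                  model, nrow(fit$trace), utils::tail(fit$trace$cost, 1),
                  fit$stop_reason))
  invisible(fit)
}

#' Run the full experiment end-to-end and write the report
#'
#' Simulates (or loads) a cohort, runs preprocessing, feature selection,
#' training over three split sequences with the WNN and the MLP
#' baseline, and writes the evaluation report to JSON.
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_subjects,trials_per_subject cohort size.
#' @param noise_sd vGRF noise level in body-weight units.
#' @param n_hidden,epochs training budget (defaults 5 nodes, 50 epochs).
#' @param include_mlp also run the MLP baseline.
#' @return the `gait_eval_report`, invisibly.
#' @export
cmd_evaluate <- function(out_dir, seed = 1, n_subjects = 30,
                         trials_per_subject = 10, noise_sd = 0.02,
                         n_hidden = 5, epochs = 50, include_mlp = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(n_subjects, trials_per_subject,
                            seed = derive_seed(seed, "generator"),
                            noise_sd = noise_sd)
  config <- training_config(E_max = epochs, n_hidden = n_hidden,
                            seed = derive_seed(seed, "training"))
  report <- run_experiment(
    cohort, config,
    split_seeds = vapply(paste0("split", 1:3), derive_seed,
                         numeric(1), master = seed),
    include_mlp = include_mlp)
  write_report_json(report, file.path(out_dir, "report.json"))
  print(report)
  invisible(report)
}
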