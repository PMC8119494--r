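#' Write a synthetic cohort to disk
#'
#' Writes one CSV with a row per sample (columns `subject_id`,
#' `trial_id`, `time`, `vgrf_left`, `vgrf_right`, `theta_a`, `theta_k`,
#' `theta_h`) and a JSON sidecar holding per-trial event sample indexes,
#' the generator parameters and the seed.
#'
#' @param cohort a `gait_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(tr) {
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               time = tr$time, vgrf_left = tr$vgrf_left,
               vgrf_right = tr$vgrf_right, theta_a = tr$theta_a,
               theta_k = tr$theta_k, theta_h = tr$theta_h)
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  sidecar <- list(
    schema_version = "1.0",
    seed = attr(cohort, "seed"),
    noise_sd = attr(cohort, "noise_sd"),
    trial_jitter = attr(cohort, "trial_jitter"),
    params = attr(cohort, "params"),
    trials = lapply(cohort, function(tr) {
      list(subject_id = tr$subject_id, trial_id = tr$trial_id, fs = tr$fs,
           events = as.list(tr$events), toe_off_pct = tr$toe_off_pct)
    })
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.csv` and `cohort.json`.
#' @return a `gait_cohort`.
#' @export
read_cohort <- function(dir) {
  csv <- utils::read.csv(file.path(dir, "cohort.csv"))
  side <- jsonlite::read_json(file.path(dir, "cohort.json"))
  trials <- lapply(side$trials, function(meta) {
    sub <- csv[csv$subject_id == meta$subject_id &
                 csv$trial_id == meta$trial_id, , drop = FALSE]
    if (nrow(sub) == 0)
      stop(sprintf("cohort.csv has no rows for subject %s trial %s",
                   meta$subject_id, meta$trial_id))
    structure(list(
      subject_id = meta$subject_id, trial_id = meta$trial_id, fs = meta$fs,
      time = sub$time, vgrf_left = sub$vgrf_left,
      vgrf_right = sub$vgrf_right, theta_a = sub$theta_a,
      theta_k = sub$theta_k, theta_h = sub$theta_h,
      events = unlist(meta$events), toe_off_pct = meta$toe_off_pct
    ), class = "gait_trial")
  })
  structure(trials, class = "gait_cohort", seed = side$seed,
            params = side$params, noise_sd = side$noise_sd,
            trial_jitter = side$trial_jitter)
}

#' Write feature/target matrices and schedules to disk
#'
#' Writes `features.csv` (22 x n) and `targets.csv` (66 x n) with rows as
#' features/targets and columns as samples, plus `schedules.json` with
#' the per-sample event schedules.
#'
#' @param gi result of [gi_transform()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_gi <- function(gi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(gi$x), file.path(dir, "features.csv"))
  utils::write.csv(as.data.frame(gi$y), file.path(dir, "targets.csv"))
  jsonlite::write_json(
    list(schema_version = "1.0",
         schedules = lapply(gi$schedules, function(s) as.list(s))),
    file.path(dir, "schedules.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read matrices and schedules written by [write_gi()]
#'
#' @param dir directory containing the GI outputs.
#' @return list with `x`, `y` and `schedules`.
#' @export
read_gi <- function(dir) {
  x <- as.matrix(utils::read.csv(file.path(dir, "features.csv"),
                                 row.names = 1))
  y <- as.matrix(utils::read.csv(file.path(dir, "targets.csv"),
                                 row.names = 1))
  side <- jsonlite::read_json(file.path(dir, "schedules.json"))
  schedules <- lapply(side$schedules, function(s) {
    df <- data.frame(m = as.integer(unlist(s$m)), label = unlist(s$label),
                     t = as.integer(unlist(s$t)), kind = unlist(s$kind),
                     leg = unlist(s$leg), stringsAsFactors = FALSE)
    class(df) <- c("gi_schedule", "data.frame")
    df
  })
  list(x = x, y = y, schedules = schedules)
}

#' Serialize fitted network parameters to JSON
#'
#' Writes shapes and flattened values with explicit field names and a
#' version tag; [read_params_json()] restores the object exactly.
#'
#' @param params a `wnn_params` or `mlp_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  arrays <- unclass(params)
  arrays <- arrays[setdiff(names(arrays), c("n_in", "n_hidden", "n_out"))]
  payload <- list(
    schema_version = "1.0",
    model = class(params)[1],
    n_in = params$n_in, n_hidden = params$n_hidden, n_out = params$n_out,
    arrays = lapply(arrays, function(a) {
      list(dim = if (is.null(dim(a))) length(a) else dim(a),
           values = as.numeric(a))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore network parameters from JSON
#'
#' @param path file written by [write_params_json()].
#' @return the restored `wnn_params` or `mlp_params` object.
#' @export
read_params_json <- function(path) {
  payload <- jsonlite::read_json(path)
  arrays <- lapply(payload$arrays, function(a) {
    dims <- unlist(a$dim)
    vals <- unlist(a$values)
    if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else vals
  })
  out <- c(arrays, list(n_in = payload$n_in,
                        n_hidden = payload$n_hidden,
                        n_out = payload$n_out))
  class(out) <- payload$model
  out
}
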