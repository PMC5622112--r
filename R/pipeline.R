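#' Build a pipeline run configuration
#'
#' Collects every knob of an end-to-end run: the dose-response model, the
#' acquisition geometry, per-condition sample size, the analysis settings
#' and all seeds. `path = "table"` uses the fast parametric feature-table
#' surrogate; `path = "image"` renders, reconstructs, segments and
#' extracts features from synthetic images (slower, full coverage).
#'
#' @param model a [dose_response_model()].
#' @param acq an [acquisition_params()] (image path only).
#' @param n_per_condition cells per (dose, duration, experiment).
#' @param durations durations to simulate (subset of `model$durations`).
#' @param experiments experiment ids.
#' @param path `"table"` or `"image"`.
#' @param C,folds SVM regularization and CV folds.
#' @param mmd_convention cross-term convention for MMD estimates.
#' @param mmd_max_n per-class subsample cap for whole-space MMD.
#' @param retain_grid feature-elimination grid (NULL = default log grid).
#' @param shift class-shift vector of the table generator.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir optional directory; when set, tables and reports are
#'   written there as CSV/JSON.
#' @return object of class `run_config`.
#' @export
run_config <- function(model = dose_response_model(),
                       acq = acquisition_params(),
                       n_per_condition = 200,
                       durations = model$durations,
                       experiments = 1:2,
                       path = c("table", "image"),
                       C = 1, folds = 10,
                       mmd_convention = "all-pairs", mmd_max_n = 1000,
                       retain_grid = NULL, shift = default_shift(),
                       seed = 1, output_dir = NULL) {
  cfg <- list(model = model, acq = acq,
              n_per_condition = n_per_condition, durations = durations,
              experiments = experiments, path = match.arg(path),
              C = C, folds = folds, mmd_convention = mmd_convention,
              mmd_max_n = mmd_max_n, retain_grid = retain_grid,
              shift = shift, seed = seed, output_dir = output_dir)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Returns findings as a character vector (empty = valid); nothing is
#' thrown.
#'
#' @param config a [run_config()].
#' @return character vector of findings.
#' @export
validate_config <- function(config) {
  f <- character(0)
  add <- function(msg) f <<- c(f, msg)
  if (!inherits(config, "run_config")) return("not a run_config object")
  if (is.null(config$seed) || !is.finite(config$seed))
    add("missing or non-finite seed: every run must fix its seeds")
  if (config$n_per_condition < 2)
    add(paste0("n_per_condition = ", config$n_per_condition,
               " < 2: the unbiased MMD estimator requires m, n >= 2"))
  if (!all(config$durations %in% config$model$durations))
    add(paste0("unknown duration(s) ",
               paste(setdiff(config$durations, config$model$durations),
                     collapse = ", "), "; valid: ",
               paste(config$model$durations, collapse = ", ")))
  if (!is.null(config$retain_grid) &&
      (any(config$retain_grid < 1) || any(config$retain_grid > 548)))
    add("retain_grid out of range [1, 548]")
  if (config$folds < 2) add("folds must be >= 2")
  if (config$n_per_condition < config$folds)
    add("n_per_condition smaller than the number of CV folds")
  if (config$C <= 0) add("C must be > 0")
  f
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (reconstruct -> extract, image path) -> classify
#' -> MMD -> report from one configuration. The report mirrors the
#' method's result surface: per-dose accuracy curve, score histograms at
#' the peak dose, whole-space MMD per dose, per-feature MMD comparison
#' across the two experiments at each experiment's argmax dose, the
#' MMD-guided feature-elimination curve, and the cross-condition transfer
#' matrix. Rerunning with the same config reproduces the report exactly.
#'
#' @param config a [run_config()]; invalid configs abort with the
#'   findings.
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid config:\n  - ", paste(findings, collapse = "\n  - "))
  seed <- as.integer(config$seed)
  .ms_log("stage simulate: path=%s n=%d", config$path,
          config$n_per_condition)
  table <- if (config$path == "table") {
    simulate_feature_study(config$model, config$n_per_condition,
                           durations = config$durations,
                           experiments = config$experiments, seed = seed,
                           shift = config$shift)
  } else {
    .simulate_image_study(config)
  }
  .ms_log("stage classify: dose-response curve")
  curve <- dose_response_curve(table, k = config$folds, C = config$C,
                               seed = seed + 1L)
  .ms_log("stage mmd: whole-space dose curve")
  mmd_curve <- mmd_dose_curve(table, max_n = config$mmd_max_n,
                              seed = seed + 2L)
  dur <- max(config$durations)
  sub <- function(e, d) table[table$duration_h == dur &
                                table$experiment == e &
                                table$dose_M %in% c(0, d), ]
  # argmax dose per experiment at the longest duration (whole-space MMD)
  mc <- mmd_curve[mmd_curve$duration_h == dur, ]
  peak <- vapply(sort(unique(mc$experiment)), function(e) {
    mce <- mc[mc$experiment == e, ]
    mce$dose_M[which.max(mce$mmd_score)]
  }, numeric(1))
  .ms_log("stage mmd: per-feature ranking at peak doses %s",
          paste(format(peak), collapse = ", "))
  exps <- sort(unique(table$experiment))
  pf <- lapply(seq_along(exps), function(i) {
    t1 <- sub(exps[i], peak[i])
    per_feature_mmd(t1[t1$dose_M == 0, ], t1[t1$dose_M > 0, ],
                    seed = seed + 3L,
                    convention = config$mmd_convention)
  })
  names(pf) <- paste0("experiment_", exps)
  .ms_log("stage mmd: elimination curve")
  t1 <- sub(exps[1], peak[1])
  fm1 <- feature_matrix(t1)
  elim <- elimination_curve(fm1$x, fm1$meta$label, pf[[1]],
                            retain_grid = config$retain_grid,
                            k = config$folds, C = config$C,
                            seed = seed + 4L)
  .ms_log("stage classify: transfer matrix")
  tm <- transfer_matrix(table, duration = dur, k = config$folds,
                        C = config$C, seed = seed + 5L)
  .ms_log("stage classify: score histogram at peak dose")
  m1 <- linear_svm(fm1$x, fm1$meta$label, C = config$C, seed = seed + 6L,
                   meta = list(dose = peak[1], duration = dur,
                               experiment = exps[1]))
  hist1 <- score_histogram(m1, fm1$x, fm1$meta$label)
  report <- structure(
    list(accuracy_curve = curve, mmd_curve = mmd_curve,
         per_feature_mmd = pf, elimination = elim, transfer = tm,
         score_histogram = hist1, peak_model = m1, peak_doses = peak,
         config = config,
         fingerprint = list(seed = seed,
                            n_per_condition = config$n_per_condition,
                            path = config$path,
                            package_version =
                              as.character(utils::packageVersion("morphoscreen")))),
    class = "run_report")
  if (!is.null(config$output_dir)) .write_report(report, config$output_dir)
  report
}

# image-path simulation: render one cell per frame per condition,
# serialize to a line-scan stream, reconstruct, segment and extract
.simulate_image_study <- function(config) {
  model <- config$model; acq <- config$acq
  grid <- expand.grid(dose = model$doses, duration = config$durations,
                      experiment = config$experiments)
  parts <- list()
  for (i in seq_len(nrow(grid))) {
    cseed <- (as.integer(config$seed) + 1009L * i) %% 2147483647L
    phen <- sample_phenotype(model, grid$dose[i], grid$duration[i],
                             n = config$n_per_condition, seed = cseed)
    frames <- lapply(seq_len(nrow(phen)), function(j)
      render_cell_image(phen[j, ], acq, seed = cseed + j)$pixels)
    wave <- render_linescan_stream(frames, acq, gap_lines = 0,
                                   seed = cseed)
    rec <- reconstruct_cells(wave, acq$frame_width, acq$frame_height)
    .ms_log("condition %d/%d: %s", i, nrow(grid),
            paste(names(rec$stats), rec$stats, collapse = " ",
                  sep = "="))
    if (length(rec$cells) == 0) next
    meta <- data.frame(
      experiment = grid$experiment[i], duration_h = grid$duration[i],
      dose_M = grid$dose[i],
      label = if (grid$dose[i] > 0) "treated" else "control",
      stringsAsFactors = FALSE)[rep(1, length(rec$cells)), ]
    tab <- extract_feature_table(rec$cells, meta)
    tab$cell_id <- sprintf("e%d_%gh_%0.0e_%05d", grid$experiment[i],
                           grid$duration[i], grid$dose[i],
                           seq_along(rec$cells))
    parts[[length(parts) + 1L]] <- tab
  }
  do.call(rbind, parts)
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$accuracy_curve,
                   file.path(dir, "accuracy_curve.csv"), row.names = FALSE)
  utils::write.csv(report$mmd_curve, file.path(dir, "mmd_curve.csv"),
                   row.names = FALSE)
  for (nm in names(report$per_feature_mmd))
    utils::write.csv(report$per_feature_mmd[[nm]],
                     file.path(dir, paste0("per_feature_mmd_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$elimination, file.path(dir, "elimination.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$transfer)),
                   file.path(dir, "transfer_matrix.csv"))
  write_model_json(report$peak_model, file.path(dir, "peak_model.json"))
  jsonlite::write_json(report$fingerprint, file.path(dir, "fingerprint.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  path: %s, n/condition: %d, seed: %d\n",
              x$fingerprint$path, x$fingerprint$n_per_condition,
              x$fingerprint$seed))
  cat("  per-dose accuracy (", max(x$config$durations), " h):\n", sep = "")
  cc <- x$accuracy_curve[x$accuracy_curve$duration_h ==
                           max(x$config$durations), ]
  for (i in seq_len(nrow(cc)))
    cat(sprintf("    %8.3g M: A = %.3f +/- %.3f\n", cc$dose_M[i],
                cc$accuracy[i], cc$se_trials[i]))
  cat(sprintf("  whole-space MMD argmax dose: %s\n",
              paste(format(x$peak_doses), collapse = ", ")))
  cat(sprintf("  elimination: accuracy %.3f with all %d features, %.3f with %d\n",
              x$elimination$accuracy[1], x$elimination$n_features[1],
              x$elimination$accuracy[nrow(x$elimination)],
              x$elimination$n_features[nrow(x$elimination)]))
  invisible(x)
}
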