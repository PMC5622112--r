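#' Default class-shift vector of the parametric generator
#'
#' Registry-length vector giving each feature's class-mean displacement (in
#' pooled-sd units) at full effect size. The default perturbs 32 features
#' spread over all four categories by 0.5 sd each, i.e. a full-effect
#' Mahalanobis separation of \eqn{0.5\sqrt{32} \approx 2.83}, for which the
#' Bayes-optimal linear classifier reaches
#' \eqn{\Phi(2.83/2) \approx 92\%} accuracy — the separability regime the
#' pipeline is designed to operate in.
#'
#' @return named numeric vector of length 548.
#' @export
default_shift <- function() {
  reg <- feature_registry()
  s <- numeric(548)
  names(s) <- reg$name
  idx <- c(1, 3, 6, 7, 11, 14, 20,                 # geometry
           45, 46, 48,                             # granularity
           54, 57, 64, 75, 80, 90,                 # intensity
           100, 120, 150, 200, 250, 300, 350, 400, # texture
           420, 450, 470, 490, 510, 520, 530, 540)
  s[idx] <- 0.5
  s
}

#' Generate a parametric single-condition feature table
#'
#' Fast surrogate for the image path: draws `n` cells for one
#' (dose, duration, experiment) condition as a 548-dimensional multivariate
#' normal whose class mean is shifted by
#' `effect_size(dose, duration) * shift` relative to the untreated
#' distribution. Features are unit-variance and independent. An optional
#' experiment-specific batch offset (common to control and treated rows of
#' the same experiment) can emulate run-to-run drift; it is off by default
#' so zero-effect conditions are exactly exchangeable across experiments.
#' At effect size 0 the treated and control distributions are identical.
#'
#' @param model a [dose_response_model()].
#' @param dose molar concentration in `model$doses`; rows are labelled
#'   `"treated"` when `dose > 0`, `"control"` otherwise.
#' @param duration incubation time in `model$durations`.
#' @param n number of cells (rows); must be >= 2 (downstream MMD needs
#'   m, n >= 2).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param experiment experiment repeat id (1 or 2 in the default design).
#' @param shift 548-vector of per-feature displacements at full effect;
#'   default [default_shift()].
#' @param batch_sd sd of the per-experiment batch offset (0 disables it).
#' @return data.frame with columns `cell_id`, `experiment`, `duration_h`,
#'   `dose_M`, `label`, `f001`..`f548`.
#' @export
generate_feature_table <- function(model, dose, duration, n, seed = 1,
                                   experiment = 1L, shift = default_shift(),
                                   batch_sd = 0) {
  stopifnot(inherits(model, "dose_response_model"), length(shift) == 548,
            batch_sd >= 0)
  if (n < 2) stop("n must be >= 2 (the unbiased MMD estimator needs m, n >= 2)")
  eff <- effect_size(model, dose, duration)
  mu <- eff * shift
  if (batch_sd > 0) {
    # batch offset is a fixed function of the experiment id only, so both
    # classes of one experiment share it across calls
    mu <- mu + .with_seed(97003L + as.integer(experiment),
                          rnorm(548, sd = batch_sd))
  }
  X <- .with_seed(seed, matrix(rnorm(n * 548), n, 548))
  X <- sweep(X, 2, mu, "+")
  colnames(X) <- .feature_colnames()
  label <- if (dose > 0) "treated" else "control"
  out <- data.frame(
    cell_id = sprintf("e%d_%gh_%0.0e_%s_%05d", experiment, duration,
                      dose, substr(label, 1, 1), seq_len(n)),
    experiment = as.integer(experiment), duration_h = duration,
    dose_M = dose, label = label, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(X))
}

#' Simulate a full multi-condition feature study
#'
#' Generates one combined feature table covering every dose in the model,
#' both durations and a configurable number of experimental repeats —
#' the desk-scale analogue of the full acquisition campaign (negative
#' control plus a dilution series, two durations, two repeats).
#'
#' @param model a [dose_response_model()].
#' @param n_per_condition cells per (dose, duration, experiment) cell.
#' @param durations subset of `model$durations` to simulate.
#' @param experiments experiment ids (default `1:2`).
#' @param seed base seed; per-condition seeds are derived deterministically.
#' @param shift,batch_sd passed to [generate_feature_table()].
#' @return one data.frame in feature-table layout.
#' @export
simulate_feature_study <- function(model, n_per_condition = 1000,
                                   durations = model$durations,
                                   experiments = 1:2, seed = 1,
                                   shift = default_shift(), batch_sd = 0) {
  stopifnot(all(durations %in% model$durations))
  grid <- expand.grid(dose = model$doses, duration = durations,
                      experiment = experiments)
  parts <- lapply(seq_len(nrow(grid)), function(i) {
    cond_seed <- (as.integer(seed) + 1009L * i) %% 2147483647L
    generate_feature_table(model, grid$dose[i], grid$duration[i],
                           n_per_condition, seed = cond_seed,
                           experiment = grid$experiment[i],
                           shift = shift, batch_sd = batch_sd)
  })
  do.call(rbind, parts)
}

#' Split a feature table into metadata and feature matrix
#' @param table a feature table data.frame.
#' @return list with `meta` (data.frame) and `x` (numeric matrix n x 548).
#' @export
feature_matrix <- function(table) {
  fc <- .feature_colnames()
  stopifnot(all(fc %in% names(table)))
  list(meta = table[setdiff(names(table), fc)],
       x = as.matrix(table[fc]))
}
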