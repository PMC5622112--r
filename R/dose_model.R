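#' Dose-response effect model
#'
#' Defines how strongly a treatment at a given molar concentration and
#' incubation time perturbs cellular morphology, on a normalized scale in
#' \[0, 1\]. The shape is a Hill curve in concentration,
#' \eqn{h(c) = c^k / (c^k + EC_{50}^k)}, multiplied by
#' \eqn{1 - rollback\_fraction} for doses above `peak_dose` (emulating the
#' loss of separability observed at the highest dose, e.g. from solvent
#' toxicity), and by `duration_scale` for the shorter of the two incubation
#' times. The effect at dose 0 (negative control) is exactly 0.
#'
#' @param doses ordered numeric vector of molar concentrations, including 0
#'   for the negative control. Default: control plus a 10-fold dilution
#'   series from 1 nM to 10 uM.
#' @param ec50 Hill midpoint concentration (M).
#' @param hill_k Hill slope (dimensionless, > 0).
#' @param peak_dose concentration of maximal effect; above it the effect is
#'   reduced by `rollback_fraction`.
#' @param rollback_fraction relative effect reduction above `peak_dose`,
#'   in \[0, 1).
#' @param duration_scale multiplier in (0, 1) applied at the shorter
#'   (12 h) incubation; 24 h uses the full effect.
#' @param durations supported incubation times in hours (shorter one is
#'   scaled by `duration_scale`).
#' @return an object of class `dose_response_model`.
#' @examples
#' m <- dose_response_model()
#' effect_size(m, 1e-6, 24)   # maximal effect
#' effect_size(m, 0, 24)      # exactly 0
#' @export
dose_response_model <- function(doses = c(0, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5),
                                ec50 = 5e-8, hill_k = 1,
                                peak_dose = 1e-6, rollback_fraction = 0.3,
                                duration_scale = 0.6,
                                durations = c(12, 24)) {
  stopifnot(is.numeric(doses), all(doses >= 0), 0 %in% doses,
            ec50 > 0, hill_k > 0, peak_dose > 0,
            rollback_fraction >= 0, rollback_fraction < 1,
            duration_scale > 0, duration_scale < 1,
            length(durations) == 2)
  structure(list(doses = sort(unique(doses)), ec50 = ec50, hill_k = hill_k,
                 peak_dose = peak_dose,
                 rollback_fraction = rollback_fraction,
                 duration_scale = duration_scale,
                 durations = sort(durations)),
            class = "dose_response_model")
}

#' Effect size of a dose/duration condition
#'
#' @param model a [dose_response_model()].
#' @param dose molar concentration; must be one of `model$doses`.
#' @param duration incubation time in hours; must be one of
#'   `model$durations`.
#' @return scalar effect in \[0, 1\].
#' @export
effect_size <- function(model, dose, duration) {
  stopifnot(inherits(model, "dose_response_model"))
  if (!all(dose %in% model$doses))
    stop("unknown dose ", paste(setdiff(dose, model$doses), collapse = ", "),
         "; valid doses (M): ", paste(format(model$doses), collapse = ", "))
  if (!all(duration %in% model$durations))
    stop("unknown duration ", paste(setdiff(duration, model$durations),
                                    collapse = ", "),
         "; valid durations (h): ", paste(model$durations, collapse = ", "))
  h <- ifelse(dose == 0, 0,
              dose^model$hill_k / (dose^model$hill_k + model$ec50^model$hill_k))
  h <- ifelse(dose > model$peak_dose, h * (1 - model$rollback_fraction), h)
  ifelse(duration == min(model$durations), h * model$duration_scale, h)
}

#' @export
print.dose_response_model <- function(x, ...) {
  cat("Dose-response effect model (Hill)\n")
  cat(sprintf("  EC50 %.3g M, slope %.2g, peak %.3g M, rollback %.0f%%, 12 h scale %.2f\n",
              x$ec50, x$hill_k, x$peak_dose, 100 * x$rollback_fraction,
              x$duration_scale))
  eff <- sapply(x$doses, function(d) effect_size(x, d, max(x$durations)))
  cat("  effect at 24 h:",
      paste(sprintf("%.3g M=%.2f", x$doses, eff), collapse = ", "), "\n")
  invisible(x)
}
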