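#' Phenotype parameters of a single synthetic cell
#'
#' Generative parameters from which one cell image is rendered. All lengths
#' are in pixels, intensities in normalized \[0, 1\] units.
#'
#' @param mean_radius equivalent radius of the cell (px).
#' @param radius_sd cell-to-cell standard deviation of the radius (px), used
#'   by [sample_phenotype()].
#' @param eccentricity elliptical eccentricity in \[0, 1).
#' @param texture_grain correlation length of the interior texture (px).
#' @param intensity_mean mean interior intensity.
#' @param intensity_sd amplitude of the interior texture.
#' @param edge_sharpness boundary blur scale (px); smaller is sharper.
#' @return an object of class `phenotype_params`.
#' @export
phenotype_params <- function(mean_radius = 12, radius_sd = 1.5,
                             eccentricity = 0.15, texture_grain = 1.5,
                             intensity_mean = 0.55, intensity_sd = 0.06,
                             edge_sharpness = 1.0) {
  p <- list(mean_radius = mean_radius, radius_sd = radius_sd,
            eccentricity = eccentricity, texture_grain = texture_grain,
            intensity_mean = intensity_mean, intensity_sd = intensity_sd,
            edge_sharpness = edge_sharpness)
  stopifnot(mean_radius > 0, radius_sd >= 0,
            eccentricity >= 0, eccentricity < 1,
            texture_grain > 0, intensity_mean > 0, intensity_sd >= 0,
            edge_sharpness > 0)
  # keep interior intensities representable in [0, 1]
  if (intensity_mean + 3 * intensity_sd > 1 ||
      intensity_mean - 3 * intensity_sd < 0)
    stop("intensity_mean +/- 3*intensity_sd must lie within [0, 1]")
  structure(p, class = "phenotype_params")
}

#' Acquisition parameters of the synthetic line-scan camera
#'
#' @param frame_height lines per frame.
#' @param frame_width samples per line.
#' @param background_level normalized background intensity.
#' @param noise_sd additive Gaussian noise level (normalized units).
#' @param cells_per_frame expected cells per frame (kept at <= 1; the flow
#'   is assumed dilute enough that frames hold at most one cell).
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_height = 64, frame_width = 64,
                               background_level = 0.15, noise_sd = 0.01,
                               cells_per_frame = 1) {
  stopifnot(frame_height >= 8, frame_width >= 8,
            frame_height == round(frame_height),
            frame_width == round(frame_width),
            background_level >= 0, background_level <= 1, noise_sd >= 0,
            cells_per_frame > 0, cells_per_frame <= 1)
  structure(list(frame_height = as.integer(frame_height),
                 frame_width = as.integer(frame_width),
                 background_level = background_level, noise_sd = noise_sd,
                 cells_per_frame = cells_per_frame),
            class = "acquisition_params")
}

# baseline phenotype, per-parameter displacement at full effect, and
# cell-to-cell variation sd (truncated-normal scale). The displacement
# direction is a design choice of the generator: treated cells swell,
# elongate, coarsen their texture and lose a little interior intensity.
.pheno_axes <- function() {
  list(
    baseline = c(mean_radius = 12, eccentricity = 0.15, texture_grain = 1.5,
                 intensity_mean = 0.55, intensity_sd = 0.06,
                 edge_sharpness = 1.0),
    displacement = c(mean_radius = 4, eccentricity = 0.25,
                     texture_grain = 1.2, intensity_mean = -0.08,
                     intensity_sd = 0.03, edge_sharpness = 0.8),
    variation_sd = c(mean_radius = 1.5, eccentricity = 0.05,
                     texture_grain = 0.25, intensity_mean = 0.03,
                     intensity_sd = 0.008, edge_sharpness = 0.15),
    lower = c(mean_radius = 4, eccentricity = 0, texture_grain = 0.3,
              intensity_mean = 0.2, intensity_sd = 0.005,
              edge_sharpness = 0.3),
    upper = c(mean_radius = 26, eccentricity = 0.9, texture_grain = 5,
              intensity_mean = 0.85, intensity_sd = 0.12,
              edge_sharpness = 3)
  )
}

# exact truncated normal via inverse-CDF sampling
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + runif(n) * (pb - pa), mean, sd)
}

#' Sample per-cell phenotypes for a treatment condition
#'
#' Draws cell phenotypes whose parameters are the untreated baseline shifted
#' along each axis by `effect_size(dose, duration)` times that axis' maximal
#' displacement, plus truncated-normal cell-to-cell variation. At dose 0 the
#' shift is exactly zero.
#'
#' @param model a [dose_response_model()].
#' @param dose molar concentration in `model$doses`.
#' @param duration incubation time in `model$durations`.
#' @param n number of cells to draw.
#' @param seed integer seed; the draw is a pure function of
#'   `(model, dose, duration, n, seed)`.
#' @param variation_scale multiplier on the cell-to-cell variation sd
#'   (0 gives the deterministic baseline-plus-displacement limit).
#' @return data.frame of `n` rows with phenotype columns plus `dose_M`,
#'   `duration_h`, `effect`.
#' @export
sample_phenotype <- function(model, dose, duration, n = 1, seed = 1,
                             variation_scale = 1) {
  stopifnot(inherits(model, "dose_response_model"), n >= 1,
            variation_scale >= 0)
  eff <- effect_size(model, dose, duration)  # validates dose/duration
  ax <- .pheno_axes()
  res <- .with_seed(seed, {
    vals <- lapply(names(ax$baseline), function(p) {
      mu <- ax$baseline[[p]] + eff * ax$displacement[[p]]
      .rtruncnorm(n, mu, variation_scale * ax$variation_sd[[p]],
                  ax$lower[[p]], ax$upper[[p]])
    })
    names(vals) <- names(ax$baseline)
    vals
  })
  df <- as.data.frame(res)
  df$dose_M <- dose
  df$duration_h <- duration
  df$effect <- eff
  df
}

# evaluate `code` under set.seed(seed), restoring the caller's RNG state
# afterwards so seeded generators are pure functions of their arguments.
.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
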