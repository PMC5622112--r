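#' Render a synthetic single-cell bright-field image
#'
#' Draws one elliptical cell with band-limited interior texture on a noisy
#' background, together with its ground-truth mask. The ellipse axes are
#' derived from `mean_radius` (area-preserving: \eqn{ab = r^2}) and
#' `eccentricity`; orientation is uniform random. Interior texture is
#' Gaussian-filtered white noise with filter sigma `texture_grain`, scaled
#' to `intensity_sd`. The boundary is blurred over `edge_sharpness` pixels
#' via a logistic profile in normalized radial distance, and i.i.d. Gaussian
#' noise of sd `noise_sd` is added everywhere. Pixels are clipped to
#' \[0, 1\].
#'
#' @param phen a [phenotype_params()] (or one row of [sample_phenotype()]).
#' @param acq an [acquisition_params()].
#' @param seed integer seed; identical `(phen, acq, seed)` give bit-identical
#'   images.
#' @return an object of class `cell_image`: list with `pixels` (matrix,
#'   rows = lines), `mask` (logical matrix, ground truth), and `truth`
#'   (phenotype, orientation, centre, seed).
#' @export
render_cell_image <- function(phen, acq = acquisition_params(), seed = 1) {
  stopifnot(inherits(acq, "acquisition_params"))
  p <- phen
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- phenotype_params(mean_radius = p$mean_radius, radius_sd = 0,
                          eccentricity = p$eccentricity,
                          texture_grain = p$texture_grain,
                          intensity_mean = p$intensity_mean,
                          intensity_sd = p$intensity_sd,
                          edge_sharpness = p$edge_sharpness)
  }
  stopifnot(inherits(p, "phenotype_params"))
  h <- acq$frame_height; w <- acq$frame_width
  ecc2 <- 1 - p$eccentricity^2
  a <- p$mean_radius / ecc2^0.25   # semi-major
  b <- p$mean_radius * ecc2^0.25   # semi-minor
  if (2 * a >= min(h, w) - 2)
    stop("cell (major axis ", round(2 * a, 1),
         " px) does not fit in the ", h, "x", w, " frame")
  .with_seed(seed, {
    theta <- runif(1, 0, pi)
    # small random off-centre placement, kept inside the frame
    maxoff <- pmax(0, (min(h, w) / 2 - a - 2))
    cy <- (h + 1) / 2 + runif(1, -1, 1) * min(maxoff, 3)
    cx <- (w + 1) / 2 + runif(1, -1, 1) * min(maxoff, 3)
    yy <- matrix(seq_len(h), h, w) - cy
    xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    u <- xx * cos(theta) + yy * sin(theta)
    v <- -xx * sin(theta) + yy * cos(theta)
    d <- sqrt((u / a)^2 + (v / b)^2)      # 1 on the true boundary
    mask <- d <= 1
    # logistic edge whose 10-90% transition width ~ edge_sharpness px
    alpha <- stats::plogis(4 * (1 - d) * p$mean_radius / p$edge_sharpness)
    tex <- 0
    if (p$intensity_sd > 0) {
      noise <- matrix(rnorm(h * w), h, w)
      sm <- .gauss_blur(noise, p$texture_grain)
      s <- stats::sd(as.vector(sm))
      if (s > 0) tex <- sm / s * p$intensity_sd
    }
    interior <- pmin(pmax(p$intensity_mean + tex, 0), 1)
    img <- acq$background_level + alpha * (interior - acq$background_level)
    if (acq$noise_sd > 0) img <- img + rnorm(h * w, sd = acq$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    structure(list(pixels = img, mask = mask,
                   truth = list(phenotype = unclass(p), orientation = theta,
                                centre = c(row = cy, col = cx),
                                semi_axes = c(major = a, minor = b),
                                seed = seed)),
              class = "cell_image")
  })
}

# separable Gaussian blur with reflective padding
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(min(r, n))), seq_len(n),
                           n + 1 - rev(seq_len(min(r, n))))
  conv1 <- function(x) as.vector(stats::filter(x, k, sides = 2))
  blur_dim <- function(mm) {
    n <- nrow(mm)
    ii <- pad_idx(n)
    out <- apply(mm[ii, , drop = FALSE], 2, conv1)
    out[(r + 1):(r + n), , drop = FALSE]
  }
  t(blur_dim(t(blur_dim(m))))
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("cell_image: %d x %d px, mask area %d px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask)))
  invisible(x)
}

#' Serialize image frames into a 1-D line-scan waveform
#'
#' Inverse of [stack_linescans()]: emits each frame's lines (rows) in
#' acquisition order as one concatenated waveform, optionally separated by
#' noisy background lines, as a line-scan camera would produce. Frames must
#' share dimensions; placements are sequential, so they cannot overlap in
#' time by construction, and negative gaps are rejected.
#'
#' @param frames list of matrices (or `cell_image` objects, whose `pixels`
#'   are used), all of dimension `frame_height x frame_width`.
#' @param acq an [acquisition_params()]; supplies background level/noise for
#'   gap lines.
#' @param gap_lines integer vector (recycled) of background lines inserted
#'   before each frame; 0 for none.
#' @param seed seed for the gap-line noise.
#' @return numeric waveform vector.
#' @export
render_linescan_stream <- function(frames, acq = acquisition_params(),
                                   gap_lines = 0, seed = 1) {
  stopifnot(length(frames) >= 1, all(gap_lines >= 0),
            all(gap_lines == round(gap_lines)))
  mats <- lapply(frames, function(f) if (inherits(f, "cell_image")) f$pixels else f)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != acq$frame_height) || any(dims[2, ] != acq$frame_width))
    stop("all frames must be frame_height x frame_width")
  gap_lines <- rep_len(as.integer(gap_lines), length(mats))
  .with_seed(seed, {
    parts <- vector("list", 2 * length(mats))
    for (i in seq_along(mats)) {
      g <- gap_lines[i]
      gap <- if (g > 0)
        pmin(pmax(acq$background_level +
                    rnorm(g * acq$frame_width, sd = acq$noise_sd), 0), 1)
      else numeric(0)
      parts[[2 * i - 1]] <- gap
      parts[[2 * i]] <- as.vector(t(mats[[i]]))  # row-major: line by line
    }
    unlist(parts, use.names = FALSE)
  })
}
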