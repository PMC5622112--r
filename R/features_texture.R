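## Texture features (registry 97-548): 13 Haralick statistics from the
## gray-level co-occurrence matrix (GLCM) at 4 offsets (0, 45, 90, 135
## degrees) x 8 distances (1,2,3,4,5,6,8,10 px) = 416 values, then Gabor
## energy at 4 orientations x 9 wavelengths = 36 values.

# quantize masked intensities to `levels` gray levels over the masked
# range; ties at bin edges go to the lower bin; pixels outside the mask
# are NA and never enter a pair.
.glcm_quantize <- function(image, mask, levels = 8) {
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  v <- image[mask]
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) {
    q[mask] <- 1L
  } else {
    g <- ceiling((v - rng[1]) / (rng[2] - rng[1]) * levels)
    g[g < 1L] <- 1L
    q[mask] <- as.integer(g)
  }
  q
}

# symmetric normalized GLCM for offset (dr, dc); NULL when no valid pair.
.glcm <- function(q, dr, dc, levels = 8) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r1) == 0 || length(c1) == 0) return(NULL)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  counts <- tabulate(a[ok] + levels * (b[ok] - 1L), nbins = levels * levels)
  P <- matrix(counts, levels, levels)
  P <- P + t(P)
  P / sum(P)
}

# 13 Haralick statistics of one normalized symmetric GLCM. Entropies use
# the natural logarithm with 0 log 0 = 0. Degenerate cases (zero variance)
# yield the documented sentinel 0 for correlation/IMC terms.
.haralick13 <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  variance <- sig2
  idm <- sum(P / (1 + (i - j)^2))
  # sum / difference distributions
  s <- as.vector(i + j)
  d <- as.vector(abs(i - j))
  psum <- vapply(2:(2 * L), function(k) sum(P[s == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(P[d == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sum_average <- sum(ks * psum)
  sum_entropy <- -sum(xlogx(psum))
  sum_variance <- sum((ks - sum_average)^2 * psum)
  entropy <- -sum(xlogx(P))
  diff_average <- sum(kd * pdiff)
  diff_variance <- sum((kd - diff_average)^2 * pdiff)
  diff_entropy <- -sum(xlogx(pdiff))
  # information measures of correlation
  py <- colSums(P)
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxy > 0, P * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}

# offsets in (dr, dc) for the four standard GLCM angles at distance d:
# 0 deg = horizontal, 90 deg = vertical, 45/135 the diagonals.
.glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0),
         "135" = c(-d, -d))
}

#' Texture features of a masked cell image
#'
#' Haralick statistics are computed from symmetric, normalized GLCMs with
#' 8 gray levels quantized over the masked intensity range; only pixel
#' pairs with both ends inside the mask contribute. When the mask is too
#' small to contain any pair at an offset, the 13 affected values are set
#' to the sentinel 0. Gabor energy is the mean modulus of the complex
#' Gabor response over the mask.
#'
#' @param image numeric matrix of intensities.
#' @param mask logical matrix, same shape; area must be >= 16 px.
#' @param quantization number of gray levels for the GLCM.
#' @return named numeric vector of length 452.
#' @export
texture_features <- function(image, mask, quantization = 8) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)))
  mask <- mask > 0
  if (sum(mask) < 16) stop("mask area < 16 px")
  q <- .glcm_quantize(image, mask, quantization)
  har <- unlist(lapply(.glcm_distances, function(d)
    unlist(lapply(.glcm_angles, function(a) {
      off <- .glcm_offset(a, d)
      P <- .glcm(q, off[1], off[2], quantization)
      v <- if (is.null(P)) {
        .ms_log("texture: no valid pair at d=%d a=%d, sentinel 0", d, a)
        stats::setNames(numeric(13), .haralick_stats)
      } else .haralick13(P)
      names(v) <- sprintf("haralick_%s_d%02d_a%03d", .haralick_stats, d, a)
      v
    }))))
  gab <- .gabor_energies(image, mask)
  out <- c(har, gab)
  out[!is.finite(out)] <- 0
  out
}

# complex Gabor filter bank; energy = mean modulus over the mask.
# sigma = 0.56 * wavelength (one-octave bandwidth), kernel truncated at
# +/- 2.5 sigma and clipped to the image size.
.gabor_energies <- function(image, mask) {
  h <- nrow(image); w <- ncol(image)
  vals <- unlist(lapply(.gabor_wavelengths, function(wl) {
    sig <- 0.56 * wl
    r <- min(ceiling(2.5 * sig), (min(h, w) - 1) %/% 2)
    g <- seq(-r, r)
    X <- matrix(g, length(g), length(g), byrow = TRUE)  # column coordinate
    Y <- matrix(g, length(g), length(g))                # row coordinate
    vapply(.gabor_angles, function(a) {
      th <- a * pi / 180
      xr <- X * cos(th) + Y * sin(th)
      yr <- -X * sin(th) + Y * cos(th)
      env <- exp(-(xr^2 + 0.25 * yr^2) / (2 * sig^2))  # aspect ratio 0.5
      kr <- env * cos(2 * pi * xr / wl)
      ki <- env * sin(2 * pi * xr / wl)
      re <- .conv2_same(image, kr)
      im <- .conv2_same(image, ki)
      mean(sqrt(re[mask]^2 + im[mask]^2))
    }, numeric(1))
  }))
  names(vals) <- unlist(lapply(.gabor_wavelengths, function(wl)
    sprintf("gabor_w%02g_a%03d", wl, .gabor_angles)))
  vals
}

# 2-D convolution keeping the input size (EBImage filter2 is FFT-based
# circular convolution; adequate here because crops carry a background
# border)
.conv2_same <- function(m, k) {
  t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(m)), t(k))))
}
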