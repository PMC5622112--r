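## Granularity features (registry 44-53): 10-scale granular spectrum by
## iterated morphological opening with disc structuring elements.

#' Granular spectrum of the masked intensity image
#'
#' At each scale \eqn{s = 1..10}, the value is the fraction of the total
#' masked intensity removed between openings with disc radii \eqn{s-1} and
#' \eqn{s} (radius 0 = original image). Values are non-negative and their
#' cumulative sum is at most 1; a constant-intensity cell yields an
#' all-zero spectrum.
#'
#' @param image numeric matrix of intensities in \[0, 1\].
#' @param mask logical matrix, same shape, nonempty.
#' @param scales number of radii (fixed at 10 in the registry).
#' @return numeric vector `granularity_01` .. `granularity_10`.
#' @export
granularity_features <- function(image, mask, scales = 10) {
  stopifnot(is.matrix(image), is.matrix(mask),
            all(dim(image) == dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  masked <- image * mask
  total <- sum(masked)
  if (total <= 0) stop("zero total intensity inside the mask")
  img <- EBImage::Image(t(masked))
  prev <- total
  out <- numeric(scales)
  for (s in seq_len(scales)) {
    brush <- EBImage::makeBrush(2 * s + 1, shape = "disc")
    opened <- EBImage::opening(img, brush)
    cur <- sum(t(EBImage::imageData(opened))[mask])
    out[s] <- max(0, (prev - cur) / total)
    prev <- min(prev, cur)
  }
  names(out) <- sprintf("granularity_%02d", seq_len(scales))
  out
}
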