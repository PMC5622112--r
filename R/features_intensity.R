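## Intensity features (registry 54-96): 10 whole-mask statistics, the same
## 10 on the 1-px boundary ring, mass displacement, intensity-weighted
## centroid, and a 20-value radial profile (mean and CV in 10 concentric
## equal-area rings around the binary centroid).

.int_stats <- function(v, prefix) {
  if (length(v) == 0) v <- 0
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  out <- c(integrated = sum(v), mean = mean(v), median = median(v),
           std = if (length(v) > 1) sd(v) else 0,
           mad = mad(v), min = min(v), max = max(v),
           q25 = q[1], q75 = q[2], iqr = q[2] - q[1])
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Intensity features of a masked cell image
#'
#' @param image numeric matrix of intensities.
#' @param mask logical matrix, same shape, nonempty.
#' @return named numeric vector of length 43.
#' @export
intensity_features <- function(image, mask) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  v <- image[mask]
  whole <- .int_stats(v, "int")
  # 1-px boundary ring: mask minus its erosion
  er <- .erode1(mask)
  ring <- mask & !er
  edge <- .int_stats(image[ring], "edge")
  # centroids: binary vs intensity-weighted
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  wsum <- sum(v)
  if (wsum > 0) {
    wy <- sum(idx[, 1] * v) / wsum
    wx <- sum(idx[, 2] * v) / wsum
  } else { wy <- cy; wx <- cx }
  md <- sqrt((wy - cy)^2 + (wx - cx)^2)
  # radial profile: 10 concentric equal-area rings by radius quantile
  rad <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  br <- quantile(rad, probs = seq(0, 1, length.out = 11), type = 7)
  bin <- cut(rad, breaks = unique(br), include.lowest = TRUE,
             labels = FALSE)
  rmean <- rcv <- numeric(10)
  for (k in 1:10) {
    vk <- v[which(bin == k)]
    if (length(vk) == 0) { rmean[k] <- 0; rcv[k] <- 0; next }
    m <- mean(vk)
    rmean[k] <- m
    rcv[k] <- if (length(vk) > 1 && m != 0) sd(vk) / m else 0
  }
  names(rmean) <- sprintf("radial_mean_%02d", 1:10)
  names(rcv) <- sprintf("radial_cv_%02d", 1:10)
  out <- c(whole, edge,
           mass_displacement = md, centroid_x = wx, centroid_y = wy,
           rmean, rcv)
  out[!is.finite(out)] <- 0
  out
}

# binary erosion by the 4-connected unit cross
.erode1 <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  mask &
    pad[1:nrow(mask), 2:(ncol(mask) + 1)] &
    pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)] &
    pad[2:(nrow(mask) + 1), 1:ncol(mask)] &
    pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
}
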