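## Geometry features (registry 1-43): 13 shape scalars followed by 30
## Zernike moment magnitudes (orders 0-9, non-negative repetitions of equal
## parity), computed on the binary mask scaled to its enclosing circle.

#' Geometry features of a cell mask
#'
#' The 13 shape scalars are: area (px), perimeter (corner-corrected chain
#' code), form factor \eqn{4\pi A / P^2}, solidity (area / convex hull
#' area), extent (area / bounding box), eccentricity, major and minor axis
#' lengths (from second central moments), orientation (rad), compactness
#' \eqn{P^2 / 4\pi A}, equivalent diameter, and max/min Feret diameters
#' (rotating calipers on the convex hull). They are followed by 30 Zernike
#' magnitudes.
#'
#' @param mask logical matrix with a single connected component.
#' @return named numeric vector of length 43.
#' @export
geometry_features <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  A <- nrow(idx)
  r <- idx[, 1]; c <- idx[, 2]
  cy <- mean(r); cx <- mean(c)
  # second central moments (+1/12 per-pixel for pixel extent)
  mu20 <- mean((c - cx)^2) + 1 / 12
  mu02 <- mean((r - cy)^2) + 1 / 12
  mu11 <- mean((c - cx) * (r - cy))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  P <- .mask_perimeter(mask)
  bb <- (diff(range(r)) + 1) * (diff(range(c)) + 1)
  hull <- .mask_hull(idx)
  feret <- .feret_diameters(hull)
  hull_area <- .polygon_area(hull) + .polygon_perimeter(hull) / 2 + 1
  shape <- c(
    area = A, perimeter = P,
    form_factor = 4 * pi * A / P^2,
    solidity = min(1, A / hull_area),
    extent = A / bb, eccentricity = ecc,
    major_axis_length = major, minor_axis_length = minor,
    orientation = orient,
    compactness = P^2 / (4 * pi * A),
    equivalent_diameter = 2 * sqrt(A / pi),
    feret_max = unname(feret[1]), feret_min = unname(feret[2]))
  zk <- .zernike_magnitudes(idx, cy, cx)
  out <- c(shape, zk)
  out[!is.finite(out)] <- 0
  out
}

# chain-code perimeter with Vossepoel-Smeulders weights (0.980 straight,
# 1.406 diagonal) on the 8-connected outer boundary; accurate to ~1% on
# digital disks of radius >= 10.
.mask_perimeter <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  inner <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] &
    pad[1:nrow(mask), 2:(ncol(mask) + 1)] &
    pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)] &
    pad[2:(nrow(mask) + 1), 1:ncol(mask)] &
    pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  bidx <- which(mask & !inner, arr.ind = TRUE)
  nb <- nrow(bidx)
  if (nb <= 1) return(max(1, 4 * nb))
  # order boundary pixels by angle around the centroid (valid for
  # star-convex shapes, which segmented single cells are in practice)
  cy <- mean(bidx[, 1]); cx <- mean(bidx[, 2])
  o <- order(atan2(bidx[, 1] - cy, bidx[, 2] - cx))
  b <- bidx[o, , drop = FALSE]
  d <- sqrt(diff(c(b[, 1], b[1, 1]))^2 + diff(c(b[, 2], b[1, 2]))^2)
  # map steps to corrected weights; longer jumps kept as Euclidean length
  w <- ifelse(abs(d - 1) < 1e-9, 0.980,
              ifelse(abs(d - sqrt(2)) < 1e-9, 1.406, d))
  sum(w)
}

.mask_hull <- function(idx) {
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}

.polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.polygon_perimeter <- function(p) {
  n <- nrow(p)
  if (n < 2) return(0)
  sum(sqrt(diff(c(p[, 1], p[1, 1]))^2 + diff(c(p[, 2], p[1, 2]))^2))
}

# max Feret = hull diameter; min Feret = minimal width over hull edge
# directions (+1 px for pixel extent on both)
.feret_diameters <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(c(feret_max = 1, feret_min = 1))
  dmax <- max(stats::dist(hull))
  if (n < 3) return(c(feret_max = dmax + 1, feret_min = 1))
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- hull %*% nrm
    diff(range(proj))
  }, numeric(1))
  c(feret_max = dmax + 1, feret_min = min(widths) + 1)
}

# Zernike radial polynomial R_nm(rho)
.zernike_radial <- function(n, m, rho) {
  s <- 0:((n - m) / 2)
  coef <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
  out <- numeric(length(rho))
  for (i in seq_along(s)) out <- out + coef[i] * rho^(n - 2 * s[i])
  out
}

# Zernike moment magnitudes of the binary mask, mapped to the unit disk by
# centroid and maximal centroid-to-pixel distance (enclosing circle).
.zernike_magnitudes <- function(idx, cy, cx) {
  y <- idx[, 1] - cy; x <- idx[, 2] - cx
  rad <- sqrt(x^2 + y^2)
  R <- max(rad) + 0.5
  rho <- rad / R
  theta <- atan2(y, x)
  npix <- length(rho)
  nm <- .zernike_nm
  vals <- vapply(seq_len(nrow(nm)), function(k) {
    n <- nm[k, "n"]; m <- nm[k, "m"]
    Rnm <- .zernike_radial(n, m, rho)
    re <- sum(Rnm * cos(m * theta))
    im <- -sum(Rnm * sin(m * theta))
    (n + 1) / pi * sqrt(re^2 + im^2) / npix
  }, numeric(1))
  names(vals) <- sprintf("zernike_%d_%d", nm[, "n"], nm[, "m"])
  vals
}
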