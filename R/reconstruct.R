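#' Stack a 1-D line-scan waveform into 2-D frames
#'
#' Rebuilds image frames from a serialized line-scan stream by cutting the
#' waveform into lines of `samples_per_line` samples and stacking
#' `lines_per_frame` consecutive lines per frame, in acquisition order.
#' A trailing partial frame is discarded with a warning.
#'
#' @param waveform numeric vector; its length must be divisible by
#'   `samples_per_line`.
#' @param samples_per_line samples in one line (frame width).
#' @param lines_per_frame lines in one frame (frame height).
#' @return list of `lines_per_frame x samples_per_line` matrices.
#' @examples
#' stack_linescans(0:5, samples_per_line = 3, lines_per_frame = 2)
#' @export
stack_linescans <- function(waveform, samples_per_line, lines_per_frame) {
  stopifnot(is.numeric(waveform), samples_per_line >= 1, lines_per_frame >= 1)
  if (length(waveform) %% samples_per_line != 0)
    stop("waveform length (", length(waveform),
         ") is not divisible by samples_per_line (", samples_per_line, ")")
  n_lines <- length(waveform) %/% samples_per_line
  n_frames <- n_lines %/% lines_per_frame
  if (n_lines %% lines_per_frame != 0)
    warning("discarding trailing partial frame (",
            n_lines %% lines_per_frame, " lines)")
  if (n_frames == 0) return(list())
  keep <- waveform[seq_len(n_frames * lines_per_frame * samples_per_line)]
  lapply(seq_len(n_frames), function(i) {
    off <- (i - 1) * lines_per_frame * samples_per_line
    matrix(keep[off + seq_len(lines_per_frame * samples_per_line)],
           nrow = lines_per_frame, ncol = samples_per_line, byrow = TRUE)
  })
}

#' Flag frames that contain an object
#'
#' A frame is flagged when its intensity range after 3x3 median filtering
#' exceeds `min_contrast`; empty (background-only) frames fall below the
#' threshold.
#'
#' @param frames nonempty list of frame matrices.
#' @param min_contrast normalized intensity threshold (0 returns every
#'   frame).
#' @return integer indices of flagged frames (possibly empty).
#' @export
detect_cell_frames <- function(frames, min_contrast = 0.1) {
  stopifnot(length(frames) >= 1, min_contrast >= 0)
  flag <- vapply(frames, function(f) {
    med <- .median3x3(f)
    diff(range(med)) >= min_contrast
  }, logical(1))
  which(flag)
}

# 3x3 median filter with edge replication
.median3x3 <- function(m) {
  img <- EBImage::medianFilter(EBImage::Image(t(m)), size = 1)
  t(EBImage::imageData(img))
}

#' Segment the single cell in a frame
#'
#' Standard chain: per-frame min-max normalization, global Otsu threshold,
#' morphological closing (disc radius `close_radius`), hole filling,
#' largest connected component, minimum-area filter; the result is cropped
#' to a fixed `crop_size` window centred on the mask centroid and padded
#' with the frame's median background where the window leaves the frame.
#'
#' @param frame numeric matrix (one reconstructed frame).
#' @param min_area smallest acceptable component area (px).
#' @param crop_size side of the square crop window (px).
#' @param close_radius disc radius of the morphological closing (px).
#' @return a `cell_image` (pixels + mask + provenance), or `NULL` with a
#'   message when no component survives ("no cell found").
#' @export
segment_cell <- function(frame, min_area = 50, crop_size = 64,
                         close_radius = 2) {
  stopifnot(is.matrix(frame), min_area >= 1, crop_size >= 8)
  rng <- range(frame)
  if (rng[2] - rng[1] <= 0) {
    .ms_log("segment_cell: flat frame, no cell found")
    return(NULL)
  }
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  # light smoothing suppresses texture/noise jitter on the threshold
  # contour; the returned pixels stay unsmoothed
  norm <- .gauss_blur(norm, 0.8)
  img <- EBImage::Image(t(norm))           # EBImage is x = column major
  # Otsu initialization refined by IsoData (Ridler-Calvard): with a
  # dominant background mode Otsu lands off the half-rise point of a
  # blurred edge; iterating to the midpoint of the class means fixes that
  thr <- EBImage::otsu(img, range = c(0, 1))
  v <- as.vector(norm)
  for (it in 1:50) {
    newt <- (mean(v[v < thr]) + mean(v[v >= thr])) / 2
    if (!is.finite(newt) || abs(newt - thr) < 1e-6) break
    thr <- newt
  }
  bw <- img > thr
  # bright-field cells may be darker than background; segment the side
  # with the smaller pixel fraction (the object, in a dilute frame)
  if (mean(bw) > 0.5) bw <- !bw
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
  bw <- EBImage::closing(bw, brush)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0 || max(tab) < min_area) {
    .ms_log("segment_cell: no component >= %d px, no cell found", min_area)
    return(NULL)
  }
  keep <- which.max(tab)                   # largest component only
  mask_t <- EBImage::imageData(lab) == keep
  mask <- t(mask_t)                        # back to row-major matrix
  idx <- which(mask, arr.ind = TRUE)
  cy <- round(mean(idx[, 1])); cx <- round(mean(idx[, 2]))
  half <- crop_size %/% 2
  rows <- (cy - half + 1):(cy - half + crop_size)
  cols <- (cx - half + 1):(cx - half + crop_size)
  bg <- stats::median(frame[!mask])
  crop_px <- matrix(bg, crop_size, crop_size)
  crop_mk <- matrix(FALSE, crop_size, crop_size)
  rin <- rows >= 1 & rows <= nrow(frame)
  cin <- cols >= 1 & cols <= ncol(frame)
  crop_px[rin, cin] <- frame[rows[rin], cols[cin]]
  crop_mk[rin, cin] <- mask[rows[rin], cols[cin]]
  structure(list(pixels = crop_px, mask = crop_mk,
                 truth = NULL,
                 provenance = list(offset = c(row = rows[1] - 1L,
                                              col = cols[1] - 1L),
                                   area = sum(crop_mk),
                                   threshold = as.numeric(thr))),
            class = "cell_image")
}

#' Place a segmented cell's mask back into frame coordinates
#'
#' Uses the crop offset recorded in the cell's provenance to express the
#' mask in the coordinates of the source frame (e.g. to compare against a
#' generator's ground-truth mask).
#'
#' @param cell a `cell_image` returned by [segment_cell()].
#' @param frame_dim integer c(rows, cols) of the source frame.
#' @return logical matrix of dimension `frame_dim`.
#' @export
mask_in_frame <- function(cell, frame_dim) {
  stopifnot(inherits(cell, "cell_image"), !is.null(cell$provenance))
  off <- cell$provenance$offset
  out <- matrix(FALSE, frame_dim[1], frame_dim[2])
  rr <- (off[1] + 1):(off[1] + nrow(cell$mask))
  cc <- (off[2] + 1):(off[2] + ncol(cell$mask))
  ok_r <- rr >= 1 & rr <= frame_dim[1]
  ok_c <- cc >= 1 & cc <= frame_dim[2]
  out[rr[ok_r], cc[ok_c]] <- cell$mask[ok_r, ok_c]
  out
}

#' Reconstruct and segment every cell in a waveform
#'
#' Convenience wrapper: [stack_linescans()], [detect_cell_frames()], then
#' [segment_cell()] on each flagged frame; frames without an acceptable
#' component are skipped and counted.
#'
#' @inheritParams stack_linescans
#' @inheritParams segment_cell
#' @param min_contrast passed to [detect_cell_frames()].
#' @return list with `cells` (list of `cell_image`) and `stats`
#'   (frames seen / flagged / segmented).
#' @export
reconstruct_cells <- function(waveform, samples_per_line, lines_per_frame,
                              min_contrast = 0.1, min_area = 50,
                              crop_size = 64) {
  frames <- stack_linescans(waveform, samples_per_line, lines_per_frame)
  hit <- detect_cell_frames(frames, min_contrast)
  cells <- list()
  for (i in hit) {
    ci <- segment_cell(frames[[i]], min_area = min_area,
                       crop_size = crop_size)
    if (!is.null(ci)) {
      ci$provenance$frame <- i
      cells[[length(cells) + 1L]] <- ci
    }
  }
  list(cells = cells,
       stats = c(frames = length(frames), flagged = length(hit),
                 segmented = length(cells)))
}
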