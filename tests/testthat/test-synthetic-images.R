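test_that("noiseless, texture-free rendering is piecewise constant at intensity_mean", {
  ph <- phenotype_params(intensity_sd = 0, edge_sharpness = 0.3)
  acq <- acquisition_params(noise_sd = 0)
  cell <- render_cell_image(ph, acq, seed = 5)
  erode_n <- function(m, k) { for (i in seq_len(k)) m <- morphoscreen:::.erode1(m); m }
  deep <- erode_n(cell$mask, 2)           # interior, clear of the edge blur
  expect_true(all(abs(cell$pixels[deep] - ph$intensity_mean) < 1e-3))
  far <- erode_n(!cell$mask, 5)           # background, clear of the edge
  expect_true(all(abs(cell$pixels[far] - acq$background_level) < 1e-3))
})

test_that("zero eccentricity gives a disk: axis ratio within 2% by moment oracle", {
  ph <- phenotype_params(eccentricity = 0, mean_radius = 14)
  cell <- render_cell_image(ph, acquisition_params(noise_sd = 0), seed = 2)
  o <- moment_oracle(cell$mask)
  expect_lt(abs(o$ratio - 1), 0.02)
  expect_equal(o$area, pi * 14^2, tolerance = 0.02)
})

test_that("rendering is bit-identical for identical seed and parameters", {
  ph <- phenotype_params()
  acq <- acquisition_params()
  a <- render_cell_image(ph, acq, seed = 33)
  b <- render_cell_image(ph, acq, seed = 33)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  c <- render_cell_image(ph, acq, seed = 34)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("a cell larger than the frame is rejected", {
  ph <- phenotype_params(mean_radius = 40)
  expect_error(render_cell_image(ph, acquisition_params(frame_height = 64,
                                                        frame_width = 64)),
               "does not fit")
})

test_that("line-scan serialization round-trips through stack_linescans exactly", {
  acq <- acquisition_params(frame_height = 16, frame_width = 24)
  set.seed(4)
  frames <- replicate(3, matrix(runif(16 * 24), 16, 24), simplify = FALSE)
  wv <- render_linescan_stream(frames, acq, gap_lines = 0)
  expect_length(wv, 3 * 16 * 24)
  back <- stack_linescans(wv, samples_per_line = 24, lines_per_frame = 16)
  expect_identical(back, frames)
})

test_that("a constant frame serializes to a constant waveform of the right length", {
  acq <- acquisition_params(frame_height = 8, frame_width = 10)
  wv <- render_linescan_stream(list(matrix(0.3, 8, 10)), acq)
  expect_identical(wv, rep(0.3, 80))
})

test_that("two spaced cells produce exactly two above-background segments", {
  acq <- acquisition_params(frame_height = 64, frame_width = 64,
                            noise_sd = 0)
  cells <- lapply(c(7, 8), function(s)
    render_cell_image(phenotype_params(intensity_sd = 0), acq, seed = s))
  set.seed(1)
  gaps <- rpois(2, 40) + 64          # Poisson spacing, >= one frame apart
  wv <- render_linescan_stream(cells, acq, gap_lines = gaps, seed = 1)
  # independent segment-counting oracle: per-line maxima, then runs of
  # consecutive lines rising above background
  lines <- matrix(wv, ncol = acq$frame_width, byrow = TRUE)
  above <- apply(lines, 1, max) > acq$background_level + 0.1
  runs <- rle(above)
  expect_identical(sum(runs$values), 2L)
})

test_that("negative gaps (overlapping placements) are rejected", {
  acq <- acquisition_params()
  f <- matrix(0.2, 64, 64)
  expect_error(render_linescan_stream(list(f), acq, gap_lines = -3))
})
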