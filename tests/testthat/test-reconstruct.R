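test_that("stack_linescans cuts a waveform into row-major frames", {
  fr <- stack_linescans(c(0, 1, 2, 3, 4, 5), samples_per_line = 3,
                        lines_per_frame = 2)
  expect_length(fr, 1)
  expect_identical(fr[[1]], matrix(c(0, 1, 2, 3, 4, 5), 2, 3, byrow = TRUE))
})

test_that("indivisible waveform length is rejected; partial frames warn", {
  expect_error(stack_linescans(1:7, 3, 2), "not divisible")
  expect_warning(fr <- stack_linescans(1:9, 3, 2), "partial frame")
  expect_length(fr, 1)
})

test_that("constant waveforms stack to constant frames", {
  fr <- stack_linescans(rep(0.4, 60), 5, 4)
  expect_length(fr, 3)
  for (f in fr) expect_true(all(f == 0.4))
})

test_that("frame detection flags cell frames and passes over background", {
  acq <- acquisition_params(noise_sd = 0.01)
  set.seed(6)
  bg <- replicate(3, matrix(acq$background_level + rnorm(64 * 64, sd = 0.01),
                            64, 64), simplify = FALSE)
  expect_identical(detect_cell_frames(bg, min_contrast = 0.1), integer(0))
  cells <- lapply(4:6, function(s)
    render_cell_image(phenotype_params(), acq, seed = s)$pixels)
  expect_identical(detect_cell_frames(c(bg, cells), min_contrast = 0.1),
                   4:6)
  # degenerate threshold returns everything
  expect_identical(detect_cell_frames(bg, min_contrast = 0), 1:3)
})

test_that("a noiseless hard disk segments to its exact mask", {
  dk <- disk_mask(15)
  seg <- segment_cell(flat_frame(dk))
  expect_identical(mask_in_frame(seg, c(64, 64)), dk)
})

test_that("noisy rendered ellipses segment with IoU >= 0.95 against ground truth", {
  ious <- sapply(1:10, function(s) {
    cell <- render_cell_image(phenotype_params(eccentricity = 0.4),
                              acquisition_params(noise_sd = 0.02), seed = s)
    seg <- segment_cell(cell$pixels)
    mk <- mask_in_frame(seg, dim(cell$mask))
    sum(mk & cell$mask) / sum(mk | cell$mask)
  })
  expect_gte(median(ious), 0.95)
  expect_gt(min(ious), 0.90)
})

test_that("a blank frame yields the no-cell signal", {
  expect_null(segment_cell(matrix(0.2, 64, 64)))
})

test_that("segmentation is translation-equivariant within crop bounds", {
  dk <- disk_mask(10, cy = 28, cx = 26)
  sh <- disk_mask(10, cy = 34, cx = 37)   # same disk, shifted (+6, +11)
  s1 <- segment_cell(flat_frame(dk), crop_size = 40)
  s2 <- segment_cell(flat_frame(sh), crop_size = 40)
  # centroid-centred crops make the shifted masks identical
  expect_identical(s1$mask, s2$mask)
  off <- s2$provenance$offset - s1$provenance$offset
  expect_equal(unname(off), c(6, 11))
})

test_that("nearly all generated frames yield exactly one accepted cell", {
  m <- dose_response_model()
  acq <- acquisition_params(noise_sd = 0.02)
  n_ok <- 0; n_tot <- 0
  for (dose in m$doses) {
    ph <- sample_phenotype(m, dose, 24, n = 10, seed = 77 + round(dose * 1e9))
    for (j in seq_len(nrow(ph))) {
      cell <- render_cell_image(ph[j, ], acq, seed = 1000 + j)
      seg <- segment_cell(cell$pixels)
      n_tot <- n_tot + 1
      if (!is.null(seg)) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.99)
})
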