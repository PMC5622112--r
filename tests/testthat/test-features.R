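test_that("the registry has 548 uniquely named features at the fixed index ranges", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 548L)
  expect_identical(reg$index, 1:548)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_identical(unique(reg$category[1:43]), "geometry")
  expect_identical(unique(reg$category[44:53]), "granularity")
  expect_identical(unique(reg$category[54:96]), "intensity")
  expect_identical(unique(reg$category[97:548]), "texture")
})

test_that("geometry of a disk matches the pixel-count and second-moment oracles", {
  g <- geometry_features(disk_mask(20))
  expect_equal(unname(g["area"]), pi * 20^2, tolerance = 0.02)
  expect_lte(unname(g["eccentricity"]), 0.05)
  expect_lt(abs(g["form_factor"] - 1), 0.05)
  expect_equal(unname(g["equivalent_diameter"]), 40, tolerance = 0.02)
  expect_equal(unname(g["feret_max"]), 41, tolerance = 0.03)
  # rotationally symmetric mask: all nonzero-repetition Zernike magnitudes
  # vanish
  nonzero_m <- grepl("zernike_[0-9]_[1-9]", names(g))
  expect_lt(max(g[nonzero_m]), 0.02)
  expect_error(geometry_features(matrix(FALSE, 8, 8)), "empty mask")
})

test_that("a 2:1 ellipse has a 2:1 axis ratio by the moment oracle", {
  g <- geometry_features(ellipse_mask(24, 12))
  ratio <- g["major_axis_length"] / g["minor_axis_length"]
  expect_lt(abs(ratio - 2), 0.06)
  o <- moment_oracle(ellipse_mask(24, 12))
  expect_equal(unname(g["major_axis_length"]), o$major, tolerance = 1e-6)
})

test_that("geometry scales correctly: double the radius, 4x area and 2x perimeter", {
  g1 <- geometry_features(disk_mask(10, n = 96))
  g2 <- geometry_features(disk_mask(20, n = 96))
  expect_equal(unname(g2["area"] / g1["area"]), 4, tolerance = 0.03)
  expect_equal(unname(g2["perimeter"] / g1["perimeter"]), 2, tolerance = 0.03)
})

test_that("granular spectrum is zero for constant cells and bounded by 1", {
  dk <- disk_mask(18)
  g <- granularity_features(flat_frame(dk, fg = 0.5, bg = 0), dk)
  expect_length(g, 10)
  expect_true(all(g == 0))
  cell <- render_cell_image(phenotype_params(), acquisition_params(), seed = 8)
  g2 <- granularity_features(cell$pixels, cell$mask)
  expect_true(all(g2 >= 0))
  expect_lte(sum(g2), 1)
  expect_error(granularity_features(flat_frame(dk, fg = 0, bg = 0), dk),
               "zero total intensity")
})

test_that("bright grains of radius 3 concentrate spectrum mass at scale 3 +/- 1", {
  img <- matrix(0, 64, 64)
  mk <- matrix(TRUE, 64, 64)
  for (cy in c(12, 32, 52)) for (cx in c(12, 32, 52))
    img[disk_mask(3, n = 64, cy = cy, cx = cx)] <- 1
  g <- granularity_features(img, mk)
  expect_gt(sum(g[2:4]), 0.8 * sum(g))
})

test_that("intensity features satisfy their closed-form cases", {
  dk <- disk_mask(15)
  f <- intensity_features(flat_frame(dk, fg = 0.5, bg = 0.1), dk)
  expect_equal(unname(f["int_mean"]), 0.5)
  expect_equal(unname(f["int_median"]), 0.5)
  expect_equal(unname(f["int_std"]), 0)
  expect_equal(unname(f["int_mad"]), 0)
  expect_equal(unname(f["mass_displacement"]), 0)
  # linear ramp: integrated intensity equals the direct masked sum exactly
  ramp <- matrix(seq(0, 1, length.out = 64), 64, 64, byrow = TRUE)
  f2 <- intensity_features(ramp, dk)
  expect_identical(unname(f2["int_integrated"]), sum(ramp[dk]))
  # symmetric Gaussian spot centred on the mask centroid
  yy <- row(ramp) - 32.5; xx <- col(ramp) - 32.5
  spot <- exp(-(xx^2 + yy^2) / 50)
  f3 <- intensity_features(spot, dk)
  expect_lte(unname(f3["mass_displacement"]), 0.5)
})

test_that("Haralick features match hand-computed GLCM values on toy patches", {
  # constant patch: ASM = 1, contrast = 0 at every offset/distance
  dk <- disk_mask(10, n = 32)
  tx <- texture_features(flat_frame(dk, fg = 0.7, bg = 0), dk)
  expect_length(tx, 452)
  asm <- tx[grep("haralick_asm", names(tx))]
  ctr <- tx[grep("haralick_contrast", names(tx))]
  expect_true(all(abs(asm - 1) < 1e-12))
  expect_true(all(ctr == 0))
  # 4x4 alternating patch, distance 1, 0 deg: exact hand computation.
  # quantized levels alternate 1,8 along rows -> all horizontal pairs are
  # (1,8) or (8,1): P is 0.5 at the two off-diagonal cells,
  # ASM = 0.5, contrast = 49, entropy = log 2
  patch <- matrix(c(0, 1), 4, 4, byrow = TRUE)  # rows alternate 0,1,0,1
  mk4 <- matrix(TRUE, 4, 4)
  q <- morphoscreen:::.glcm_quantize(patch, mk4, 8)
  P <- morphoscreen:::.glcm(q, 0, 1, 8)
  h <- morphoscreen:::.haralick13(P)
  expect_equal(unname(h["asm"]), 0.5)
  expect_equal(unname(h["contrast"]), 49)
  expect_equal(unname(h["entropy"]), log(2))
})

test_that("GLCM agrees exactly with a brute-force co-occurrence oracle", {
  set.seed(5)
  img <- matrix(runif(64), 8, 8)
  mk <- matrix(TRUE, 8, 8); mk[1, 1] <- FALSE
  q <- morphoscreen:::.glcm_quantize(img, mk, 8)
  for (off in list(c(0, 1), c(-1, 1), c(-1, 0), c(-2, -2))) {
    P <- morphoscreen:::.glcm(q, off[1], off[2], 8)
    # brute-force loop over all pixel pairs
    cnt <- matrix(0, 8, 8)
    for (r in 1:8) for (c in 1:8) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= 8 && c2 >= 1 && c2 <= 8 &&
          !is.na(q[r, c]) && !is.na(q[r2, c2])) {
        cnt[q[r, c], q[r2, c2]] <- cnt[q[r, c], q[r2, c2]] + 1
        cnt[q[r2, c2], q[r, c]] <- cnt[q[r2, c2], q[r, c]] + 1
      }
    }
    expect_equal(P, cnt / sum(cnt))
  }
})

test_that("checkerboard texture has higher contrast than blurred noise", {
  mk <- disk_mask(12, n = 32)
  chk <- (row(matrix(0, 32, 32)) + col(matrix(0, 32, 32))) %% 2
  t1 <- texture_features(chk, mk)
  set.seed(3)
  sm <- morphoscreen:::.gauss_blur(matrix(rnorm(32 * 32), 32, 32), 2)
  t2 <- texture_features((sm - min(sm)) / diff(range(sm)), mk)
  expect_gt(t1["haralick_contrast_d01_a000"],
            t2["haralick_contrast_d01_a000"])
})

test_that("extract_features returns 548 finite values with correct category slices", {
  cell <- render_cell_image(phenotype_params(), acquisition_params(), seed = 19)
  fv <- extract_features(cell)
  expect_length(fv, 548)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_registry()$name)
  # deterministic
  expect_identical(fv, extract_features(cell))
})

test_that("features are stable under 90-degree rotation of the cell", {
  cell <- render_cell_image(phenotype_params(eccentricity = 0),
                            acquisition_params(noise_sd = 0), seed = 23)
  rot <- list(pixels = t(cell$pixels[nrow(cell$pixels):1, ]),
              mask = t(cell$mask[nrow(cell$mask):1, ]))
  f1 <- extract_features(cell)
  f2 <- extract_features(rot)
  for (nm in c("area", "int_q25", "int_q75", "int_median"))
    expect_equal(unname(f1[nm]), unname(f2[nm]), tolerance = 0.01)
  gr <- grep("granularity", names(f1))
  expect_equal(unname(f1[gr]), unname(f2[gr]), tolerance = 0.01)
})

test_that("small masks are rejected for texture and sentinel rules apply", {
  mk <- matrix(FALSE, 16, 16); mk[8, 8] <- TRUE
  expect_error(texture_features(matrix(0.5, 16, 16), mk), "mask area")
})
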