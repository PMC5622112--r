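## Fixed 548-feature registry: 43 geometry (1-43), 10 granularity (44-53),
## 43 intensity (54-96), 452 texture (97-548). The composition is versioned
## and immutable: 13 shape scalars + 30 Zernike magnitudes; a 10-bin
## granular spectrum; 43 intensity scalars; 13 Haralick statistics x
## 4 offsets x 8 distances (416) + Gabor energy at 4 orientations x
## 9 wavelengths (36).

.haralick_stats <- c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "diff_variance", "diff_entropy", "imc1", "imc2")
.glcm_distances <- c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L)
.glcm_angles <- c(0L, 45L, 90L, 135L)
.gabor_wavelengths <- c(2, 3, 4, 5, 6, 8, 10, 12, 16)
.gabor_angles <- c(0L, 45L, 90L, 135L)

# Zernike (n, m) pairs: orders n = 0..9, repetitions m >= 0 of same parity
.zernike_nm <- local({
  nm <- do.call(rbind, lapply(0:9, function(n) {
    m <- seq(n %% 2, n, by = 2)
    cbind(n = rep(n, length(m)), m = m)
  }))
  stopifnot(nrow(nm) == 30)
  nm
})

#' The fixed 548-feature registry
#'
#' Ordered catalogue of every morphological feature the extractor produces:
#' indices 1-43 geometry (13 shape scalars + 30 Zernike moment magnitudes),
#' 44-53 granularity (10-scale granular spectrum), 54-96 intensity
#' (43 scalars) and 97-548 texture (13 Haralick statistics at 4 offsets x
#' 8 distances, plus 36 Gabor energies). The order is immutable across runs;
#' feature tables and weight vectors are always in registry order.
#'
#' @return data.frame with columns `index`, `name`, `category`, `params`.
#' @examples
#' reg <- feature_registry()
#' table(reg$category)
#' @export
feature_registry <- function() {
  if (is.null(.registry_env$reg)) .registry_env$reg <- .build_registry()
  .registry_env$reg
}
.registry_env <- new.env(parent = emptyenv())

.build_registry <- function() {
  shape <- c("area", "perimeter", "form_factor", "solidity", "extent",
             "eccentricity", "major_axis_length", "minor_axis_length",
             "orientation", "compactness", "equivalent_diameter",
             "feret_max", "feret_min")
  zk <- sprintf("zernike_%d_%d", .zernike_nm[, "n"], .zernike_nm[, "m"])
  geometry <- c(shape, zk)
  granularity <- sprintf("granularity_%02d", 1:10)
  istats <- c("integrated", "mean", "median", "std", "mad", "min", "max",
              "q25", "q75", "iqr")
  intensity <- c(paste0("int_", istats), paste0("edge_", istats),
                 "mass_displacement", "centroid_x", "centroid_y",
                 sprintf("radial_mean_%02d", 1:10),
                 sprintf("radial_cv_%02d", 1:10))
  # order: distance (outer), angle, statistic (inner)
  har <- unlist(lapply(.glcm_distances, function(d)
    unlist(lapply(.glcm_angles, function(a)
      sprintf("haralick_%s_d%02d_a%03d", .haralick_stats, d, a)))))
  gab <- unlist(lapply(.gabor_wavelengths, function(w)
    sprintf("gabor_w%02g_a%03d", w, .gabor_angles)))
  texture <- c(har, gab)
  nm <- c(geometry, granularity, intensity, texture)
  cat_ <- rep(c("geometry", "granularity", "intensity", "texture"),
              c(length(geometry), length(granularity), length(intensity),
                length(texture)))
  stopifnot(length(nm) == 548, !anyDuplicated(nm),
            sum(cat_ == "geometry") == 43, sum(cat_ == "granularity") == 10,
            sum(cat_ == "intensity") == 43, sum(cat_ == "texture") == 452)
  data.frame(index = seq_len(548), name = nm, category = cat_,
             params = "", stringsAsFactors = FALSE)
}

#' Column names of a feature table (f001..f548 plus metadata)
#' @keywords internal
.feature_colnames <- function() sprintf("f%03d", 1:548)

#' Export the feature registry as JSON
#'
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
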