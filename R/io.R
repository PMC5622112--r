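#' Write / read a feature table as delimited text
#'
#' Comma-delimited with header
#' `cell_id,experiment,duration_h,dose_M,label,f001..f548`.
#'
#' @param table feature-table data.frame.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  fc <- .feature_colnames()
  stopifnot(all(c("cell_id", "experiment", "duration_h", "dose_M",
                  "label", fc) %in% names(table)))
  utils::write.csv(table[c("cell_id", "experiment", "duration_h",
                           "dose_M", "label", fc)],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path file path.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(.feature_colnames() %in% names(tab)))
  tab
}

#' Serialize a linear SVM model to JSON
#'
#' Stores the weight vector `w`, bias `b`, the standardizer and training
#' metadata, mirroring the convention of publishing the fitted hyperplane
#' alongside results.
#'
#' @param model a `linear_svm`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "linear_svm"))
  obj <- list(w = unname(model$w), b = model$b,
              feature_names = names(model$w),
              standardizer = if (!is.null(model$standardizer))
                list(center = unname(model$standardizer$center),
                     scale = unname(model$standardizer$scale)),
              levels = model$levels, C = model$C, seed = model$seed,
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- NULL
  if (!is.null(obj$standardizer)) {
    std <- structure(
      list(center = obj$standardizer$center,
           scale = obj$standardizer$scale,
           zero_variance = rep(FALSE, length(obj$standardizer$center))),
      class = "standardizer")
  }
  structure(list(w = stats::setNames(obj$w, obj$feature_names), b = obj$b,
                 standardizer = std, levels = obj$levels, C = obj$C,
                 seed = obj$seed, epochs = NA_integer_,
                 meta = as.list(obj$meta)),
            class = "linear_svm")
}

#' Write a cell image (and its mask) as 16-bit grayscale TIFF
#'
#' Requires the `tiff` package. A JSON sidecar with the ground truth (if
#' present) is written next to the image.
#'
#' @param cell a `cell_image`.
#' @param path TIFF path for the pixel data; the mask goes to
#'   `*_mask.tiff` and the sidecar to `*.json`.
#' @return `path`, invisibly.
#' @export
write_cell_tiff <- function(cell, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  stopifnot(inherits(cell, "cell_image"))
  tiff::writeTIFF(cell$pixels, path, bits.per.sample = 16)
  stem <- sub("\\.tiff?$", "", path)
  tiff::writeTIFF(cell$mask * 1, paste0(stem, "_mask.tiff"),
                  bits.per.sample = 16)
  if (!is.null(cell$truth))
    jsonlite::write_json(cell$truth, paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
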