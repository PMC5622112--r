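#' Extract the full 548-feature profile of one cell
#'
#' Concatenates, in immutable registry order, the geometry (43),
#' granularity (10), intensity (43) and texture (452) features of a
#' segmented cell. Non-finite values arising from degenerate inputs are
#' replaced by the documented sentinel 0 inside the category extractors,
#' so the returned vector is always finite.
#'
#' @param cell a `cell_image` (from [render_cell_image()] or
#'   [segment_cell()]), or a list with `pixels` and `mask` matrices.
#' @return named numeric vector of length 548 in registry order.
#' @examples
#' cell <- render_cell_image(phenotype_params(), acquisition_params(), seed = 7)
#' fv <- extract_features(cell)
#' length(fv)  # 548
#' @export
extract_features <- function(cell) {
  stopifnot(is.list(cell), is.matrix(cell$pixels), is.matrix(cell$mask))
  v <- c(geometry_features(cell$mask),
         granularity_features(cell$pixels, cell$mask),
         intensity_features(cell$pixels, cell$mask),
         texture_features(cell$pixels, cell$mask))
  reg <- feature_registry()
  stopifnot(length(v) == 548, identical(names(v), reg$name))
  v
}

#' Extract features for a list of cells into a feature table
#'
#' @param cells list of `cell_image` objects.
#' @param meta data.frame with one row per cell (columns such as
#'   `experiment`, `duration_h`, `dose_M`, `label`); recycled defaults are
#'   used when absent.
#' @return data.frame in feature-table layout (`cell_id`, metadata,
#'   `f001`..`f548`).
#' @export
extract_feature_table <- function(cells, meta = NULL) {
  stopifnot(length(cells) >= 1)
  X <- t(vapply(cells, extract_features, numeric(548)))
  colnames(X) <- .feature_colnames()
  if (is.null(meta))
    meta <- data.frame(experiment = 1L, duration_h = NA_real_,
                       dose_M = NA_real_, label = NA_character_,
                       stringsAsFactors = FALSE)[rep(1, length(cells)), ]
  stopifnot(nrow(meta) == length(cells))
  cbind(data.frame(cell_id = sprintf("cell_%05d", seq_along(cells)),
                   stringsAsFactors = FALSE),
        meta, as.data.frame(X), row.names = NULL)
}
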