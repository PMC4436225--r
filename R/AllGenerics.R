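#' @import methods
NULL

#' Accessor generics for raster grids
#'
#' Small family of accessors shared by [GeoGrid-class] and
#' [CategoricalGrid-class]: the value matrix, the missing-data mask, the cell
#' size in metres, the top-left origin and the grid extent.
#'
#' @param x a grid object.
#' @name grid-accessors
#' @aliases gridValues cellSize origin nodataMask gridExtent
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname grid-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname grid-accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname grid-accessors
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' Nearest-neighbour resampling generic
#'
#' @param x a [GeoGrid-class] or [CategoricalGrid-class].
#' @param targetCellSize output cell edge in metres (> 0).
#' @return an object of the same class as `x` on the new cell size.
#' @seealso [resampleNearest,GeoGrid-method]
#' @export
setGeneric("resampleNearest",
           function(x, targetCellSize) standardGeneric("resampleNearest"))

#' Label-table accessor for categorical grids
#'
#' @param x a [CategoricalGrid-class].
#' @return named character vector mapping code (as name) to label.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
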