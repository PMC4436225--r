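# Core raster operations: nearest-neighbour resampling, temporal averaging,
# water masking. All operations propagate nodata and never invent values in
# masked cells.

# Map output pixel indices (1..nOut) to source pixel indices along one axis.
# Output pixel i (0-based) has centre (i + 0.5) * t; the nearest source centre
# is the source cell containing that point. When the point falls exactly on a
# source cell boundary the two neighbours are equidistant; the top-left (lower
# index) candidate wins. Indices beyond the source extent (padding) give NA.
.nnIndex <- function(nSrc, srcSize, outSize, nOut) {
  i <- seq_len(nOut) - 1
  r <- (2 * i + 1) * outSize / (2 * srcSize)   # centre in source-cell units
  j <- floor(r + 1e-9)
  tie <- abs(r - round(r)) < 1e-9 & round(r) >= 1
  j[tie] <- round(r[tie]) - 1
  j <- j + 1L
  j[j > nSrc] <- NA_integer_
  as.integer(j)
}

.resampleMatrix <- function(m, srcSize, targetCellSize) {
  if (!is.numeric(targetCellSize) || length(targetCellSize) != 1L ||
      !is.finite(targetCellSize) || targetCellSize <= 0)
    stop("targetCellSize must be a single positive number")
  extH <- nrow(m) * srcSize
  extW <- ncol(m) * srcSize
  nOutR <- as.integer(ceiling(extH / targetCellSize - 1e-9))
  nOutC <- as.integer(ceiling(extW / targetCellSize - 1e-9))
  ri <- .nnIndex(nrow(m), srcSize, targetCellSize, nOutR)
  ci <- .nnIndex(ncol(m), srcSize, targetCellSize, nOutC)
  out <- m[ri, ci, drop = FALSE]
  if (anyNA(ri)) out[is.na(ri), ] <- NA
  if (anyNA(ci)) out[, is.na(ci)] <- NA
  out
}

#' @describeIn resampleNearest continuous grid; each output pixel copies the
#'   source pixel whose centre is nearest its own centre (ties go top-left),
#'   so coarse-to-fine resampling is exact block replication. The extent is
#'   preserved (padded with nodata when not an integer multiple of the target
#'   cell size) and nodata propagates.
#' @export
setMethod("resampleNearest", "GeoGrid", function(x, targetCellSize) {
  geoGrid(.resampleMatrix(x@values, x@cellSize, targetCellSize),
          cellSize = targetCellSize, origin = x@origin)
})

#' @describeIn resampleNearest categorical grid; codes are copied, never
#'   interpolated, and the label table is preserved.
#' @export
setMethod("resampleNearest", "CategoricalGrid", function(x, targetCellSize) {
  categoricalGrid(.resampleMatrix(x@codes, x@cellSize, targetCellSize),
                  labels = x@labels, cellSize = targetCellSize,
                  origin = x@origin)
})

#' Per-pixel mean over the months of a stack
#'
#' Arithmetic mean of the unmasked monthly values at each pixel. A pixel is
#' masked in the output when fewer than `minValidMonths` months are valid
#' there. Used to build the summer (May-September) composites.
#'
#' @param stack a [MonthlyStack-class].
#' @param minValidMonths minimum valid months per pixel (default 1).
#' @return a [GeoGrid-class] aligned with the stack.
#' @examples
#' g <- function(v) geoGrid(matrix(v, 1, 1), 100)
#' s <- monthlyStack(list(g(20), g(22), g(24), g(26), g(28)))
#' gridValues(temporalMean(s))  # 24
#' @export
temporalMean <- function(stack, minValidMonths = 1L) {
  if (!is(stack, "MonthlyStack") || length(stack@grids) == 0L)
    stop("temporalMean needs a nonempty MonthlyStack")
  nm <- length(stack@grids)
  if (minValidMonths < 1L || minValidMonths > nm)
    stop("minValidMonths must lie in [1, number of months]")
  arr <- vapply(stack@grids, function(g) g@values,
                stack@grids[[1L]]@values)
  dim(arr) <- c(dim(stack@grids[[1L]]@values), nm)
  valid <- apply(!is.na(arr), c(1, 2), sum)
  m <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  m[valid < minValidMonths] <- NA
  m[valid == 0L] <- NA
  geoGrid(m, cellSize = cellSize(stack@grids[[1L]]),
          origin = origin(stack@grids[[1L]]))
}

#' Mask water surfaces out of a grid
#'
#' Pixels whose land-cover code is a water class become nodata; all other
#' pixels are unchanged. Water is excluded from the whole downscaling and
#' risk procedure.
#'
#' @param grid a [GeoGrid-class].
#' @param water an aligned [CategoricalGrid-class] of land-cover codes.
#' @param waterCodes integer codes treated as water (default 210, the
#'   Globcover water-bodies class).
#' @return the masked [GeoGrid-class].
#' @export
applyWaterMask <- function(grid, water, waterCodes = 210L) {
  if (!isAligned(grid, water))
    stop("applyWaterMask: grids are not aligned")
  v <- grid@values
  v[water@codes %in% waterCodes] <- NA
  geoGrid(v, cellSize = grid@cellSize, origin = grid@origin)
}

# Block mean over f x f cell blocks (exact factor); NA-aware. Internal: used
# by the scene generator to emulate the coarse LST sensor footprint.
.blockMean <- function(m, f) {
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * f + 1):(i * f)
    for (j in seq_len(nc)) {
      blk <- m[rows, ((j - 1) * f + 1):(j * f)]
      if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
    }
  }
  out
}
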