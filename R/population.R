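# Exposure (total population) and vulnerability (elderly population) layers.

#' Exposure layer: total population on the analysis mask
#'
#' Pass-through of the 100-m total-population grid with the mask harmonised
#' to the scene's analysis mask (water and other excluded pixels become
#' nodata). Population mass over the unmasked region is preserved.
#'
#' @param popTotal 100-m [GeoGrid-class], persons per cell.
#' @param analysisMask optional logical matrix (TRUE = excluded) or an
#'   aligned [CategoricalGrid-class] of land cover whose water pixels are
#'   excluded.
#' @param waterCodes water codes when `analysisMask` is a land-cover grid.
#' @return a [GeoGrid-class].
#' @export
exposureLayer <- function(popTotal, analysisMask = NULL,
                          waterCodes = 210L) {
  v <- popTotal@values
  if (!is.null(analysisMask)) {
    if (is(analysisMask, "CategoricalGrid")) {
      if (!isAligned(popTotal, analysisMask))
        stop("exposureLayer: mask grid not aligned with population")
      v[analysisMask@codes %in% waterCodes] <- NA
    } else {
      v[analysisMask] <- NA
    }
  }
  geoGrid(v, cellSize = popTotal@cellSize, origin = popTotal@origin)
}

#' Vulnerability layer: elderly population per pixel
#'
#' Multiplies each pixel's total population by the elderly fraction of the
#' municipality the pixel belongs to, so municipal elderly totals equal
#' `fraction x municipal population` exactly. Counts stay real-valued.
#'
#' @param popTotal 100-m [GeoGrid-class], persons per cell.
#' @param municipalities aligned [CategoricalGrid-class] of municipality
#'   codes.
#' @param fractions named numeric (names = municipality codes) of elderly
#'   fractions in [0, 1], or a data.frame with columns `municipality_id`
#'   and `fraction` (the elderly-fractions CSV layout).
#' @return a [GeoGrid-class] of elderly persons per cell.
#' @export
vulnerabilityLayer <- function(popTotal, municipalities, fractions) {
  if (!isAligned(popTotal, municipalities))
    stop("vulnerabilityLayer: grids are not aligned")
  if (is.data.frame(fractions))
    fractions <- structure(fractions$fraction,
                           names = as.character(fractions$municipality_id))
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("elderly fractions must lie in [0, 1]")
  codes <- municipalities@codes
  present <- unique(codes[!is.na(codes) & !is.na(popTotal@values)])
  missing <- setdiff(as.character(present), names(fractions))
  if (length(missing))
    stop("no elderly fraction for municipality code(s): ",
         paste(missing, collapse = ", "))
  f <- matrix(NA_real_, nrow(codes), ncol(codes))
  ok <- !is.na(codes)
  f[ok] <- fractions[as.character(codes[ok])]
  v <- popTotal@values * f
  # pixels with population but no municipality keep their mask from f;
  # pixels outside the analysis mask stay NA via popTotal
  geoGrid(v, cellSize = popTotal@cellSize, origin = popTotal@origin)
}

#' Read an elderly-fractions table
#'
#' CSV with columns `municipality_id,fraction`.
#'
#' @param path CSV path.
#' @return named numeric vector.
#' @export
readElderlyFractions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(tab$fraction, names = as.character(tab$municipality_id))
}
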