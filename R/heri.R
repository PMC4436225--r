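# Risk-triangle core: normalize hazard / exposure / vulnerability, combine
# with equal weights, classify into the five HERI levels.

#' Normalize a layer to the [0, 1] scale
#'
#' Default is min-max scaling `(x - min) / (max - min)` over the unmasked
#' pixels, which guarantees the 0-to-1 scale; `method = "range"` divides by
#' the range only (`x / (max - min)`), the literal divide-by-range variant.
#' Normalization is meant to be applied per city and per period.
#'
#' @param grid a [GeoGrid-class] with at least two distinct unmasked values.
#' @param method "minmax" (default) or "range".
#' @return the normalized [GeoGrid-class].
#' @export
normalizeLayer <- function(grid, method = c("minmax", "range")) {
  method <- match.arg(method)
  v <- grid@values
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) <= 0)
    stop("normalizeLayer: layer is constant; no risk gradient expressible")
  v <- if (method == "minmax") (v - rng[1L]) / diff(rng) else v / diff(rng)
  geoGrid(v, cellSize = grid@cellSize, origin = grid@origin)
}

#' Combine normalized layers into the risk index
#'
#' Exposure and vulnerability are first averaged into a single "exposed and
#' vulnerable" layer (each weighted 50%), which is then combined with the
#' hazard layer (weighted 50%):
#' `HERI = 0.5 H + 0.5 (0.5 E + 0.5 V) = 0.5 H + 0.25 E + 0.25 V`.
#' A convex combination, so the output stays within the pointwise range of
#' its inputs and in [0, 1] for normalized inputs.
#'
#' @param hazard,exposure,vulnerability aligned normalized
#'   [GeoGrid-class] layers.
#' @param config a [HeriConfig-class] (weights).
#' @return the HERI [GeoGrid-class].
#' @export
combineLayers <- function(hazard, exposure, vulnerability,
                          config = heriConfig()) {
  stopifnot(is(config, "HeriConfig"))
  validObject(config)
  if (!isAligned(hazard, exposure) || !isAligned(hazard, vulnerability))
    stop("combineLayers: layers are not aligned")
  ev <- config@wExposure * exposure@values +
    config@wVulnerability * vulnerability@values
  v <- config@wHazard * hazard@values + (1 - config@wHazard) * ev
  geoGrid(v, cellSize = hazard@cellSize, origin = hazard@origin)
}

#' Classify the risk index into five levels
#'
#' Splits HERI into five equal-risk levels: very low (HERI <= 0.2), low
#' (0.2 < HERI <= 0.4), moderate (0.4 < HERI <= 0.6), high
#' (0.6 < HERI <= 0.8) and very high (HERI > 0.8), coded 1..5. Nodata
#' propagates. Values outside [0, 1] beyond a 1e-9 tolerance are an error.
#'
#' @param heri the combined [GeoGrid-class] index.
#' @param config a [HeriConfig-class] (bounds and level names).
#' @return a [CategoricalGrid-class] with codes 1..5.
#' @export
classifyHeri <- function(heri, config = heriConfig()) {
  stopifnot(is(config, "HeriConfig"))
  v <- heri@values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("classifyHeri: values outside [0, 1]")
  v <- pmin(pmax(v, 0), 1)
  b <- config@levelBounds
  code <- matrix(1L, nrow(v), ncol(v))
  for (cut in b) code <- code + (v > cut)
  code[is.na(v)] <- NA_integer_
  categoricalGrid(code,
                  labels = structure(config@levelNames,
                                     names = as.character(1:5)),
                  cellSize = heri@cellSize, origin = heri@origin)
}

#' Full risk-index step: normalize, combine, classify
#'
#' Convenience wrapper running [normalizeLayer()] on the three raw layers,
#' [combineLayers()] and [classifyHeri()].
#'
#' @param hazard,exposure,vulnerability aligned raw [GeoGrid-class] layers.
#' @param config a [HeriConfig-class].
#' @return list with elements `heri` ([GeoGrid-class]) and `levels`
#'   ([CategoricalGrid-class]).
#' @export
heriIndex <- function(hazard, exposure, vulnerability,
                      config = heriConfig()) {
  h <- normalizeLayer(hazard, config@normalization)
  e <- normalizeLayer(exposure, config@normalization)
  v <- normalizeLayer(vulnerability, config@normalization)
  heri <- combineLayers(h, e, v, config)
  list(heri = heri, levels = classifyHeri(heri, config))
}
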