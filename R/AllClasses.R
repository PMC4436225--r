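# S4 data model. Grids store missing data as NA inside the value/code matrix;
# the nodata mask is derived, so mask and values can never disagree in shape.

#' GeoGrid: a continuous raster layer
#'
#' A 2-D numeric raster on a projected equal-area grid. Cells are square
#' (`cellSize` metres per edge), the origin is the top-left corner (x, y),
#' rows run north to south. Missing data are `NA` in `values`; every statistic
#' and model fit in the package skips them. Two grids are *aligned* iff they
#' share shape, cell size and origin.
#'
#' @slot values numeric matrix (rows x cols); `NA` marks nodata.
#' @slot cellSize positive scalar, metres per pixel edge.
#' @slot origin numeric length-2, (x, y) of the top-left corner in metres.
#' @export
setClass("GeoGrid",
         representation(values = "matrix", cellSize = "numeric",
                        origin = "numeric"))

setValidity("GeoGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite (x, y) pair")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' CategoricalGrid: an integer-coded raster layer
#'
#' Same spatial model as [GeoGrid-class] but holding integer class codes
#' (land cover, municipality id, risk level) plus a code-to-label table.
#' Every unmasked code must appear in the label table.
#'
#' @slot codes integer matrix; `NA` marks nodata.
#' @slot labels named character vector; names are the codes as strings.
#' @slot cellSize,origin as in [GeoGrid-class].
#' @export
setClass("CategoricalGrid",
         representation(codes = "matrix", labels = "character",
                        cellSize = "numeric", origin = "numeric"))

setValidity("CategoricalGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be a (x, y) pair")
  present <- unique(object@codes[!is.na(object@codes)])
  missing <- setdiff(as.character(present), names(object@labels))
  if (length(missing))
    msg <- c(msg, paste0("codes without a label: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' MonthlyStack: aligned monthly rasters
#'
#' An ordered set of aligned [GeoGrid-class] layers, one per calendar month
#' (5..9 for the May-September summer window). Month indices must be strictly
#' increasing.
#'
#' @slot months integer vector of month indices.
#' @slot grids list of aligned GeoGrid objects, same length as `months`.
#' @export
setClass("MonthlyStack",
         representation(months = "integer", grids = "list"))

setValidity("MonthlyStack", function(object) {
  msg <- character()
  if (length(object@months) != length(object@grids))
    msg <- c(msg, "months and grids differ in length")
  if (length(object@months) && any(diff(object@months) <= 0))
    msg <- c(msg, "months must be strictly increasing")
  if (!all(vapply(object@grids, is, logical(1), class2 = "GeoGrid")))
    msg <- c(msg, "grids must all be GeoGrid objects")
  if (length(object@grids) > 1L) {
    ok <- vapply(object@grids[-1L], isAligned, logical(1),
                 b = object@grids[[1L]])
    if (!all(ok)) msg <- c(msg, "all grids in a stack must be aligned")
  }
  if (length(msg)) msg else TRUE
})

#' ClassFit: a fitted per-land-cover-class LST ~ NDVI model
#'
#' One downscaling model for one land-cover class and one diurnal period,
#' either an ordinary linear regression ("LRM") or a penalized cubic
#' regression spline ("GAM"). Stores the fitted model object together with
#' its in-sample metrics: coefficient of determination, the linear slope
#' (LRM only, degrees C per unit NDVI), model significance and RMSE.
#'
#' @slot classCode integer land-cover code the fit belongs to.
#' @slot modelKind "LRM" or "GAM".
#' @slot model the underlying `lm` or `mgcv::gam` object.
#' @slot r2,pValue,rmse,nObs in-sample fit metrics.
#' @slot slopeCoef linear regression coefficient; `NA` for GAM fits.
#' @slot ndviRange range of NDVI seen at fit time; GAM predictions are
#'   clamped to it (constant extrapolation).
#' @slot fallback TRUE when the class had too few samples and inherited the
#'   pooled all-classes model.
#' @export
setClass("ClassFit",
         representation(classCode = "integer", modelKind = "character",
                        model = "ANY", r2 = "numeric", slopeCoef = "numeric",
                        pValue = "numeric", rmse = "numeric", nObs = "integer",
                        ndviRange = "numeric", fallback = "logical"))

setValidity("ClassFit", function(object) {
  msg <- character()
  if (!object@modelKind %in% c("LRM", "GAM"))
    msg <- c(msg, "modelKind must be 'LRM' or 'GAM'")
  if (is.finite(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
    msg <- c(msg, "r2 out of [0, 1]")
  if (is.finite(object@rmse) && object@rmse < 0)
    msg <- c(msg, "rmse must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SceneSpec: recipe for a synthetic city scene
#'
#' Parameters of the synthetic-city generator. The layout is a concentric
#' urban-to-rural ring structure; the coastal variant masks a water stripe on
#' the eastern edge. Per-class LST responses to NDVI are monotone
#' non-increasing (linear, or a saturating nonlinear curve), matching the
#' negative warm-season LST-NDVI relation.
#'
#' @slot name scene name.
#' @slot shape integer (rows, cols) of the 100-m analysis grid; must be a
#'   multiple of 30 so the 300-m and 1-km grids tile the same extent.
#' @slot classCodes land-cover codes from city centre outwards.
#' @slot ndviClassMeans named per-class mean NDVI in [-0.1, 0.9].
#' @slot lstResponse named list of per-class response descriptions:
#'   `list(kind = "linear", intercept =, slope =)` or
#'   `list(kind = "saturating", intercept =, depth =, scale =)`.
#' @slot dayNightOffset degrees C subtracted from the day response at night.
#' @slot noiseSd,noiseSdNight i.i.d. noise SD (degrees C) added to the coarse
#'   day / night LST; night is smaller, reflecting the steadier nocturnal
#'   surface signal.
#' @slot popTotal total persons in the scene.
#' @slot popDecay e-folding distance (metres) of the centre-peaked density.
#' @slot nMunicipalities number of contiguous municipal regions.
#' @slot elderlyFractions per-municipality elderly (>= 65) fraction in [0, 1].
#' @slot coastal TRUE adds the water stripe.
#' @slot seed RNG seed; the same seed gives a bit-identical scene.
#' @export
setClass("SceneSpec",
         representation(name = "character", shape = "integer",
                        classCodes = "integer", ndviClassMeans = "numeric",
                        lstResponse = "list", dayNightOffset = "numeric",
                        noiseSd = "numeric", noiseSdNight = "numeric",
                        popTotal = "numeric", popDecay = "numeric",
                        nMunicipalities = "integer",
                        elderlyFractions = "numeric", coastal = "logical",
                        seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape <= 0))
    msg <- c(msg, "shape must be two positive integers")
  if (any(object@shape %% 30L != 0L))
    msg <- c(msg, "shape must be a multiple of 30 (100 m cells per side)")
  if (any(object@elderlyFractions < 0) || any(object@elderlyFractions > 1))
    msg <- c(msg, "elderlyFractions must lie in [0, 1]")
  if (length(object@elderlyFractions) != object@nMunicipalities)
    msg <- c(msg, "need one elderly fraction per municipality")
  if (object@popTotal < 0) msg <- c(msg, "popTotal must be >= 0")
  if (object@noiseSd < 0 || object@noiseSdNight < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  codes <- as.character(object@classCodes)
  if (!all(codes %in% names(object@ndviClassMeans)))
    msg <- c(msg, "every class code needs an NDVI mean")
  if (!all(codes %in% names(object@lstResponse)))
    msg <- c(msg, "every class code needs an LST response")
  if (length(msg)) msg else TRUE
})

#' CityScene: the full input bundle for one city
#'
#' All layers the risk analysis consumes, at their native resolutions:
#' land cover at 300 m, monthly NDVI at 250 m, monthly coarse day/night LST
#' at 1 km, total population and municipality partition at 100 m, plus the
#' per-municipality elderly fractions. Synthetic scenes also carry the
#' noise-free 100-m "truth" LST used by recovery tests.
#'
#' @slot name city name.
#' @slot landCover 300-m [CategoricalGrid-class].
#' @slot ndviMonthly 250-m [MonthlyStack-class].
#' @slot lstDayMonthly,lstNightMonthly 1-km [MonthlyStack-class].
#' @slot populationTotal 100-m [GeoGrid-class], persons per cell.
#' @slot municipalities 100-m [CategoricalGrid-class].
#' @slot elderlyFractions named numeric, municipality code -> fraction.
#' @slot truthLstDay,truthLstNight 100-m summer-mean noise-free LST
#'   ([GeoGrid-class]) or NULL for real data.
#' @export
setClass("CityScene",
         representation(name = "character", landCover = "CategoricalGrid",
                        ndviMonthly = "MonthlyStack",
                        lstDayMonthly = "MonthlyStack",
                        lstNightMonthly = "MonthlyStack",
                        populationTotal = "GeoGrid",
                        municipalities = "CategoricalGrid",
                        elderlyFractions = "numeric",
                        truthLstDay = "ANY", truthLstNight = "ANY"))

#' HeriConfig: weights, thresholds and options of the risk index
#'
#' Hazard is weighted 50% against the combined "exposed and vulnerable"
#' layer, which itself averages exposure and vulnerability 50/50 — so
#' HERI = 0.5 H + 0.25 E + 0.25 V on normalized layers. Level bounds split
#' [0, 1] into five equal risk classes.
#'
#' @slot wHazard hazard weight against the exposure+vulnerability block.
#' @slot wExposure,wVulnerability weights within that block; must sum to 1.
#' @slot levelBounds strictly increasing cut points inside (0, 1).
#' @slot levelNames five level names, lowest risk first.
#' @slot normalization "minmax" ((x - min)/range, the default) or "range"
#'   (x / range).
#' @export
setClass("HeriConfig",
         representation(wHazard = "numeric", wExposure = "numeric",
                        wVulnerability = "numeric", levelBounds = "numeric",
                        levelNames = "character", normalization = "character"))

setValidity("HeriConfig", function(object) {
  msg <- character()
  if (abs(object@wExposure + object@wVulnerability - 1) > 1e-9)
    msg <- c(msg, "exposure and vulnerability weights must sum to 1")
  if (object@wHazard < 0 || object@wHazard > 1)
    msg <- c(msg, "wHazard must lie in [0, 1]")
  b <- object@levelBounds
  if (length(b) != 4L || any(diff(b) <= 0) || any(b <= 0) || any(b >= 1))
    msg <- c(msg, "levelBounds must be four increasing values in (0, 1)")
  if (length(object@levelNames) != 5L)
    msg <- c(msg, "need five level names")
  if (!object@normalization %in% c("minmax", "range"))
    msg <- c(msg, "normalization must be 'minmax' or 'range'")
  if (length(msg)) msg else TRUE
})

# ---- constructors -----------------------------------------------------------

#' Create a continuous raster grid
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param cellSize metres per pixel edge.
#' @param origin (x, y) of the top-left corner; defaults to (0, 0).
#' @return a [GeoGrid-class].
#' @examples
#' g <- geoGrid(matrix(1:12, 3, 4), cellSize = 100)
#' gridExtent(g)
#' @export
geoGrid <- function(values, cellSize, origin = c(0, 0)) {
  storage.mode(values) <- "double"
  new("GeoGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin))
}

#' Create a categorical (integer-coded) raster grid
#'
#' @param codes integer matrix; `NA` marks nodata.
#' @param labels named character vector (names = codes). Codes present in the
#'   matrix but absent from `labels` get an auto "C<code>" label.
#' @param cellSize,origin as in [geoGrid()].
#' @return a [CategoricalGrid-class].
#' @export
categoricalGrid <- function(codes, labels = NULL, cellSize, origin = c(0, 0)) {
  storage.mode(codes) <- "integer"
  present <- sort(unique(codes[!is.na(codes)]))
  auto <- structure(paste0("C", present), names = as.character(present))
  if (is.null(labels)) labels <- auto
  else {
    miss <- setdiff(names(auto), names(labels))
    labels <- c(labels, auto[miss])
  }
  new("CategoricalGrid", codes = codes, labels = labels,
      cellSize = as.numeric(cellSize), origin = as.numeric(origin))
}

#' Build a monthly stack of aligned grids
#'
#' @param grids list of aligned [GeoGrid-class] layers.
#' @param months integer month indices, strictly increasing; defaults to
#'   5..9 (May-September) when `grids` has five layers, else 1..n.
#' @return a [MonthlyStack-class].
#' @export
monthlyStack <- function(grids, months = NULL) {
  if (is.null(months))
    months <- if (length(grids) == 5L) 5:9 else seq_along(grids)
  new("MonthlyStack", months = as.integer(months), grids = grids)
}

#' Risk-index configuration
#'
#' @param wHazard,wExposure,wVulnerability layer weights (see
#'   [HeriConfig-class]).
#' @param levelBounds four increasing cut points in (0, 1).
#' @param levelNames five level names, lowest first.
#' @param normalization "minmax" or "range".
#' @return a [HeriConfig-class].
#' @export
heriConfig <- function(wHazard = 0.5, wExposure = 0.5, wVulnerability = 0.5,
                       levelBounds = c(0.2, 0.4, 0.6, 0.8),
                       levelNames = c("very low", "low", "moderate",
                                      "high", "very high"),
                       normalization = c("minmax", "range")) {
  new("HeriConfig", wHazard = wHazard, wExposure = wExposure,
      wVulnerability = wVulnerability, levelBounds = levelBounds,
      levelNames = levelNames, normalization = match.arg(normalization))
}

# ---- accessors --------------------------------------------------------------

#' @rdname grid-accessors
setMethod("gridValues", "GeoGrid", function(x) x@values)
#' @rdname grid-accessors
setMethod("gridValues", "CategoricalGrid", function(x) x@codes)
#' @rdname grid-accessors
setMethod("cellSize", "GeoGrid", function(x) x@cellSize)
#' @rdname grid-accessors
setMethod("cellSize", "CategoricalGrid", function(x) x@cellSize)
#' @rdname grid-accessors
setMethod("origin", "GeoGrid", function(x) x@origin)
#' @rdname grid-accessors
setMethod("origin", "CategoricalGrid", function(x) x@origin)
#' @rdname grid-accessors
setMethod("nodataMask", "GeoGrid", function(x) is.na(x@values))
#' @rdname grid-accessors
setMethod("nodataMask", "CategoricalGrid", function(x) is.na(x@codes))

#' @rdname grid-accessors
setMethod("gridExtent", "GeoGrid", function(x)
  c(width = ncol(x@values) * x@cellSize,
    height = nrow(x@values) * x@cellSize))
#' @rdname grid-accessors
setMethod("gridExtent", "CategoricalGrid", function(x)
  c(width = ncol(x@codes) * x@cellSize,
    height = nrow(x@codes) * x@cellSize))

setMethod("classLabels", "CategoricalGrid", function(x) x@labels)

#' Test whether two grids share shape, cell size and origin
#'
#' @param a,b grid objects ([GeoGrid-class] or [CategoricalGrid-class]).
#' @return TRUE iff aligned.
#' @export
isAligned <- function(a, b) {
  identical(dim(gridValues(a)), dim(gridValues(b))) &&
    isTRUE(all.equal(cellSize(a), cellSize(b))) &&
    isTRUE(all.equal(origin(a), origin(b)))
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "GeoGrid", function(object) {
  v <- object@values
  cat(sprintf("GeoGrid: %d x %d cells, %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), object@cellSize,
              object@origin[1], object@origin[2]))
  ok <- v[!is.na(v)]
  if (length(ok))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata\n",
                min(ok), max(ok), sum(is.na(v))))
  else cat("  all nodata\n")
})

setMethod("show", "CategoricalGrid", function(object) {
  cat(sprintf("CategoricalGrid: %d x %d cells, %g m, %d classes\n",
              nrow(object@codes), ncol(object@codes), object@cellSize,
              length(object@labels)))
})

setMethod("show", "MonthlyStack", function(object) {
  cat(sprintf("MonthlyStack: months %s", paste(object@months, collapse = ",")))
  if (length(object@grids)) {
    g <- object@grids[[1L]]
    cat(sprintf(" | %d x %d @ %g m", nrow(g@values), ncol(g@values),
                g@cellSize))
  }
  cat("\n")
})

setMethod("show", "ClassFit", function(object) {
  cat(sprintf("ClassFit C%d [%s]%s: R2=%.3f slope=%s p=%.4g RMSE=%.3f n=%d\n",
              object@classCode, object@modelKind,
              if (object@fallback) " (pooled fallback)" else "",
              object@r2,
              if (is.na(object@slopeCoef)) "-" else
                sprintf("%.2f", object@slopeCoef),
              object@pValue, object@rmse, object@nObs))
})

setMethod("show", "CityScene", function(object) {
  cat(sprintf("CityScene '%s'\n", object@name))
  cat(sprintf("  land cover : %d x %d @ %g m\n",
              nrow(object@landCover@codes), ncol(object@landCover@codes),
              object@landCover@cellSize))
  cat(sprintf("  NDVI       : %d months @ %g m\n",
              length(object@ndviMonthly@months),
              cellSize(object@ndviMonthly@grids[[1]])))
  cat(sprintf("  LST        : %d months @ %g m (day & night)\n",
              length(object@lstDayMonthly@months),
              cellSize(object@lstDayMonthly@grids[[1]])))
  cat(sprintf("  population : %.0f persons, %d municipalities\n",
              sum(object@populationTotal@values, na.rm = TRUE),
              length(object@elderlyFractions)))
})
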