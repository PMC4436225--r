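# One-call pipeline: scene -> training table -> class fits -> fine LST ->
# hazard / exposure / vulnerability -> HERI -> level summary.

#' Run the full heat-risk analysis on a city scene
#'
#' Fits the per-class downscaling models for one diurnal period, predicts
#' fine LST, builds the summer 100-m hazard layer, the exposure and
#' vulnerability layers, combines them into the HERI and summarizes the
#' five risk levels.
#'
#' @param scene a [CityScene-class].
#' @param period "day" or "night".
#' @param model "GAM" (default) or "LRM".
#' @param config a [HeriConfig-class].
#' @param minSamples minimum training pairs per class.
#' @return list with `fits`, `fitReport`, `predicted` (monthly fine LST),
#'   `hazard`, `exposure`, `vulnerability`, `heri`, `levels`, `summary`.
#' @examples
#' \donttest{
#' scene <- generateScene(defaultSpec("inland"))
#' run <- runHeatRisk(scene, "day", model = "GAM")
#' run$summary
#' }
#' @export
runHeatRisk <- function(scene, period = c("day", "night"),
                        model = c("GAM", "LRM"), config = heriConfig(),
                        minSamples = 30L) {
  stopifnot(is(scene, "CityScene"))
  period <- match.arg(period)
  model <- match.arg(model)
  lstStack <- if (period == "day") scene@lstDayMonthly else
    scene@lstNightMonthly
  table <- buildTrainingTable(lstStack, scene@ndviMonthly, scene@landCover)
  fits <- fitClassModels(table, kind = model, minSamples = minSamples)
  pred <- predictFineLst(fits, scene@ndviMonthly, scene@landCover)
  lc100 <- resampleNearest(scene@landCover, cellSize(scene@populationTotal))
  hazard <- applyWaterMask(hazardLayer(pred), lc100)
  exposure <- exposureLayer(scene@populationTotal, lc100)
  vulnerability <- vulnerabilityLayer(exposure, scene@municipalities,
                                      scene@elderlyFractions)
  hx <- heriIndex(hazard, exposure, vulnerability, config)
  list(fits = fits,
       fitReport = compileFitReport(fits, period = period),
       predicted = pred, hazard = hazard, exposure = exposure,
       vulnerability = vulnerability, heri = hx$heri, levels = hx$levels,
       summary = summarizeRisk(hx$levels, hazard, exposure, vulnerability))
}
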