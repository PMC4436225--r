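# Access to the reference tables shipped under inst/extdata.

#' Published per-level coverage areas for eleven Italian cities
#'
#' Reference per-city, per-period (day/night) coverage-area percentages of
#' the five risk levels from the 2001-2013 summer analysis of eleven major
#' Italian cities, with each city's coastal/inland group. These are the
#' inputs of the cross-city aggregation (see [aggregateCoverage()]): the
#' coastal day+night means for the high and very high levels are 11.3% and
#' 6.0%, the inland means 8.1% and 3.3%.
#'
#' @return data.frame with columns `city`, `group`, `period`, `level`,
#'   `level_name`, `coverage_area_pct`.
#' @export
italianCityCoverage <- function() {
  path <- system.file("extdata", "italian_city_risk_coverage.csv",
                      package = "heatrisk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' City-to-group table for the reference cities
#'
#' @return data.frame with columns `city` and `group` (coastal/inland);
#'   Rome counts as inland (hybrid coastal/inland, reported with the inland
#'   cities).
#' @export
italianCityGroups <- function() {
  tab <- italianCityCoverage()
  unique(tab[, c("city", "group")])
}
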