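riskLevels <- function(codes, cellSize = 100) {
  categoricalGrid(codes,
                  labels = structure(c("very low", "low", "moderate",
                                       "high", "very high"),
                                     names = as.character(1:5)),
                  cellSize = cellSize)
}

test_that("a uniform level covers everything at citywide density", {
  lv <- riskLevels(matrix(3L, 10, 10))
  lst <- geoGrid(matrix(28, 10, 10), 100)
  pop <- geoGrid(matrix(12, 10, 10), 100)
  eld <- geoGrid(matrix(2.4, 10, 10), 100)
  s <- summarizeRisk(lv, lst, pop, eld)
  expect_equal(s$coverage_area_pct[3], 100)
  expect_equal(s$total_pop_freq_pct[3], 100)
  expect_equal(s$total_pop_density[3], 1200 / 1)  # 1200 persons per km2
  expect_equal(s$mean_lst[3], 28)
  expect_equal(s$coverage_area_pct[-3], rep(0, 4))
})

test_that("the 4-pixel toy reproduces the hand-computed summary", {
  lv <- riskLevels(matrix(c(5L, 1L, 1L, 1L), 2, 2))
  lst <- geoGrid(matrix(c(30, 24, 25, 26), 2, 2), 100)
  pop <- geoGrid(matrix(c(50, 20, 20, 10), 2, 2), 100)
  eld <- geoGrid(matrix(c(10, 4, 4, 2), 2, 2), 100)
  s <- summarizeRisk(lv, lst, pop, eld)
  five <- s[s$level == 5, ]
  expect_equal(five$coverage_area_pct, 25)
  expect_equal(five$total_pop_freq_pct, 50)
  expect_equal(five$total_pop_density, 5000)  # 50 persons / 0.01 km2
  expect_equal(five$sd_lst, 0)                # single-pixel level
  expect_equal(five$mean_lst, 30)
})

test_that("percentages partition 100 and mass is conserved on a real run", {
  for (run in list(inlandRun("day", "GAM"),
                   runHeatRisk(coastalScene(), "day", model = "GAM"))) {
    s <- run$summary
    expect_equal(sum(s$coverage_area_pct), 100, tolerance = 1e-9)
    expect_equal(sum(s$total_pop_freq_pct), 100, tolerance = 1e-9)
    expect_equal(sum(s$elderly_pop_freq_pct), 100, tolerance = 1e-9)
    # level populations reconstruct the city total exactly
    cellKm2 <- 0.01
    lvlPop <- s$total_pop_density * s$coverage_area_pct / 100 *
      sum(!is.na(gridValues(run$levels))) * cellKm2
    cityPop <- sum(gridValues(run$exposure)[!is.na(gridValues(run$levels))],
                   na.rm = TRUE)
    expect_equal(sum(lvlPop), cityPop, tolerance = 1e-6)
  }
})

test_that("population density rises from very low to very high risk", {
  for (run in list(inlandRun("day", "GAM"),
                   runHeatRisk(coastalScene(), "day", model = "GAM"))) {
    d <- run$summary$total_pop_density
    expect_true(all(diff(d) > 0))
    e <- run$summary$elderly_pop_density
    expect_true(all(diff(e) > 0))
  }
})

test_that("cross-city aggregation reproduces the published coastal/inland averages", {
  cov <- italianCityCoverage()
  agg <- aggregateCoverage(cov, italianCityGroups())
  get <- function(group, level)
    agg$mean_coverage_pct[agg$group == group & agg$level == level]
  expect_equal(round(get("coastal", 4), 1), 11.3)
  expect_equal(round(get("coastal", 5), 1), 6.0)
  expect_equal(round(get("inland", 4), 1), 8.1)
  expect_equal(round(get("inland", 5), 1), 3.3)
  # 5 coastal and 6 inland cities, day + night members each
  expect_equal(unique(agg$n_members[agg$group == "coastal"]), 10)
  expect_equal(unique(agg$n_members[agg$group == "inland"]), 12)
})

test_that("aggregation handles single members and rejects empty groups", {
  one <- data.frame(city = "A", period = "day", level = 4,
                    coverage_area_pct = 7.7)
  agg <- aggregateCoverage(one, data.frame(city = "A", group = "g"))
  expect_equal(agg$mean_coverage_pct, 7.7)

  expect_error(aggregateCoverage(one, data.frame(city = "B", group = "h")),
               "group")
})

test_that("map export writes a raster and a legended PNG", {
  lv <- riskLevels(matrix(rep(1:5, each = 5), 5, 5))
  prefix <- file.path(withr::local_tempdir(), "risk")
  paths <- exportMap(lv, prefix)
  expect_true(file.exists(paths["raster"]))
  expect_true(file.exists(paths["png"]))
  back <- readGrid(paths[["raster"]])
  expect_equal(gridValues(back), gridValues(lv))
  expect_equal(length(heriPalette()), 5L)

  empty <- riskLevels(matrix(NA_integer_, 2, 2))
  expect_error(exportMap(empty, file.path(tempdir(), "x")), "nodata")
})
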