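# A 1-km LST pixel over a 4x4 block of 250-m NDVI cells, one class.
toyTrainingInputs <- function(months = 5L, ndviSeed = 31) {
  withr::local_seed(ndviSeed)
  ndviGrids <- lapply(months, function(m)
    geoGrid(matrix(runif(16, 0.2, 0.6), 4, 4), 250))
  lstGrids <- lapply(seq_along(months), function(i)
    geoGrid(matrix(25 + i, 1, 1), 1000))
  list(ndvi = monthlyStack(ndviGrids, months),
       lst = monthlyStack(lstGrids, months),
       lc = categoricalGrid(matrix(20L, 4, 4), cellSize = 250))
}

test_that("each fine cell pairs its NDVI with the block-replicated coarse LST", {
  inp <- toyTrainingInputs()
  tab <- buildTrainingTable(inp$lst, inp$ndvi, inp$lc)
  expect_equal(nrow(tab), 16L)
  expect_equal(unique(tab$lst), 26)
  expect_setequal(tab$ndvi, as.vector(gridValues(inp$ndvi@grids[[1]])))
  expect_equal(unique(tab$class), 20L)

  # a class absent from the scene contributes no rows
  expect_equal(sum(tab$class == 190L), 0L)

  # two months double the row count
  tab2 <- buildTrainingTable(toyTrainingInputs(months = 5:6)$lst,
                             toyTrainingInputs(months = 5:6)$ndvi,
                             inp$lc)
  expect_equal(nrow(tab2), 32L)
})

test_that("masked and water cells are dropped from the training table", {
  inp <- toyTrainingInputs()
  ndviNA <- gridValues(inp$ndvi@grids[[1]])
  ndviNA[1, 1] <- NA
  lcw <- gridValues(inp$lc)
  lcw[4, 4] <- 210L
  tab <- buildTrainingTable(inp$lst,
                            monthlyStack(list(geoGrid(ndviNA, 250)), 5L),
                            categoricalGrid(lcw, cellSize = 250))
  expect_equal(nrow(tab), 14L)
})

test_that("mismatched stacks are rejected", {
  inp <- toyTrainingInputs()
  shifted <- monthlyStack(inp$lst@grids, 6L)
  expect_error(buildTrainingTable(shifted, inp$ndvi, inp$lc),
               "different months")
})

test_that("the linear fit recovers an exact line and degrades gracefully", {
  x <- seq(0.1, 0.7, length.out = 40)
  exact <- fitLrm(data.frame(ndvi = x, lst = 30 - 10 * x), 20L)
  expect_equal(exact@slopeCoef, -10, tolerance = 1e-10)
  expect_equal(exact@r2, 1)
  expect_equal(exact@rmse, 0, tolerance = 1e-10)
  expect_equal(exact@pValue, 0)

  flat <- fitLrm(data.frame(ndvi = x, lst = rep(22, 40)), 20L)
  expect_equal(flat@slopeCoef, 0, tolerance = 1e-10)
  expect_equal(flat@r2, 0)

  expect_error(fitLrm(data.frame(ndvi = x[1:5], lst = x[1:5]), 20L),
               class = "heatrisk_fit_skipped")
  expect_error(fitLrm(data.frame(ndvi = rep(0.4, 40), lst = 30 - x), 20L),
               class = "heatrisk_degenerate_fit")
})

test_that("the fitted slope lies within 3 SE of the generating slope", {
  pairs <- linePairs(n = 500L, intercept = 34, slope = -10, noiseSd = 1,
                     seed = 1L)
  fit <- fitLrm(pairs, 190L)
  se <- summary(fit@model)$coefficients["ndvi", "Std. Error"]
  expect_lt(abs(fit@slopeCoef - (-10)), 3 * se)
  expect_lt(fit@slopeCoef, 0)
  expect_lt(fit@pValue, 0.05)
})

test_that("on noise-free linear truth the spline collapses onto the line", {
  x <- rep(seq(0.1, 0.6, length.out = 50), each = 2)
  d <- data.frame(ndvi = x, lst = 30 - 10 * x)
  gam <- fitGam(d, 20L)
  lrm <- fitLrm(d, 20L)
  grid <- seq(0.1, 0.6, by = 0.01)
  expect_lt(max(abs(heatrisk:::.predictFit(gam, grid) -
                      heatrisk:::.predictFit(lrm, grid))), 1e-6)
  expect_equal(gam@rmse, 0, tolerance = 1e-8)
  expect_true(is.na(gam@slopeCoef))

  expect_error(fitGam(d[1:10, ], 20L), class = "heatrisk_fit_skipped")
})

test_that("the spline never fits worse than the line, and beats it on curvature", {
  run <- inlandRun("day", "LRM")
  rug <- inlandRun("day", "GAM")
  for (code in names(run$fits)) {
    expect_lte(rug$fits[[code]]@rmse,
               run$fits[[code]]@rmse + 1e-8)
  }
  # classes with a saturating true response: strict improvement
  for (code in c("14", "20", "50")) {
    expect_lt(rug$fits[[code]]@rmse, run$fits[[code]]@rmse)
  }
})

test_that("all fitted slopes are negative on both presets and periods", {
  for (run in list(inlandRun("day", "LRM"), inlandRun("night", "LRM"))) {
    slopes <- vapply(run$fits, function(f) f@slopeCoef, numeric(1))
    expect_true(all(slopes < 0))
  }
})

test_that("night-time fits are more accurate than daytime fits", {
  day <- inlandRun("day", "LRM")$fits
  night <- inlandRun("night", "LRM")$fits
  for (code in names(day)) {
    expect_lt(night[[code]]@rmse, day[[code]]@rmse)
  }
})

test_that("sparse classes inherit the pooled model", {
  withr::local_seed(41)
  n <- 200
  tab <- data.frame(
    month = 5L,
    class = c(rep(20L, n), rep(190L, 10L)),
    ndvi = runif(n + 10, 0.1, 0.7))
  tab$lst <- 30 - 8 * tab$ndvi + rnorm(n + 10, 0, 0.5)
  fits <- fitClassModels(tab, "LRM", minSamples = 30L)
  expect_false(fits[["20"]]@fallback)
  expect_true(fits[["190"]]@fallback)
  expect_equal(fits[["190"]]@classCode, 190L)
  # fallback carries the pooled fit
  expect_equal(fits[["190"]]@nObs, n + 10L)
})

test_that("per-pixel prediction applies the class model to the pixel NDVI", {
  d <- data.frame(ndvi = seq(0, 1, length.out = 50))
  d$lst <- 30 - 10 * d$ndvi
  fit <- fitLrm(d, 20L)
  ndvi <- monthlyStack(list(geoGrid(matrix(c(0.5, NA, 0.2, 0.8), 2, 2),
                                    250)), 5L)
  lc <- categoricalGrid(matrix(20L, 2, 2), cellSize = 250)
  pred <- predictFineLst(list(`20` = fit), ndvi, lc)
  v <- gridValues(pred@grids[[1]])
  expect_equal(v[1, 1], 25)
  expect_true(is.na(v[2, 1]))
  expect_equal(v[2, 2], 22)

  expect_error(predictFineLst(list(`190` = fit), ndvi, lc),
               "no fitted model")
})

test_that("GAM predictions use constant extrapolation beyond the fitted range", {
  withr::local_seed(42)
  x <- runif(200, 0.2, 0.6)
  d <- data.frame(ndvi = x, lst = 35 - 12 * tanh(x / 0.5) + rnorm(200, 0, 0.3))
  gam <- fitGam(d, 14L)
  below <- heatrisk:::.predictFit(gam, c(-0.1, 0.2))
  above <- heatrisk:::.predictFit(gam, c(0.6, 0.9))
  expect_equal(below[1], heatrisk:::.predictFit(gam, min(x)))
  expect_equal(above[2], heatrisk:::.predictFit(gam, max(x)))
})

test_that("a zero-noise linear scene is reconstructed almost exactly", {
  scene <- zeroNoiseScene()
  run <- runHeatRisk(scene, "day", model = "LRM")
  err <- gridValues(run$hazard) - gridValues(scene@truthLstDay)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 0.1)
})

test_that("the fit report tabulates metrics with correct average rows", {
  mkFit <- function(code, rmse, r2, slope) {
    new("ClassFit", classCode = code, modelKind = "LRM", model = NULL,
        r2 = r2, slopeCoef = slope, pValue = 0.01, rmse = rmse,
        nObs = 100L, ndviRange = c(0, 1), fallback = FALSE)
  }
  one <- compileFitReport(list(mkFit(20L, 1.5, 0.3, -8)), period = "day")
  expect_equal(nrow(one), 2L)
  expect_equal(one$rmse[2], one$rmse[1])

  two <- compileFitReport(list(mkFit(20L, 1.0, 0.2, -6),
                               mkFit(14L, 2.0, 0.4, -12)), period = "day")
  avg <- two[is.na(two$class), ]
  expect_equal(avg$rmse, 1.5)
  expect_equal(avg$r2, 0.3)
  expect_equal(avg$slope, -9)
  # rows sorted by class code
  expect_equal(two$class[1:2], c(14L, 20L))
})

test_that("a full synthetic run reports all classes for both models and periods", {
  reports <- rbind(inlandRun("day", "LRM")$fitReport,
                   inlandRun("day", "GAM")$fitReport,
                   inlandRun("night", "LRM")$fitReport,
                   inlandRun("night", "GAM")$fitReport)
  classRows <- reports[!is.na(reports$class), ]
  expect_equal(nrow(classRows), 2L * 2L * 5L)
  expect_setequal(unique(classRows$class), c(14L, 20L, 50L, 130L, 190L))
})
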