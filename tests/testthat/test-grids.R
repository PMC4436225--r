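test_that("nearest-neighbour resampling replicates coarse pixels exactly", {
  g <- geoGrid(matrix(7, 1, 1), cellSize = 1000)
  out <- resampleNearest(g, 250)
  expect_equal(gridValues(out), matrix(7, 4, 4))
  expect_equal(cellSize(out), 250)

  same <- resampleNearest(g, 1000)
  expect_equal(gridValues(same), gridValues(g))
})

test_that("2x2 grid at 500 m resampled to 250 m forms per-value quadrants", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  out <- resampleNearest(geoGrid(m, 500), 250)
  expect_equal(gridValues(out), bruteForceResample(m, 500, 250))
  expect_equal(gridValues(out)[1:2, 1:2], matrix(1, 2, 2))
  expect_equal(gridValues(out)[3:4, 3:4], matrix(4, 2, 2))
})

test_that("resampling matches the brute-force nearest-centre oracle, ties top-left", {
  withr::local_seed(11)
  cases <- list(c(300, 100, 6), c(250, 100, 6), c(1000, 250, 6),
                c(300, 250, 5))  # n chosen so the extent divides evenly
  for (sizes in cases) {
    n <- sizes[3]
    m <- matrix(rnorm(n * n), n, n)
    out <- resampleNearest(geoGrid(m, sizes[1]), sizes[2])
    expect_equal(gridValues(out), bruteForceResample(m, sizes[1], sizes[2]),
                 info = paste(sizes[1:2], collapse = "->"))
  }
})

test_that("fine-then-back resampling is the identity on unmasked pixels", {
  withr::local_seed(12)
  m <- matrix(rnorm(25), 5, 5)
  m[2, 3] <- NA
  for (fine in c(100, 250, 500)) {
    back <- resampleNearest(resampleNearest(geoGrid(m, 1000), fine), 1000)
    expect_equal(gridValues(back), m, info = fine)
  }
})

test_that("nodata propagates through resampling and never gains values", {
  m <- matrix(c(NA, 2, 3, 4), 2, 2)
  out <- gridValues(resampleNearest(geoGrid(m, 500), 250))
  expect_true(all(is.na(out[1:2, 1:2])))
  expect_equal(sum(is.na(out)), 4L)
})

test_that("categorical resampling keeps codes and the label table", {
  cg <- categoricalGrid(matrix(c(190L, 210L), 1, 2),
                        labels = c(`190` = "urban", `210` = "water"),
                        cellSize = 300)
  out <- resampleNearest(cg, 100)
  expect_s4_class(out, "CategoricalGrid")
  expect_equal(classLabels(out), classLabels(cg))
  expect_equal(unique(as.vector(gridValues(out))), c(190L, 210L))
})

test_that("invalid target cell size is rejected", {
  g <- geoGrid(matrix(1, 2, 2), 500)
  expect_error(resampleNearest(g, 0), "positive")
  expect_error(resampleNearest(g, -100), "positive")
})

test_that("temporal mean averages unmasked months per pixel", {
  g <- function(v) geoGrid(matrix(v, 1, 1), 100)
  s <- monthlyStack(list(g(20), g(22), g(24), g(26), g(28)))
  expect_equal(gridValues(temporalMean(s))[1, 1], 24)

  # idempotence on identical months
  same <- monthlyStack(replicate(5, g(17.5)))
  expect_equal(gridValues(temporalMean(same))[1, 1], 17.5)
})

test_that("min_valid_months masks incomplete pixels", {
  g <- function(v) geoGrid(matrix(v, 1, 1), 100)
  s <- monthlyStack(list(g(20), g(22), g(24), g(26), g(NA)))
  expect_equal(gridValues(temporalMean(s, minValidMonths = 4))[1, 1], 23)
  expect_true(is.na(gridValues(temporalMean(s, minValidMonths = 5))[1, 1]))
})

test_that("temporal mean is bounded by the per-pixel min and max", {
  withr::local_seed(13)
  grids <- lapply(1:5, function(i) {
    m <- matrix(rnorm(16, 25, 3), 4, 4)
    m[sample(16, 2)] <- NA
    geoGrid(m, 250)
  })
  s <- monthlyStack(grids)
  arr <- simplify2array(lapply(grids, gridValues))
  lo <- apply(arr, c(1, 2), min, na.rm = TRUE)
  hi <- apply(arr, c(1, 2), max, na.rm = TRUE)
  mv <- gridValues(temporalMean(s))
  ok <- !is.na(mv)
  expect_true(all(mv[ok] >= lo[ok] - 1e-12 & mv[ok] <= hi[ok] + 1e-12))
})

test_that("empty stacks and bad completeness thresholds are rejected", {
  expect_error(temporalMean(monthlyStack(list())), "nonempty")
  g <- geoGrid(matrix(1, 1, 1), 100)
  expect_error(temporalMean(monthlyStack(list(g)), minValidMonths = 2))
})

test_that("water masking removes exactly the water pixels", {
  lc <- matrix(20L, 3, 3)
  g <- geoGrid(matrix(1:9, 3, 3), 300)

  none <- applyWaterMask(g, categoricalGrid(lc, cellSize = 300))
  expect_equal(gridValues(none), gridValues(g))

  lc[2, 2] <- 210L
  one <- applyWaterMask(g, categoricalGrid(lc, cellSize = 300))
  expect_equal(sum(is.na(gridValues(one))), 1L)
  expect_true(is.na(gridValues(one)[2, 2]))

  allWater <- applyWaterMask(g, categoricalGrid(matrix(210L, 3, 3),
                                                cellSize = 300))
  expect_true(all(is.na(gridValues(allWater))))
})

test_that("water masking requires aligned grids", {
  g <- geoGrid(matrix(1, 2, 2), 300)
  w <- categoricalGrid(matrix(210L, 3, 3), cellSize = 300)
  expect_error(applyWaterMask(g, w), "aligned")
})
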