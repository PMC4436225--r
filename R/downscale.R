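# Hazard-layer engine: per-land-cover-class LST ~ NDVI models fitted on
# 250-m-resampled data, used to predict fine LST, scored with R2 / slope /
# significance / RMSE, summer-averaged and delivered at 100 m.
#
# One pooled model per (class, period): all months in the input stack feed a
# single fit, so the class response is a single predictive model rather than
# a per-month family.

.classedStop <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Build the per-class (NDVI, LST) training table
#'
#' The coarse monthly LST and the land-cover grid are resampled (nearest
#' neighbour) to the NDVI resolution; every valid fine cell then contributes
#' one (month, class, NDVI, LST) row per month, where LST is the
#' block-replicated coarse value. Water and masked cells are dropped.
#'
#' @param lstCoarse 1-km [MonthlyStack-class] of LST.
#' @param ndvi 250-m [MonthlyStack-class] of NDVI (defines the target grid).
#' @param landCover [CategoricalGrid-class] of land-cover codes.
#' @param waterCodes codes excluded as water (default 210).
#' @return data.frame with columns `month`, `class`, `ndvi`, `lst`.
#' @export
buildTrainingTable <- function(lstCoarse, ndvi, landCover,
                               waterCodes = 210L) {
  stopifnot(is(lstCoarse, "MonthlyStack"), is(ndvi, "MonthlyStack"))
  if (!identical(lstCoarse@months, ndvi@months))
    stop("LST and NDVI stacks cover different months")
  fineSize <- cellSize(ndvi@grids[[1L]])
  lc <- resampleNearest(landCover, fineSize)
  ref <- ndvi@grids[[1L]]
  if (!identical(dim(lc@codes), dim(ref@values)))
    stop("land cover and NDVI extents do not overlap/align")
  cls <- lc@codes
  cls[cls %in% waterCodes] <- NA_integer_
  out <- vector("list", length(ndvi@months))
  for (i in seq_along(ndvi@months)) {
    lstFine <- resampleNearest(lstCoarse@grids[[i]], fineSize)
    if (!identical(dim(lstFine@values), dim(ref@values)))
      stop("coarse LST extent does not overlap/align with NDVI")
    nd <- ndvi@grids[[i]]@values
    lv <- lstFine@values
    ok <- !is.na(nd) & !is.na(lv) & !is.na(cls)
    out[[i]] <- data.frame(month = ndvi@months[i], class = cls[ok],
                           ndvi = nd[ok], lst = lv[ok])
  }
  do.call(rbind, out)
}

.fitMetrics <- function(y, fitted) {
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0
  list(r2 = r2, rmse = sqrt(rss / length(y)), rss = rss, tss = tss)
}

.checkPairs <- function(pairs, minSamples) {
  n <- nrow(pairs)
  if (n < minSamples)
    .classedStop("heatrisk_fit_skipped",
                 sprintf("only %d pairs (< %d): fit skipped", n, minSamples))
  if (stats::var(pairs$ndvi) < 1e-12)
    .classedStop("heatrisk_degenerate_fit",
                 "zero NDVI variance: degenerate fit")
  n
}

#' Fit the per-class linear regression model (LRM)
#'
#' Ordinary least squares `LST = a + b * NDVI`. Returns the coefficient of
#' determination, the regression coefficient `b` with its two-sided p-value,
#' and the in-sample RMSE. Negative `b` is the expected warm-season
#' LST-NDVI relation.
#'
#' @param pairs data.frame with columns `ndvi` and `lst` for one class.
#' @param classCode integer land-cover code (metadata only).
#' @param minSamples minimum pairs required (default 30); fewer raises a
#'   `heatrisk_fit_skipped` condition and the class falls back to the pooled
#'   all-classes model in [fitClassModels()].
#' @return a [ClassFit-class] with `modelKind = "LRM"`.
#' @export
fitLrm <- function(pairs, classCode = NA_integer_, minSamples = 30L) {
  n <- .checkPairs(pairs, minSamples)
  fit <- stats::lm(lst ~ ndvi, data = pairs)
  met <- .fitMetrics(pairs$lst, stats::fitted(fit))
  slope <- unname(stats::coef(fit)[2L])
  p <- if (met$rmse < 1e-12) 0 else {
    ct <- summary(fit)$coefficients
    if (nrow(ct) >= 2L && !is.nan(ct[2L, 4L])) ct[2L, 4L] else NA_real_
  }
  new("ClassFit", classCode = as.integer(classCode), modelKind = "LRM",
      model = fit, r2 = met$r2, slopeCoef = slope, pValue = p,
      rmse = met$rmse, nObs = as.integer(n),
      ndviRange = range(pairs$ndvi), fallback = FALSE)
}

#' Fit the per-class generalized additive model (GAM)
#'
#' Penalized cubic regression spline `LST = f(NDVI)` via [mgcv::gam()], with
#' the smoothing parameter chosen by generalized cross-validation. Because
#' the second-derivative penalty leaves straight lines unpenalized, the
#' spline nests the linear fit, so its in-sample RMSE can never exceed the
#' LRM's. Significance is an F-test of the smooth against the intercept-only
#' model, with effective degrees of freedom from the smoother trace.
#'
#' @inheritParams fitLrm
#' @param k spline basis dimension (default 12, reduced automatically when
#'   NDVI has fewer unique values).
#' @return a [ClassFit-class] with `modelKind = "GAM"`; `slopeCoef` is `NA`.
#' @export
fitGam <- function(pairs, classCode = NA_integer_, minSamples = 30L,
                   k = 12L) {
  n <- .checkPairs(pairs, minSamples)
  nUnique <- length(unique(pairs$ndvi))
  kEff <- min(k, nUnique)
  if (kEff < 4L)
    .classedStop("heatrisk_degenerate_fit",
                 "too few distinct NDVI values for a spline basis")
  fit <- mgcv::gam(lst ~ s(ndvi, bs = "cr", k = kEff), data = pairs,
                   method = "GCV.Cp")
  met <- .fitMetrics(pairs$lst, stats::fitted(fit))
  edf <- 1 + sum(fit$edf)
  df1 <- max(edf - 1, 1e-8)
  df2 <- max(n - edf, 1)
  p <- if (met$rmse < 1e-12 || met$tss <= 0) 0 else {
    Fstat <- ((met$tss - met$rss) / df1) / (met$rss / df2)
    stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  new("ClassFit", classCode = as.integer(classCode), modelKind = "GAM",
      model = fit, r2 = met$r2, slopeCoef = NA_real_, pValue = p,
      rmse = met$rmse, nObs = as.integer(n),
      ndviRange = range(pairs$ndvi), fallback = FALSE)
}

#' Fit one model per land-cover class, with pooled fallback
#'
#' Splits the training table by class and fits the requested model to each.
#' Classes with fewer than `minSamples` pairs inherit the pooled
#' all-classes model (flagged `fallback = TRUE`).
#'
#' @param table training table from [buildTrainingTable()].
#' @param kind "LRM" or "GAM".
#' @param minSamples minimum pairs per class.
#' @return named list of [ClassFit-class], names = class codes as strings.
#' @export
fitClassModels <- function(table, kind = c("LRM", "GAM"), minSamples = 30L) {
  kind <- match.arg(kind)
  fitter <- if (kind == "LRM") fitLrm else fitGam
  codes <- sort(unique(table$class))
  pooled <- NULL
  fits <- list()
  for (code in codes) {
    sub <- table[table$class == code, , drop = FALSE]
    fits[[as.character(code)]] <- tryCatch(
      fitter(sub, classCode = code, minSamples = minSamples),
      heatrisk_fit_skipped = function(e) {
        if (is.null(pooled))
          pooled <<- fitter(table, classCode = NA_integer_,
                            minSamples = minSamples)
        f <- pooled
        f@classCode <- as.integer(code)
        f@fallback <- TRUE
        f
      })
  }
  fits
}

.predictFit <- function(fit, x) {
  if (fit@modelKind == "GAM") {
    x <- pmin(fit@ndviRange[2L], pmax(fit@ndviRange[1L], x))
    as.numeric(mgcv::predict.gam(fit@model, newdata = data.frame(ndvi = x)))
  } else {
    as.numeric(stats::predict(fit@model, newdata = data.frame(ndvi = x)))
  }
}

#' Predict fine-resolution monthly LST from the class models
#'
#' Applies, pixel by pixel and month by month, the model of the pixel's
#' land-cover class to its NDVI. GAM predictions are clamped to the NDVI
#' range seen at fit time (constant extrapolation). Masked NDVI pixels stay
#' masked; water is excluded.
#'
#' @param fits named list from [fitClassModels()].
#' @param ndvi 250-m [MonthlyStack-class].
#' @param landCover [CategoricalGrid-class].
#' @param waterCodes water codes to exclude (default 210).
#' @return a [MonthlyStack-class] of predicted LST at the NDVI resolution.
#' @export
predictFineLst <- function(fits, ndvi, landCover, waterCodes = 210L) {
  fineSize <- cellSize(ndvi@grids[[1L]])
  lc <- resampleNearest(landCover, fineSize)
  cls <- lc@codes
  cls[cls %in% waterCodes] <- NA_integer_
  codes <- sort(unique(cls[!is.na(cls)]))
  missing <- setdiff(as.character(codes), names(fits))
  if (length(missing))
    stop("no fitted model (or fallback) for land-cover class(es): ",
         paste(missing, collapse = ", "))
  grids <- lapply(seq_along(ndvi@months), function(i) {
    nd <- ndvi@grids[[i]]@values
    v <- matrix(NA_real_, nrow(nd), ncol(nd))
    for (code in codes) {
      idx <- which(cls == code & !is.na(nd))
      if (length(idx))
        v[idx] <- .predictFit(fits[[as.character(code)]], nd[idx])
    }
    geoGrid(v, cellSize = fineSize, origin = origin(ndvi@grids[[i]]))
  })
  monthlyStack(grids, ndvi@months)
}

#' Summer-mean hazard layer at 100 m
#'
#' Averages the predicted monthly LST over the summer stack
#' ([temporalMean()]) and resamples the composite to the target resolution
#' (nearest neighbour) — the hazard side of the risk triangle.
#'
#' @param pred [MonthlyStack-class] of predicted fine LST.
#' @param minValidMonths per-pixel completeness rule (default 1).
#' @param targetCellSize output resolution in metres (default 100).
#' @return a [GeoGrid-class] at `targetCellSize`.
#' @export
hazardLayer <- function(pred, minValidMonths = 1L, targetCellSize = 100) {
  resampleNearest(temporalMean(pred, minValidMonths), targetCellSize)
}

#' Tabulate fit metrics, with per-model average rows
#'
#' One row per class, sorted by class code, plus an "Average" row per model
#' kind holding the unweighted arithmetic mean of each metric column
#' (optionally also the `nObs`-weighted mean).
#'
#' @param fits list of [ClassFit-class] (one or both model kinds).
#' @param period optional period label ("day"/"night") copied into the rows.
#' @param weighted also append an `nObs`-weighted average row.
#' @return data.frame with columns `class`, `period`, `model`, `r2`,
#'   `slope`, `p_value`, `rmse`, `n_obs`, `fallback`.
#' @export
compileFitReport <- function(fits, period = NA_character_,
                             weighted = FALSE) {
  if (!length(fits)) stop("compileFitReport needs at least one fit")
  rows <- do.call(rbind, lapply(fits, function(f)
    data.frame(class = f@classCode, period = period, model = f@modelKind,
               r2 = f@r2, slope = f@slopeCoef, p_value = f@pValue,
               rmse = f@rmse, n_obs = f@nObs, fallback = f@fallback)))
  rows <- rows[order(rows$model, rows$class), , drop = FALSE]
  avg <- do.call(rbind, lapply(split(rows, rows$model), function(g) {
    out <- data.frame(class = NA_integer_, period = period,
                      model = g$model[1L], r2 = mean(g$r2),
                      slope = mean(g$slope), p_value = mean(g$p_value),
                      rmse = mean(g$rmse),
                      n_obs = as.integer(round(mean(g$n_obs))),
                      fallback = NA)
    if (weighted) {
      w <- g$n_obs / sum(g$n_obs)
      out <- rbind(out, data.frame(
        class = NA_integer_, period = period, model = g$model[1L],
        r2 = sum(w * g$r2), slope = sum(w * g$slope),
        p_value = sum(w * g$p_value), rmse = sum(w * g$rmse),
        n_obs = as.integer(sum(g$n_obs)), fallback = NA))
    }
    out
  }))
  res <- rbind(rows, avg)
  rownames(res) <- NULL
  res
}
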