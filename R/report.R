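# Zonal statistics per risk level, cross-city aggregation and map export.

#' Per-risk-level zonal summary
#'
#' For each of the five risk levels: mean and SD of LST over the level's
#' pixels, coverage area as % of the unmasked city area, total and elderly
#' population frequency as % of the city totals, and total and elderly
#' population density in persons per km2 (level population / level area).
#' Empty levels report zeros. Percentages partition 100 exactly before any
#' rounding.
#'
#' @param levels 100-m [CategoricalGrid-class] of risk levels (codes 1..5).
#' @param lst aligned 100-m [GeoGrid-class] of summer LST.
#' @param popTotal,popElderly aligned 100-m population [GeoGrid-class]
#'   layers.
#' @return data.frame with one row per level: `level`, `level_name`,
#'   `mean_lst`, `sd_lst`, `coverage_area_pct`, `total_pop_freq_pct`,
#'   `elderly_pop_freq_pct`, `total_pop_density`, `elderly_pop_density`.
#' @export
summarizeRisk <- function(levels, lst, popTotal, popElderly) {
  if (!isAligned(levels, lst) || !isAligned(levels, popTotal) ||
      !isAligned(levels, popElderly))
    stop("summarizeRisk: grids are not aligned")
  lv <- levels@codes
  unmasked <- sum(!is.na(lv))
  if (unmasked == 0L) stop("summarizeRisk: level grid is all nodata")
  cellKm2 <- (levels@cellSize / 1000)^2
  totPop <- sum(popTotal@values[!is.na(lv)], na.rm = TRUE)
  totEld <- sum(popElderly@values[!is.na(lv)], na.rm = TRUE)
  labs <- classLabels(levels)
  rows <- lapply(1:5, function(l) {
    idx <- which(lv == l)
    n <- length(idx)
    if (n == 0L)
      return(data.frame(level = l,
                        level_name = unname(labs[as.character(l)]),
                        mean_lst = 0, sd_lst = 0, coverage_area_pct = 0,
                        total_pop_freq_pct = 0, elderly_pop_freq_pct = 0,
                        total_pop_density = 0, elderly_pop_density = 0))
    t <- lst@values[idx]
    p <- sum(popTotal@values[idx], na.rm = TRUE)
    e <- sum(popElderly@values[idx], na.rm = TRUE)
    areaKm2 <- n * cellKm2
    data.frame(level = l, level_name = unname(labs[as.character(l)]),
               mean_lst = mean(t, na.rm = TRUE),
               sd_lst = if (sum(!is.na(t)) > 1L) stats::sd(t, na.rm = TRUE)
               else 0,
               coverage_area_pct = 100 * n / unmasked,
               total_pop_freq_pct = if (totPop > 0) 100 * p / totPop else 0,
               elderly_pop_freq_pct = if (totEld > 0) 100 * e / totEld
               else 0,
               total_pop_density = p / areaKm2,
               elderly_pop_density = e / areaKm2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-city mean coverage per risk level
#'
#' Unweighted arithmetic mean of `coverage_area_pct` across all
#' (city, period) members of each city group — e.g. the coastal vs inland
#' day+night averages of the high and very high levels.
#'
#' @param summaries data.frame with columns `city`, `period`, `level` (or
#'   `level_name`) and `coverage_area_pct`, one row per city x period x
#'   level.
#' @param groups data.frame with columns `city` and `group`.
#' @return data.frame with columns `group`, `level`, `mean_coverage_pct`
#'   and `n_members`.
#' @export
aggregateCoverage <- function(summaries, groups) {
  lvlCol <- if ("level" %in% names(summaries)) "level" else "level_name"
  need <- c("city", "period", lvlCol, "coverage_area_pct")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("summaries lacks column(s): ", paste(miss, collapse = ", "))
  summaries <- summaries[, setdiff(names(summaries), "group"),
                         drop = FALSE]
  m <- merge(summaries, groups, by = "city")
  if (!nrow(m)) stop("no summaries match any group")
  empty <- setdiff(unique(groups$group), unique(m$group))
  if (length(empty))
    stop("empty group(s): ", paste(empty, collapse = ", "))
  agg <- stats::aggregate(m$coverage_area_pct,
                          by = list(group = m$group, level = m[[lvlCol]]),
                          FUN = mean)
  cnt <- stats::aggregate(m$coverage_area_pct,
                          by = list(group = m$group, level = m[[lvlCol]]),
                          FUN = length)
  out <- data.frame(group = agg$group, level = agg$level,
                    mean_coverage_pct = agg$x, n_members = cnt$x)
  out[order(out$group, out$level), , drop = FALSE]
}

#' Default five-level risk palette
#'
#' Green -> yellow -> red ramp for the very low .. very high levels.
#' @return character vector of five colours.
#' @export
heriPalette <- function() {
  c("#1a9641", "#a6d96a", "#ffffbf", "#fdae61", "#d7191c")
}

#' Export a risk-level map
#'
#' Writes the categorical raster (`<path>.asc`, via [writeGrid()]) and a
#' rendered PNG (`<path>.png`) with a fixed five-colour legend.
#'
#' @param levels a [CategoricalGrid-class] of risk levels.
#' @param path output path prefix (no extension).
#' @param palette five colours, lowest level first.
#' @return invisibly, the two file paths written.
#' @export
exportMap <- function(levels, path, palette = heriPalette()) {
  if (all(is.na(levels@codes)))
    stop("exportMap: level grid is all nodata")
  ascPath <- paste0(path, ".asc")
  pngPath <- paste0(path, ".png")
  writeGrid(levels, ascPath)
  labs <- classLabels(levels)
  m <- levels@codes
  grDevices::png(pngPath, width = 720, height = 620)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 10), xpd = NA)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = palette,
                  breaks = seq(0.5, 5.5, by = 1), axes = FALSE,
                  main = "Risk levels", asp = nrow(m) / ncol(m))
  graphics::legend("topright", inset = c(-0.32, 0), fill = palette,
                   legend = labs[as.character(1:5)], bty = "n",
                   title = "HERI level")
  invisible(c(raster = ascPath, png = pngPath))
}
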