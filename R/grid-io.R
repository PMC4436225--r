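# Plain-text raster I/O (ESRI-ASCII-style grid dialect). Header lines carry
# the georeference (ncols, nrows, xllcorner, yllcorner, cellsize,
# nodata_value), then one line per row, top row first. Categorical grids get
# a "<path>.labels.csv" sidecar with the code -> label table.

.labelsPath <- function(path) paste0(path, ".labels.csv")

#' Write a grid to a plain-text raster file
#'
#' Continuous grids are written with full double precision so a write/read
#' cycle is the identity (values, mask, cell size, origin). Categorical grids
#' additionally write their label table to `<path>.labels.csv`.
#'
#' @param grid a [GeoGrid-class] or [CategoricalGrid-class].
#' @param path output file path.
#' @param nodataValue sentinel written for masked cells (default -9999).
#' @return `path`, invisibly.
#' @seealso [readGrid()]
#' @export
writeGrid <- function(grid, path, nodataValue = -9999) {
  categorical <- is(grid, "CategoricalGrid")
  if (!categorical && !is(grid, "GeoGrid"))
    stop("writeGrid: unsupported object of class ", class(grid))
  m <- gridValues(grid)
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", origin(grid)[1]),
    sprintf("yllcorner %.10g", origin(grid)[2] - nrow(m) * cellSize(grid)),
    sprintf("cellsize %.10g", cellSize(grid)),
    sprintf("nodata_value %.10g", nodataValue))
  fmt <- if (categorical) function(v) sprintf("%d", v) else
    function(v) sprintf("%.17g", v)
  body <- apply(m, 1L, function(row) {
    s <- fmt(row)
    s[is.na(row)] <- fmt(nodataValue)
    paste(s, collapse = " ")
  })
  writeLines(c(hdr, body), path)
  if (categorical) {
    lab <- classLabels(grid)
    utils::write.csv(data.frame(code = as.integer(names(lab)), label = lab,
                                row.names = NULL),
                     .labelsPath(path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a grid from a plain-text raster file
#'
#' @param path file written by [writeGrid()] (or any ESRI-ASCII-style grid).
#' @param type "auto" reads a [CategoricalGrid-class] when a
#'   `<path>.labels.csv` sidecar exists, a [GeoGrid-class] otherwise;
#'   "continuous" / "categorical" force the kind.
#' @return a [GeoGrid-class] or [CategoricalGrid-class].
#' @export
readGrid <- function(path, type = c("auto", "continuous", "categorical")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("readGrid: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (length(parts) == 2L &&
        key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value") &&
        !is.na(suppressWarnings(as.numeric(parts[2L])))) {
      hdr[[key]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("readGrid: ", path, " lacks georeference header field(s): ",
         paste(miss, collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[(i + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop("readGrid: expected ", nr, " data rows, found ", length(body))
  m <- do.call(rbind, lapply(body, function(ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])))
  if (ncol(m) != nc) stop("readGrid: row length does not match ncols")
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  org <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  labPath <- .labelsPath(path)
  if (type == "categorical" || (type == "auto" && file.exists(labPath))) {
    labels <- NULL
    if (file.exists(labPath)) {
      tab <- utils::read.csv(labPath, stringsAsFactors = FALSE)
      labels <- structure(as.character(tab$label),
                          names = as.character(tab$code))
    }
    categoricalGrid(m, labels = labels, cellSize = hdr$cellsize, origin = org)
  } else {
    geoGrid(m, cellSize = hdr$cellsize, origin = org)
  }
}

#' Default Globcover land-cover label table
#'
#' The code -> label table shipped with the package (Globcover-style classes;
#' 210 is water bodies, 190 artificial surfaces). Read from
#' `inst/extdata/globcover_labels.csv`.
#'
#' @return named character vector, names are the integer codes.
#' @export
globcoverLabels <- function() {
  path <- system.file("extdata", "globcover_labels.csv", package = "heatrisk")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(as.character(tab$label), names = as.character(tab$code))
}
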