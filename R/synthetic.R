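# Synthetic city-scene generator: a ground-truth stand-in for the satellite
# LST/NDVI products, the 300-m land-cover grid and the 100-m population grid,
# so the whole downscaling + risk pipeline is testable end to end.

# Run body with a private, seeded RNG stream; the caller's RNG state is
# untouched and the same seed gives a bit-identical scene.
.withSceneSeed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

.evalResponse <- function(resp, ndvi) {
  switch(resp$kind,
         linear = resp$intercept + resp$slope * ndvi,
         saturating = resp$intercept - resp$depth * tanh(ndvi / resp$scale),
         stop("unknown response kind: ", resp$kind))
}

#' Build a synthetic-scene specification
#'
#' All arguments have defaults describing a mid-sized city: a 12 x 12 km
#' scene with concentric land-cover rings from the built-up core (code 190)
#' out to forest (code 50), warm-season mean NDVI rising from 0.15 in the
#' core to 0.65 in the forest belt, and monotone-decreasing LST responses
#' to NDVI — linear for the urban and shrubland classes, saturating
#' (`intercept - depth * tanh(ndvi/scale)`) for the vegetated ones, so both
#' the linear and the smooth downscaling model have signal to recover.
#'
#' @param name scene name.
#' @param shape (rows, cols) of the 100-m grid; multiples of 30.
#' @param classCodes land-cover ring codes, centre outwards.
#' @param ndviClassMeans named per-class mean NDVI.
#' @param lstResponse named list of per-class responses (see
#'   [SceneSpec-class]).
#' @param dayNightOffset degrees C between day and night truth.
#' @param noiseSd,noiseSdNight coarse-LST noise SD, day / night (degrees C).
#' @param popTotal,popDecay total persons and density e-folding distance (m).
#' @param nMunicipalities,elderlyFractions municipal partition and per-
#'   municipality elderly fractions.
#' @param coastal add a water stripe along the eastern edge.
#' @param seed RNG seed.
#' @return a validated [SceneSpec-class].
#' @export
sceneSpec <- function(name = "synthetic",
                      shape = c(120L, 120L),
                      classCodes = c(190L, 14L, 20L, 130L, 50L),
                      ndviClassMeans = c(`190` = 0.15, `14` = 0.40,
                                         `20` = 0.50, `130` = 0.35,
                                         `50` = 0.65),
                      lstResponse = list(
                        `190` = list(kind = "linear", intercept = 34,
                                     slope = -10),
                        `14` = list(kind = "saturating", intercept = 35,
                                    depth = 12, scale = 0.5),
                        `20` = list(kind = "saturating", intercept = 34,
                                    depth = 11, scale = 0.5),
                        `130` = list(kind = "linear", intercept = 33,
                                     slope = -9),
                        `50` = list(kind = "saturating", intercept = 33,
                                    depth = 10, scale = 0.5)),
                      dayNightOffset = 14,
                      noiseSd = 1.0, noiseSdNight = 0.4,
                      popTotal = 300000, popDecay = 1500,
                      nMunicipalities = 5L,
                      elderlyFractions = c(0.17, 0.19, 0.21, 0.23, 0.25),
                      coastal = FALSE, seed = 42L) {
  new("SceneSpec", name = name, shape = as.integer(shape),
      classCodes = as.integer(classCodes), ndviClassMeans = ndviClassMeans,
      lstResponse = lstResponse, dayNightOffset = dayNightOffset,
      noiseSd = noiseSd, noiseSdNight = noiseSdNight,
      popTotal = popTotal, popDecay = popDecay,
      nMunicipalities = as.integer(nMunicipalities),
      elderlyFractions = elderlyFractions, coastal = coastal,
      seed = as.integer(seed))
}

#' Documented scene presets
#'
#' "inland" is the default concentric city; "coastal" adds a ~1.2-km water
#' stripe along the eastern edge (water class 210), as in a coastal-plain
#' city. Elderly fractions in both bracket the ~21% national elderly share.
#'
#' @param preset "inland" or "coastal".
#' @return a [SceneSpec-class].
#' @export
defaultSpec <- function(preset = c("inland", "coastal")) {
  preset <- match.arg(preset)
  switch(preset,
         inland = sceneSpec(name = "inland", coastal = FALSE, seed = 42L),
         coastal = sceneSpec(name = "coastal", coastal = TRUE, seed = 43L))
}

# Largest-remainder apportionment of `total` persons over weights w (>= 0).
.largestRemainder <- function(w, total) {
  out <- numeric(length(w))
  s <- sum(w)
  if (s <= 0 || total <= 0) return(out)
  raw <- w / s * total
  base <- floor(raw)
  rem <- round(total - sum(base))
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  base
}

# Smooth random NDVI anomaly field: a handful of long-wavelength cosine
# modes (6-12 km), so vegetation varies on the broad urban-rural scale and
# each 1-km sensor footprint is close to homogeneous, plus faint fine-scale
# texture.
.smoothField <- function(nr, nc, cellKm, sdLarge = 0.08, sdFine = 0.005) {
  x <- outer(rep(1, nr), (seq_len(nc) - 0.5) * cellKm)
  y <- outer((seq_len(nr) - 0.5) * cellKm, rep(1, nc))
  nModes <- 6L
  field <- matrix(0, nr, nc)
  for (k in seq_len(nModes)) {
    lambda <- stats::runif(1, 6, 12)
    theta <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    field <- field + cos(2 * pi * (x * cos(theta) + y * sin(theta)) /
                           lambda + phase)
  }
  sdf <- stats::sd(as.vector(field))
  if (sdf > 0) field <- field / sdf * sdLarge
  field + matrix(stats::rnorm(nr * nc, 0, sdFine), nr, nc)
}

#' Generate a complete synthetic city scene
#'
#' Deterministic given the spec's seed. The noise-free 100-m "truth" LST is
#' built per pixel as the class response applied to NDVI; each 1-km coarse
#' LST cell is the mean of its 10 x 10 truth block plus i.i.d. Gaussian
#' noise, emulating the coarse thermal footprint. NDVI carries a small
#' seasonal decline over the May-September months. Population is a
#' centre-peaked exponential-decay surface apportioned to whole persons by
#' largest remainder (total conserved exactly); municipalities partition the
#' land into contiguous nearest-seed regions.
#'
#' @param spec a [SceneSpec-class].
#' @return a [CityScene-class] with all layers plus day/night truth LST.
#' @examples
#' scene <- generateScene(sceneSpec(shape = c(60, 60), popTotal = 5000))
#' scene
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  .withSceneSeed(spec@seed, {
    nr <- spec@shape[1]; nc <- spec@shape[2]
    months <- 5:9

    # --- land cover at 300 m: concentric rings, optional coastal stripe ----
    nr3 <- nr %/% 3L; nc3 <- nc %/% 3L
    cy <- (nr3 + 1) / 2; cx <- (nc3 + 1) / 2
    d <- sqrt(outer((seq_len(nr3) - cy)^2, (seq_len(nc3) - cx)^2, `+`))
    dmax <- max(d)
    k <- length(spec@classCodes)
    ring <- pmin(k, 1L + floor(d / (dmax + 1e-9) * k))
    lc <- matrix(spec@classCodes[ring], nr3, nc3)
    if (spec@coastal) {
      stripe <- max(1L, round(nc3 / 10))
      lc[, (nc3 - stripe + 1L):nc3] <- 210L
    }
    landCover <- categoricalGrid(lc, labels = globcoverLabels(),
                                 cellSize = 300)
    lc250 <- resampleNearest(landCover, 250)
    lc100 <- resampleNearest(landCover, 100)
    water100 <- lc100@codes == 210L
    water250 <- lc250@codes == 210L

    # --- NDVI at 250 m: class means + smooth anomaly + seasonal decline ---
    nr25 <- nrow(lc250@codes); nc25 <- ncol(lc250@codes)
    base <- matrix(spec@ndviClassMeans[as.character(lc250@codes)],
                   nr25, nc25)
    base <- base + .smoothField(nr25, nc25, cellKm = 0.25)
    ndviGrids <- lapply(months, function(m) {
      v <- pmin(pmax(base + 0.05 * cos(2 * pi * (m - 6) / 12) - 0.04,
                     -0.1), 0.9)
      v[water250] <- NA
      geoGrid(v, cellSize = 250)
    })
    ndviMonthly <- monthlyStack(ndviGrids, months)

    # --- truth LST at 100 m, coarse LST at 1 km --------------------------
    truthFor <- function(ndvi100, night = FALSE) {
      v <- matrix(NA_real_, nr, nc)
      for (code in spec@classCodes) {
        idx <- lc100@codes == code & !is.na(ndvi100)
        v[idx] <- .evalResponse(spec@lstResponse[[as.character(code)]],
                                ndvi100[idx])
      }
      if (night) v <- v - spec@dayNightOffset
      v[water100] <- NA
      v
    }
    coarseFrom <- function(truth, sd) {
      cm <- .blockMean(truth, 10L)
      if (sd > 0)
        cm <- cm + matrix(stats::rnorm(length(cm), 0, sd),
                          nrow(cm), ncol(cm))
      geoGrid(cm, cellSize = 1000)
    }
    truthDayM <- list(); truthNightM <- list()
    lstDayM <- list(); lstNightM <- list()
    for (i in seq_along(months)) {
      nd100 <- gridValues(resampleNearest(ndviGrids[[i]], 100))
      td <- truthFor(nd100); tn <- td - spec@dayNightOffset
      tn[water100] <- NA
      truthDayM[[i]] <- td; truthNightM[[i]] <- tn
      lstDayM[[i]] <- coarseFrom(td, spec@noiseSd)
      lstNightM[[i]] <- coarseFrom(tn, spec@noiseSdNight)
    }
    truthStack <- function(lst) monthlyStack(
      lapply(lst, geoGrid, cellSize = 100), months)
    truthLstDay <- temporalMean(truthStack(truthDayM))
    truthLstNight <- temporalMean(truthStack(truthNightM))

    # --- population at 100 m: centre-peaked exponential decay ------------
    cy1 <- (nr + 1) / 2; cx1 <- (nc + 1) / 2
    dist100 <- sqrt(outer(((seq_len(nr) - cy1) * 100)^2,
                          ((seq_len(nc) - cx1) * 100)^2, `+`))
    w <- exp(-dist100 / spec@popDecay)
    w[water100] <- 0
    pop <- matrix(.largestRemainder(as.vector(w), spec@popTotal), nr, nc)
    pop[water100] <- NA
    populationTotal <- geoGrid(pop, cellSize = 100)

    # --- municipalities: contiguous nearest-seed partition of the land ---
    land <- which(!water100)
    seeds <- sample(land, spec@nMunicipalities)
    sr <- (seeds - 1) %% nr + 1; sc <- (seeds - 1) %/% nr + 1
    rowIdx <- matrix(rep(seq_len(nr), nc), nr, nc)
    colIdx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    best <- matrix(Inf, nr, nc); muni <- matrix(NA_integer_, nr, nc)
    for (m in seq_len(spec@nMunicipalities)) {
      dd <- (rowIdx - sr[m])^2 + (colIdx - sc[m])^2
      upd <- dd < best
      best[upd] <- dd[upd]; muni[upd] <- m
    }
    muni[water100] <- NA_integer_
    municipalities <- categoricalGrid(
      muni, labels = structure(paste0("M", seq_len(spec@nMunicipalities)),
                               names = as.character(
                                 seq_len(spec@nMunicipalities))),
      cellSize = 100)
    elderly <- structure(spec@elderlyFractions,
                         names = as.character(seq_len(spec@nMunicipalities)))

    new("CityScene", name = spec@name, landCover = landCover,
        ndviMonthly = ndviMonthly,
        lstDayMonthly = monthlyStack(lstDayM, months),
        lstNightMonthly = monthlyStack(lstNightM, months),
        populationTotal = populationTotal,
        municipalities = municipalities, elderlyFractions = elderly,
        truthLstDay = truthLstDay, truthLstNight = truthLstNight)
  })
}
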