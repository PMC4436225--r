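# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

inlandScene <- function() {
  fixture("inland", function() generateScene(defaultSpec("inland")))
}

coastalScene <- function() {
  fixture("coastal", function() generateScene(defaultSpec("coastal")))
}

inlandRun <- function(period = "day", model = "LRM") {
  fixture(paste("run", period, model, sep = "_"),
          function() runHeatRisk(inlandScene(), period, model = model))
}

# Single-class linear scene: the clean parameter-recovery benchmark.
zeroNoiseSpec <- function(noiseSd = 0, seed = 7L) {
  sceneSpec(name = "zeronoise", classCodes = 190L,
            ndviClassMeans = c(`190` = 0.35),
            lstResponse = list(`190` = list(kind = "linear",
                                            intercept = 34, slope = -10)),
            noiseSd = noiseSd, noiseSdNight = 0, seed = seed)
}

zeroNoiseScene <- function() {
  fixture("zeronoise", function() generateScene(zeroNoiseSpec()))
}

# n pairs straight from the generator's linear response model plus iid noise.
linePairs <- function(n = 500L, intercept = 34, slope = -10, noiseSd = 1,
                      seed = 1L) {
  withr::local_seed(seed)
  ndvi <- stats::rnorm(n, 0.35, 0.08)
  data.frame(ndvi = ndvi,
             lst = intercept + slope * ndvi + stats::rnorm(n, 0, noiseSd))
}

# Brute-force nearest-centre resampling oracle, independent of the package's
# index arithmetic: for every output pixel centre, scan all source centres.
bruteForceResample <- function(m, srcSize, outSize) {
  extH <- nrow(m) * srcSize; extW <- ncol(m) * srcSize
  nOutR <- round(extH / outSize); nOutC <- round(extW / outSize)
  srcR <- (seq_len(nrow(m)) - 0.5) * srcSize
  srcC <- (seq_len(ncol(m)) - 0.5) * srcSize
  out <- matrix(NA_real_, nOutR, nOutC)
  for (i in seq_len(nOutR)) {
    for (j in seq_len(nOutC)) {
      cy <- (i - 0.5) * outSize; cx <- (j - 0.5) * outSize
      dr <- abs(srcR - cy); dc <- abs(srcC - cx)
      # ties go to the smaller index (top-left candidate)
      out[i, j] <- m[which.min(round(dr, 9)), which.min(round(dc, 9))]
    }
  }
  out
}
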