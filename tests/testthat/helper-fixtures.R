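## Cached generator outputs (structures are deterministic, so one build per
## parameter combination serves all tests).
.fixtureCache <- new.env(parent = emptyenv())

cachedSandwich <- function(seed = 1L, connectivity = 1L, noiseSigma = 0.1, ...) {
  key <- paste(seed, connectivity, noiseSigma,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- buildSandwich(sandwichSpec(
      seed = seed, connectivity = connectivity, noiseSigma = noiseSigma, ...))
  .fixtureCache[[key]]
}

cachedAnnotated <- function(seed = 1L, connectivity = 1L, noiseSigma = 0.1, ...) {
  key <- paste("ann", seed, connectivity, noiseSigma,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fixtureCache[[key]])) {
    b <- cachedSandwich(seed, connectivity, noiseSigma, ...)
    anns <- annotateC2(b$structure)
    .fixtureCache[[key]] <- list(structure = b$structure, truth = b$truth,
                                 annotation = anns[[1L]], all = anns)
  }
  .fixtureCache[[key]]
}

cachedReference <- function() {
  if (is.null(.fixtureCache[["ref"]])) .fixtureCache[["ref"]] <- referenceC2()
  .fixtureCache[["ref"]]
}
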