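#' @rdname EnFaceImage
#' @aliases pixels,EnFaceImage-method
setMethod("pixels", "EnFaceImage", function(object) object@pixels)

#' @rdname RegionMask
#' @param object an object
#' @aliases pixels,RegionMask-method
setMethod("pixels", "RegionMask", function(object) object@pixels)

#' @rdname EnFaceImage
setMethod("mmPerPixel", "EnFaceImage", function(object) object@mmPerPixel)

#' @rdname RegionMask
setMethod("mmPerPixel", "RegionMask", function(object) object@mmPerPixel)

#' @rdname EnFaceImage
setMethod("eyeId", "EnFaceImage", function(object) object@eyeId)

#' @rdname RegionMask
setMethod("eyeId", "RegionMask", function(object) object@eyeId)

#' @rdname EnFaceImage
setMethod("axialLength", "EnFaceImage", function(object) object@axialLengthMm)

#' @rdname RoiPolygon
setMethod("vertices", "RoiPolygon", function(object) object@vertices)

#' @rdname FazResult
setMethod("fazMask", "FazResult", function(object) object@mask)

#' @rdname FazResult
setMethod("fazArea", "FazResult", function(object) object@areaMm2)

#' @rdname FazResult
setMethod("pixelCount", "FazResult", function(object) object@pixelCount)

#' @rdname SyntheticScene
setMethod("sceneImage", "SyntheticScene", function(object) object@image)

#' @rdname SyntheticScene
setMethod("truthMask", "SyntheticScene", function(object) object@truthMask)

#' @rdname ComparisonReport
setMethod("evalRecords", "ComparisonReport", function(object) object@records)

setMethod("dim", "EnFaceImage", function(x) dim(x@pixels))
setMethod("dim", "RegionMask", function(x) dim(x@pixels))

setMethod("show", "EnFaceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EnFaceImage %d x %d px, %.4f mm/px (%.2f mm field)\n",
              d[1], d[2], object@mmPerPixel, d[2] * object@mmPerPixel))
  cat(sprintf("  intensity range [%g, %g]", min(object@pixels),
              max(object@pixels)))
  if (!is.na(object@eyeId)) cat("  eye:", object@eyeId)
  if (!is.na(object@axialLengthMm))
    cat(sprintf("  axial length %.2f mm", object@axialLengthMm))
  cat("\n")
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@pixels)
  n <- sum(object@pixels)
  cat(sprintf("RegionMask %d x %d px, %d foreground px (%.4f mm^2)\n",
              d[1], d[2], n, n * object@mmPerPixel^2))
})

setMethod("show", "RoiPolygon", function(object) {
  cat(sprintf("RoiPolygon with %d vertices\n", nrow(object@vertices)))
})

setMethod("show", "FazResult", function(object) {
  cat(sprintf("FazResult: %d px, %.4f mm^2", object@pixelCount,
              object@areaMm2))
  if (!is.na(object@eyeId)) cat("  eye:", object@eyeId)
  cat("\n")
})

setMethod("show", "SyntheticScene", function(object) {
  s <- object@spec
  cat(sprintf(
    "SyntheticScene %d px, truth FAZ %.4f mm^2 (target %.2f), seed %d\n",
    s@size, sum(object@truthMask@pixels) * object@truthMask@mmPerPixel^2,
    s@fazAreaMm2, s@seed))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  cat(sprintf("  %d eyes, %d method pairs\n",
              length(unique(object@records$eye_id)),
              length(unique(paste(object@records$method_a,
                                  object@records$method_b)))))
  cat("Area by method:\n")
  print(object@areaTable, row.names = FALSE)
  cat("Similarity by pair:\n")
  print(object@similarityTable, row.names = FALSE)
})
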