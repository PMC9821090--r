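#' @rdname EnFaceImage
#' @param object an object
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname EnFaceImage
#' @export
setGeneric("mmPerPixel", function(object) standardGeneric("mmPerPixel"))

#' @rdname EnFaceImage
#' @export
setGeneric("eyeId", function(object) standardGeneric("eyeId"))

#' @rdname EnFaceImage
#' @export
setGeneric("axialLength", function(object) standardGeneric("axialLength"))

#' @rdname RoiPolygon
#' @param object an object
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname FazResult
#' @param object an object
#' @export
setGeneric("fazMask", function(object) standardGeneric("fazMask"))

#' @rdname FazResult
#' @export
setGeneric("fazArea", function(object) standardGeneric("fazArea"))

#' @rdname FazResult
#' @export
setGeneric("pixelCount", function(object) standardGeneric("pixelCount"))

#' @rdname SyntheticScene
#' @param object an object
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))

#' @rdname SyntheticScene
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))

#' @rdname ComparisonReport
#' @param object an object
#' @export
setGeneric("evalRecords", function(object) standardGeneric("evalRecords"))
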