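#' @import methods
#' @importFrom stats fft quantile sd median rnorm runif friedman.test
#'   wilcox.test cor.test shapiro.test p.adjust qt complete.cases
NULL

#' EnFaceImage: a 2D grayscale en face OCTA raster
#'
#' Container for a single en face optical coherence tomography angiography
#' (OCTA) projection: an 8-bit grayscale pixel grid plus the physical scale
#' and per-eye metadata needed for area quantification.
#'
#' The coordinate convention used throughout the package is 0-based,
#' row-major \code{(row, col)}, with pixel centers at integer coordinates:
#' pixel \code{(0, 0)} is the top-left pixel and its center sits at
#' coordinate \code{(0, 0)}.
#'
#' @slot pixels numeric matrix of intensities in \code{[0, 255]}
#'   (rows = image rows).
#' @slot mmPerPixel physical scale in mm per pixel. The default scan regime
#'   is a 3 mm x 3 mm macular field exported at 1024 x 1024 px, i.e.
#'   \code{3/1024} mm/px.
#' @slot eyeId opaque eye identifier.
#' @slot axialLengthMm measured axial length in mm, or \code{NA_real_} when
#'   unknown. Used only by \code{\link{correctedArea}}.
#'
#' @seealso \code{\link{EnFaceImage}}, \code{\link{readEnFace}}
#' @exportClass EnFaceImage
setClass("EnFaceImage",
  representation(
    pixels = "matrix",
    mmPerPixel = "numeric",
    eyeId = "character",
    axialLengthMm = "numeric"
  ),
  prototype(
    mmPerPixel = 3 / 1024,
    eyeId = NA_character_,
    axialLengthMm = NA_real_
  )
)

setValidity("EnFaceImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("'pixels' must be a numeric matrix")
  if (nrow(p) < 64L || ncol(p) < 64L)
    return("image must be at least 64 x 64 pixels")
  if (anyNA(p)) return("'pixels' must not contain NA")
  if (min(p) < 0 || max(p) > 255)
    return("intensities must lie within [0, 255]")
  if (length(object@mmPerPixel) != 1L || !is.finite(object@mmPerPixel) ||
      object@mmPerPixel <= 0)
    return("'mmPerPixel' must be a single positive number")
  if (length(object@axialLengthMm) != 1L)
    return("'axialLengthMm' must be a single number or NA")
  if (!is.na(object@axialLengthMm) && object@axialLengthMm <= 0)
    return("'axialLengthMm' must be positive when given")
  TRUE
})

#' RegionMask: a binary raster region
#'
#' A binary (foreground/background) raster with the same geometry slots as
#' \code{\linkS4class{EnFaceImage}}. This is the representation of an
#' extracted FAZ, a manual tracing, or a training label. Masks serialize to
#' 8-bit images with background 0 and foreground 255.
#'
#' @slot pixels logical matrix; \code{TRUE} is foreground.
#' @slot mmPerPixel physical scale in mm per pixel.
#' @slot eyeId opaque eye identifier.
#'
#' @seealso \code{\link{RegionMask}}, \code{\link{writeMask}}
#' @exportClass RegionMask
setClass("RegionMask",
  representation(
    pixels = "matrix",
    mmPerPixel = "numeric",
    eyeId = "character"
  ),
  prototype(
    mmPerPixel = 3 / 1024,
    eyeId = NA_character_
  )
)

setValidity("RegionMask", function(object) {
  p <- object@pixels
  if (!is.logical(p)) return("'pixels' must be a logical matrix")
  if (anyNA(p)) return("'pixels' must not contain NA")
  if (nrow(p) < 1L || ncol(p) < 1L) return("mask must be non-empty")
  if (length(object@mmPerPixel) != 1L || !is.finite(object@mmPerPixel) ||
      object@mmPerPixel <= 0)
    return("'mmPerPixel' must be a single positive number")
  TRUE
})

#' RoiPolygon: a closed polygonal region-of-interest boundary
#'
#' An ordered list of \code{(row, col)} vertices in 0-based pixel-center
#' coordinates; the polygon is implicitly closed from the last vertex back
#' to the first. Polygons produced by \code{\link{maskToPolygon}} run along
#' pixel edges (half-integer coordinates), so re-rasterization with
#' \code{\link{polygonToMask}} reproduces the source mask exactly.
#'
#' @slot vertices numeric matrix with two columns (\code{row}, \code{col}).
#' @slot eyeId opaque eye identifier.
#'
#' @seealso \code{\link{polygonToMask}}, \code{\link{maskToPolygon}}
#' @exportClass RoiPolygon
setClass("RoiPolygon",
  representation(vertices = "matrix", eyeId = "character"),
  prototype(eyeId = NA_character_)
)

setValidity("RoiPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("'vertices' must be a numeric matrix with columns (row, col)")
  if (nrow(unique(v)) < 3L)
    return("a polygon needs at least 3 distinct vertices")
  if (anyNA(v)) return("'vertices' must not contain NA")
  TRUE
})

#' BandpassParams: ImageJ-style FFT bandpass filter settings
#'
#' Parameters of the frequency-domain bandpass used as the noise-processing
#' stage before binarization. Structure sizes are given in pixels:
#' structures larger than \code{filterLarge} and smaller than
#' \code{filterSmall} are attenuated by a difference-of-Gaussians weighting.
#'
#' @slot filterLarge largest structure size (px) allowed to pass
#'   (default 1024).
#' @slot filterSmall smallest structure size (px) allowed to pass
#'   (default 3.5).
#' @slot saturationTolerance percent of pixels saturated by the post-filter
#'   autoscale, split equally between the two tails (default 5).
#' @slot suppressStripes one of \code{"none"}, \code{"horizontal"},
#'   \code{"vertical"}: optionally zero out single-orientation frequency
#'   stripes (default \code{"none"}).
#'
#' @seealso \code{\link{bandpassParams}}, \code{\link{fftBandpass}}
#' @exportClass BandpassParams
setClass("BandpassParams",
  representation(
    filterLarge = "numeric",
    filterSmall = "numeric",
    saturationTolerance = "numeric",
    suppressStripes = "character"
  )
)

setValidity("BandpassParams", function(object) {
  if (object@filterSmall <= 0) return("'filterSmall' must be positive")
  if (object@filterLarge <= object@filterSmall)
    return("'filterLarge' must exceed 'filterSmall'")
  if (object@saturationTolerance < 0 || object@saturationTolerance >= 50)
    return("'saturationTolerance' must lie in [0, 50)")
  if (!object@suppressStripes %in% c("none", "horizontal", "vertical"))
    return("'suppressStripes' must be none/horizontal/vertical")
  TRUE
})

#' KsmParams: settings of the dilation-erosion FAZ extraction
#'
#' Tunable parameters of the extraction pipeline: the number of successive
#' 3x3 dilations used to bridge capillary-signal interruptions, the matched
#' erosion count that restores the avascular field, the automatic threshold
#' method, the particle-size gate applied during component selection, and
#' the final Euclidean enlargement of the selected region.
#'
#' @slot nDilate successive 3x3 dilation iterations (default 10).
#' @slot nErode successive 3x3 erosion iterations (default = \code{nDilate}).
#' @slot thresholdMethod \code{"isodata"} (ImageJ's default auto-threshold)
#'   or \code{"otsu"}.
#' @slot particleMinPx,particleMaxPx component-size gate in pixels at the
#'   native 1024 x 1024 scale (defaults 5000 and 120000, bracketing the
#'   physiologic FAZ area range of roughly 0.04--1.0 mm^2 at 3/1024 mm/px);
#'   rescaled automatically when the image size differs from 1024.
#' @slot enlargePx Euclidean enlargement radius in pixels (default 4).
#' @slot centerPolicy rule for choosing among size-surviving components;
#'   only \code{"nearest_center"} is defined: smallest centroid-to-center
#'   distance, ties broken by larger area, then lower label index.
#'
#' @seealso \code{\link{ksmParams}}, \code{\link{extractFaz}}
#' @exportClass KsmParams
setClass("KsmParams",
  representation(
    nDilate = "integer",
    nErode = "integer",
    thresholdMethod = "character",
    particleMinPx = "numeric",
    particleMaxPx = "numeric",
    enlargePx = "numeric",
    centerPolicy = "character"
  )
)

setValidity("KsmParams", function(object) {
  if (object@nDilate < 1L) return("'nDilate' must be >= 1")
  if (object@nErode < 1L) return("'nErode' must be >= 1")
  if (object@enlargePx < 0) return("'enlargePx' must be >= 0")
  if (object@particleMinPx >= object@particleMaxPx)
    return("'particleMinPx' must be below 'particleMaxPx'")
  if (!object@thresholdMethod %in% c("isodata", "otsu"))
    return("'thresholdMethod' must be 'isodata' or 'otsu'")
  if (!object@centerPolicy %in% "nearest_center")
    return("unknown 'centerPolicy'")
  TRUE
})

#' FazResult: the outcome of one FAZ extraction
#'
#' @slot mask the extracted FAZ as a \code{\linkS4class{RegionMask}}
#'   (single connected component, holes filled, enlargement applied).
#' @slot areaMm2 uncorrected area: pixel count times \code{mmPerPixel^2}.
#' @slot pixelCount foreground pixel count.
#' @slot paramsUsed the \code{\linkS4class{KsmParams}} that produced it.
#' @slot eyeId eye identifier carried over from the input image.
#'
#' @seealso \code{\link{extractFaz}}
#' @exportClass FazResult
setClass("FazResult",
  representation(
    mask = "RegionMask",
    areaMm2 = "numeric",
    pixelCount = "integer",
    paramsUsed = "KsmParams",
    eyeId = "character"
  )
)

setValidity("FazResult", function(object) {
  if (object@pixelCount != sum(object@mask@pixels))
    return("'pixelCount' must equal the mask foreground count")
  expected <- object@pixelCount * object@mask@mmPerPixel^2
  if (abs(object@areaMm2 - expected) > 1e-9 * max(1, expected))
    return("'areaMm2' must equal pixelCount * mmPerPixel^2")
  TRUE
})

#' SyntheticSpec: parameters of the synthetic OCTA scene generator
#'
#' @slot size image side length in pixels (default 1024, minimum 256).
#' @slot mmExtent physical field of view in mm (default 3.0).
#' @slot fazAreaMm2 target ground-truth FAZ area in mm^2 (default 0.27;
#'   must lie in the physiologic range [0.04, 1.0]).
#' @slot fazIrregularity radial-perturbation amplitude in [0, 1) giving the
#'   FAZ boundary its lobulated shape (default 0.15).
#' @slot vesselDensity fraction of the frame covered by drawn vessels,
#'   in [0, 1] (default 0.35).
#' @slot gapRate probability that a terminal-capillary segment at the FAZ
#'   rim is dropped, emulating vessel-signal interruptions (default 0.15).
#' @slot noiseSigma log-normal multiplicative speckle scale (default 0.15).
#' @slot brightnessShift additive intensity offset emulating
#'   high-brightness capture (default 0).
#' @slot seed RNG seed; fixes the full output.
#'
#' @seealso \code{\link{syntheticSpec}}, \code{\link{renderScene}}
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    size = "integer",
    mmExtent = "numeric",
    fazAreaMm2 = "numeric",
    fazIrregularity = "numeric",
    vesselDensity = "numeric",
    gapRate = "numeric",
    noiseSigma = "numeric",
    brightnessShift = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (object@size < 256L) return("'size' must be >= 256")
  if (object@mmExtent <= 0) return("'mmExtent' must be positive")
  if (object@fazAreaMm2 < 0.04 || object@fazAreaMm2 > 1.0)
    return("'fazAreaMm2' must lie in [0.04, 1.0]")
  if (object@fazIrregularity < 0 || object@fazIrregularity >= 1)
    return("'fazIrregularity' must lie in [0, 1)")
  if (object@vesselDensity < 0 || object@vesselDensity > 1)
    return("'vesselDensity' must lie in [0, 1]")
  if (object@gapRate < 0 || object@gapRate > 1)
    return("'gapRate' must lie in [0, 1]")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  TRUE
})

#' SyntheticScene: a rendered synthetic OCTA image with ground truth
#'
#' @slot image the rendered \code{\linkS4class{EnFaceImage}}.
#' @slot truthMask the ground-truth FAZ \code{\linkS4class{RegionMask}}
#'   (one simply connected component containing the image center, with
#'   pixel area within 2\% of the requested physical area).
#' @slot spec the \code{\linkS4class{SyntheticSpec}} that produced it.
#' @slot vesselFraction fraction of pixels covered by drawn vessel strokes
#'   before noise; recorded so binarization accuracy can be audited.
#'
#' @seealso \code{\link{renderScene}}
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    image = "EnFaceImage",
    truthMask = "RegionMask",
    spec = "SyntheticSpec",
    vesselFraction = "numeric"
  )
)

#' ComparisonReport: the method-agreement evaluation bundle
#'
#' Produced by \code{\link{compareMethods}}. Holds the per-eye, per-pair
#' record table plus summary tables laid out the way FAZ agreement studies
#' report them: per-method areas with a Friedman test, per-pair CV with
#' Spearman correlations, per-pair Jaccard/Dice summaries, and per-pair
#' false-negative/false-positive means with paired Wilcoxon tests.
#'
#' @slot records per-eye, per-pair metric data frame.
#' @slot areaTable per-method area summary (mean, SD) plus Friedman p.
#' @slot cvTable per-pair CV summary with 95\% CI, Spearman rho and p.
#' @slot similarityTable per-pair Jaccard and Dice means with 95\% CI.
#' @slot fnFpTable per-pair mean FN\%/FP\% with paired Wilcoxon p.
#' @slot tests list of the underlying test objects and adjusted p-values.
#'
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(
    records = "data.frame",
    areaTable = "data.frame",
    cvTable = "data.frame",
    similarityTable = "data.frame",
    fnFpTable = "data.frame",
    tests = "list"
  )
)
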