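#' Construct an EnFaceImage
#'
#' @param pixels numeric matrix of intensities in \code{[0, 255]}.
#' @param mmPerPixel physical scale in mm/px (default \code{3/1024}, the
#'   3 mm macular field exported at 1024 px).
#' @param eyeId optional eye identifier.
#' @param axialLengthMm optional measured axial length (mm).
#' @return an \code{\linkS4class{EnFaceImage}}.
#' @examples
#' img <- EnFaceImage(matrix(runif(64 * 64, 0, 255), 64, 64))
#' dim(pixels(img))
#' @export
EnFaceImage <- function(pixels, mmPerPixel = 3 / 1024,
                        eyeId = NA_character_,
                        axialLengthMm = NA_real_) {
  new("EnFaceImage", pixels = pixels, mmPerPixel = mmPerPixel,
      eyeId = as.character(eyeId), axialLengthMm = as.numeric(axialLengthMm))
}

#' Construct a RegionMask
#'
#' @param pixels logical matrix (or a numeric matrix, coerced by
#'   \code{> 0}); \code{TRUE} is foreground.
#' @param mmPerPixel physical scale in mm/px.
#' @param eyeId optional eye identifier.
#' @return a \code{\linkS4class{RegionMask}}.
#' @export
RegionMask <- function(pixels, mmPerPixel = 3 / 1024,
                       eyeId = NA_character_) {
  if (is.numeric(pixels)) {
    d <- dim(pixels)
    pixels <- pixels > 0
    dim(pixels) <- d
  }
  new("RegionMask", pixels = pixels, mmPerPixel = mmPerPixel,
      eyeId = as.character(eyeId))
}

#' Construct an RoiPolygon
#'
#' @param vertices numeric matrix with columns \code{(row, col)} in 0-based
#'   pixel-center coordinates; at least 3 distinct vertices.
#' @param eyeId optional eye identifier.
#' @return an \code{\linkS4class{RoiPolygon}}.
#' @export
RoiPolygon <- function(vertices, eyeId = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("row", "col")
  new("RoiPolygon", vertices = vertices, eyeId = as.character(eyeId))
}

#' Bandpass filter settings
#'
#' Defaults follow the noise-processing stage of the extraction macro:
#' pass structures between 3.5 and 1024 px, autoscale with 5\% saturation,
#' no stripe suppression.
#'
#' @param filterLarge largest passed structure size, px.
#' @param filterSmall smallest passed structure size, px.
#' @param saturationTolerance autoscale saturation, percent.
#' @param suppressStripes \code{"none"}, \code{"horizontal"} or
#'   \code{"vertical"}.
#' @return a \code{\linkS4class{BandpassParams}}.
#' @export
bandpassParams <- function(filterLarge = 1024, filterSmall = 3.5,
                           saturationTolerance = 5,
                           suppressStripes = "none") {
  new("BandpassParams", filterLarge = as.numeric(filterLarge),
      filterSmall = as.numeric(filterSmall),
      saturationTolerance = as.numeric(saturationTolerance),
      suppressStripes = suppressStripes)
}

#' FAZ extraction settings
#'
#' @param nDilate successive 3x3 dilations bridging capillary gaps.
#' @param nErode matched 3x3 erosions restoring the avascular field
#'   (defaults to \code{nDilate}).
#' @param thresholdMethod \code{"isodata"} or \code{"otsu"}.
#' @param particleMinPx,particleMaxPx component-size gate (px) at the
#'   native 1024 scale.
#' @param enlargePx final Euclidean enlargement radius, px.
#' @param centerPolicy component choice rule; see
#'   \code{\linkS4class{KsmParams}}.
#' @return a \code{\linkS4class{KsmParams}}.
#' @examples
#' ksmParams(nDilate = 12, enlargePx = 4)
#' @export
ksmParams <- function(nDilate = 10L, nErode = nDilate,
                      thresholdMethod = "isodata",
                      particleMinPx = 5000, particleMaxPx = 120000,
                      enlargePx = 4, centerPolicy = "nearest_center") {
  new("KsmParams", nDilate = as.integer(nDilate), nErode = as.integer(nErode),
      thresholdMethod = thresholdMethod,
      particleMinPx = as.numeric(particleMinPx),
      particleMaxPx = as.numeric(particleMaxPx),
      enlargePx = as.numeric(enlargePx), centerPolicy = centerPolicy)
}

#' Synthetic OCTA scene parameters
#'
#' Defaults emulate a healthy-eye superficial-layer scan: a 3 mm field at
#' 1024 px, a 0.27 mm^2 mildly lobulated FAZ, a capillary network covering
#' about a third of the frame, occasional signal dropouts at the FAZ rim,
#' and moderate multiplicative speckle.
#'
#' @param size image side, px (>= 256).
#' @param mmExtent field of view, mm.
#' @param fazAreaMm2 target ground-truth FAZ area, mm^2.
#' @param fazIrregularity radial perturbation amplitude in [0, 1).
#' @param vesselDensity vessel coverage fraction in [0, 1].
#' @param gapRate rim-capillary dropout probability in [0, 1].
#' @param noiseSigma log-normal speckle scale.
#' @param brightnessShift additive intensity offset (high-brightness
#'   capture emulation).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SyntheticSpec}}.
#' @export
syntheticSpec <- function(size = 1024L, mmExtent = 3.0, fazAreaMm2 = 0.27,
                          fazIrregularity = 0.15, vesselDensity = 0.35,
                          gapRate = 0.15, noiseSigma = 0.15,
                          brightnessShift = 0, seed = 1L) {
  new("SyntheticSpec", size = as.integer(size), mmExtent = as.numeric(mmExtent),
      fazAreaMm2 = as.numeric(fazAreaMm2),
      fazIrregularity = as.numeric(fazIrregularity),
      vesselDensity = as.numeric(vesselDensity), gapRate = as.numeric(gapRate),
      noiseSigma = as.numeric(noiseSigma),
      brightnessShift = as.numeric(brightnessShift), seed = as.integer(seed))
}

#' Preset synthetic acquisition variants
#'
#' \code{"default"} is the calibration regime; \code{"bright"} emulates
#' high-brightness capture (large additive shift with mild contrast
#' compression applied at render time); \code{"noisy"} doubles the speckle
#' scale and the rim dropout rate.
#'
#' @param preset one of \code{"default"}, \code{"bright"}, \code{"noisy"}.
#' @param seed RNG seed.
#' @param ... further arguments forwarded to \code{\link{syntheticSpec}}.
#' @return a \code{\linkS4class{SyntheticSpec}}.
#' @export
syntheticPreset <- function(preset = c("default", "bright", "noisy"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  switch(preset,
    default = syntheticSpec(seed = seed, ...),
    bright = syntheticSpec(seed = seed, brightnessShift = 60, ...),
    noisy = syntheticSpec(seed = seed, noiseSigma = 0.30, gapRate = 0.30, ...))
}
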