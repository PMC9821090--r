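#' Binarize the vascular signal
#'
#' Global automatic thresholding of the (possibly denoised) en face image:
#' pixels above the histogram threshold are vessel signal. The default
#' method is the iterative intermeans (isodata) threshold, the behavior of
#' ImageJ's default auto-threshold; Otsu's method is selectable.
#'
#' @param img an \code{\linkS4class{EnFaceImage}}; must not be constant.
#' @param method \code{"isodata"} or \code{"otsu"}.
#' @return a \code{\linkS4class{RegionMask}} of the vessel signal.
#' @export
binarizeVasculature <- function(img, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  px <- pixels(img)
  if (min(px) == max(px))
    stop("constant image: no threshold separates vessel from background")
  thr <- switch(method,
    isodata = .isodataThreshold(px),
    otsu = EBImage::otsu(px / 255, range = c(0, 1), levels = 256) * 255)
  RegionMask(px > thr, mmPerPixel = img@mmPerPixel, eyeId = img@eyeId)
}

# iterative intermeans on the rounded 0-255 histogram
.isodataThreshold <- function(px) {
  v <- round(as.vector(px))
  t0 <- mean(v)
  repeat {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 0.5) { t0 <- t1; break }
    t0 <- t1
  }
  t0
}

#' Bridge capillary-signal gaps by successive dilations
#'
#' \code{nDilate} iterations of binary dilation with a 3x3 structuring
#' element (applied as one dilation with a \code{(2 nDilate + 1)}-pixel box
#' brush, which is exactly equivalent). Interruptions in the vascular
#' signal up to about \code{2 nDilate} px across are connected.
#'
#' @param vessels a binary \code{\linkS4class{RegionMask}} of vessel signal.
#' @param nDilate iteration count; 0 is the identity.
#' @return the dilated \code{\linkS4class{RegionMask}}.
#' @export
closeVesselGaps <- function(vessels, nDilate = 10L) {
  stopifnot(nDilate >= 0)
  if (nDilate == 0L) return(vessels)
  m <- .morphBox(pixels(vessels), nDilate, EBImage::dilate)
  RegionMask(m, mmPerPixel = vessels@mmPerPixel, eyeId = vessels@eyeId)
}

#' Recover the avascular field by matched erosions
#'
#' The dilated vessel mask undergoes \code{nErode} iterations of 3x3
#' erosion (pixels outside the frame count as background) and the
#' complement is returned: as the vessels shrink back, the avascular
#' region -- foveal center included -- grows back as foreground.
#'
#' @param closed the gap-bridged vessel \code{\linkS4class{RegionMask}}.
#' @param nErode iteration count; 0 complements without eroding.
#' @return a \code{\linkS4class{RegionMask}} of the avascular field.
#' @export
recoverFazRegion <- function(closed, nErode = 10L) {
  stopifnot(nErode >= 0)
  m <- pixels(closed)
  if (nErode > 0L) m <- .morphBox(m, nErode, EBImage::erode)
  RegionMask(!m, mmPerPixel = closed@mmPerPixel, eyeId = closed@eyeId)
}

# n iterations of a 3x3 box operation as one (2n+1) box-brush pass
.morphBox <- function(m, n, op) {
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  out <- op(num, EBImage::makeBrush(2L * as.integer(n) + 1L, "box"))
  matrix(out > 0.5, nrow(m), ncol(m))
}

#' Select the foveal avascular component by particle analysis
#'
#' Connected components (8-connectivity) of the avascular field are
#' size-gated: components outside
#' \code{[particleMinPx, particleMaxPx]} (scaled by image area relative to
#' the native 1024 x 1024 frame) are discarded. Among the survivors the
#' component whose centroid lies nearest the image center is returned
#' alone, with interior holes filled; ties break toward the larger
#' component, then the lower label index.
#'
#' @param avascular the avascular \code{\linkS4class{RegionMask}}.
#' @param params a \code{\linkS4class{KsmParams}}.
#' @return the selected single-component \code{\linkS4class{RegionMask}}.
#' @section Errors: if no component survives the size gate, an error of
#'   class \code{"fazExtractionError"} is signalled carrying the component
#'   size census in its \code{census} field.
#' @export
selectFazComponent <- function(avascular, params = ksmParams()) {
  validObject(params)
  m <- pixels(avascular)
  h <- nrow(m); w <- ncol(m)
  scale <- (h * w) / 1024^2
  gate <- c(params@particleMinPx, params@particleMaxPx) * scale
  lab <- .label8(m)
  k <- max(lab)
  sizes <- if (k > 0L) tabulate(lab[lab > 0L], nbins = k) else integer(0)
  keep <- which(sizes >= gate[1] & sizes <= gate[2])
  if (!length(keep)) {
    stop(errorCondition(
      sprintf(paste0("extraction failure: no avascular component within ",
                     "the size gate [%d, %d] px (%d component(s) seen)"),
              round(gate[1]), round(gate[2]), k),
      class = c("fazExtractionError", "error"),
      census = sizes, gate = gate))
  }
  center <- c((h - 1) / 2, (w - 1) / 2)        # 0-based pixel-center coords
  stats <- t(vapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    cen <- colMeans(idx) - 1                    # 0-based centroid
    c(dist = sqrt(sum((cen - center)^2)), area = nrow(idx))
  }, numeric(2)))
  ord <- order(stats[, "dist"], -stats[, "area"], keep)
  chosen <- keep[ord[1]]
  sel <- lab == chosen
  sel <- matrix(EBImage::fillHull(matrix(as.numeric(sel), h, w)) > 0.5, h, w)
  RegionMask(sel, mmPerPixel = avascular@mmPerPixel, eyeId = avascular@eyeId)
}

#' Enlarge a region by a Euclidean distance band
#'
#' Expands the foreground to every pixel within Euclidean distance
#' \code{enlargePx} of the original component (distance-map thresholding,
#' the raster semantics of ImageJ's "Enlarge..." for selections, which
#' yields round corners rather than the square corners of iterated 3x3
#' dilation). The component count is unchanged.
#'
#' @param faz a single-component \code{\linkS4class{RegionMask}}.
#' @param enlargePx enlargement radius, px; 0 is the identity.
#' @return the enlarged \code{\linkS4class{RegionMask}}. If the enlarged
#'   region reaches the image border a warning is issued and the result is
#'   clipped to the frame.
#' @export
enlargeRegion <- function(faz, enlargePx = 4) {
  stopifnot(enlargePx >= 0)
  m <- pixels(faz)
  if (enlargePx == 0 || !any(m)) return(faz)
  d <- EBImage::distmap(matrix(as.numeric(!m), nrow(m), ncol(m)))
  out <- m | (matrix(d, nrow(m), ncol(m)) <= enlargePx)
  if (any(out[1, ]) || any(out[nrow(out), ]) ||
      any(out[, 1]) || any(out[, ncol(out)]))
    warning("enlarged region touches the image border; clipped to frame")
  RegionMask(out, mmPerPixel = faz@mmPerPixel, eyeId = faz@eyeId)
}

#' Extract the foveal avascular zone from an en face OCTA image
#'
#' The full extraction pipeline: FFT bandpass denoising, automatic
#' binarization of the vascular signal, successive dilations bridging
#' capillary-signal interruptions, matched erosions restoring the
#' avascular field, size-gated particle selection of the central
#' component, and a final Euclidean enlargement. Deterministic for fixed
#' input and parameters.
#'
#' @param img an \code{\linkS4class{EnFaceImage}}.
#' @param params a \code{\linkS4class{KsmParams}}.
#' @param bandpass a \code{\linkS4class{BandpassParams}}, or \code{NULL}
#'   to skip the noise-processing stage.
#' @return a \code{\linkS4class{FazResult}}.
#' @section Errors: extraction failures propagate as
#'   \code{"fazExtractionError"} conditions whose message names the failing
#'   stage.
#' @examples
#' scene <- renderScene(syntheticSpec(size = 512, seed = 7))
#' res <- extractFaz(sceneImage(scene))
#' jaccardIndex(fazMask(res), truthMask(scene))
#' @export
extractFaz <- function(img, params = ksmParams(), bandpass = bandpassParams()) {
  validObject(params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("[%s] %s", name, conditionMessage(e)),
        class = c("fazExtractionError", "error"),
        census = if (!is.null(e$census)) e$census else NULL))
    })
  }
  pre <- if (is.null(bandpass)) img else
    stage("bandpass", fftBandpass(img, bandpass))
  vessels <- stage("binarize",
                   binarizeVasculature(pre, params@thresholdMethod))
  closed <- stage("dilate", closeVesselGaps(vessels, params@nDilate))
  avascular <- stage("erode", recoverFazRegion(closed, params@nErode))
  sel <- stage("select", selectFazComponent(avascular, params))
  enlarged <- stage("enlarge",
                    suppressWarnings(enlargeRegion(sel, params@enlargePx)))
  n <- sum(pixels(enlarged))
  new("FazResult", mask = enlarged, areaMm2 = n * img@mmPerPixel^2,
      pixelCount = as.integer(n), paramsUsed = params, eyeId = img@eyeId)
}
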