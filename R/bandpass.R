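#' FFT bandpass denoising
#'
#' Frequency-domain bandpass in the style of ImageJ's "Bandpass Filter":
#' structures larger than \code{filterLarge} px and smaller than
#' \code{filterSmall} px are attenuated by a difference-of-Gaussians weight
#' on the spatial-frequency magnitude. The image is mirror-padded to a
#' square power-of-two frame at least 1.5 times the larger side (so border
#' pixels see a seamless reflection rather than a wrap-around), transformed,
#' weighted, inverse-transformed, cropped back, and contrast-autoscaled
#' with \code{\link{autoscaleSaturate}}.
#'
#' The Gaussian cutoffs are placed at half amplitude: a sinusoidal
#' structure exactly at \code{filterSmall} (or \code{filterLarge}) px is
#' attenuated to 50\% amplitude, structures well inside the band pass
#' essentially unchanged. The DC term (image mean) passes whenever
#' \code{filterLarge} is at least the image size, so a constant image comes
#' back unchanged. Exact replication of ImageJ's FFT code path is not
#' attempted; the filter is specified by its band behavior.
#'
#' @param img an \code{\linkS4class{EnFaceImage}}.
#' @param params a \code{\linkS4class{BandpassParams}}.
#' @return a filtered \code{\linkS4class{EnFaceImage}} with intensities
#'   rescaled to 0--255.
#' @examples
#' img <- renderScene(syntheticSpec(size = 256, seed = 3))@image
#' filtered <- fftBandpass(img, bandpassParams(filterLarge = 256))
#' @export
fftBandpass <- function(img, params = bandpassParams()) {
  validObject(params)
  px <- pixels(img)
  h <- nrow(px); w <- ncol(px)
  n <- 2^ceiling(log2(1.5 * max(h, w)))
  padded <- .mirrorPad(px, n)
  fr <- .freqAxis(n)
  f2 <- outer(fr^2, fr^2, "+")          # squared frequency magnitude
  k <- log(2)                            # half-amplitude at the named size
  wgt <- (1 - exp(-f2 * params@filterLarge^2 * k)) *
    exp(-f2 * params@filterSmall^2 * k)
  if (params@filterLarge >= max(h, w)) wgt[1, 1] <- 1
  if (params@suppressStripes == "horizontal") {
    wgt[-1, 1] <- 0                      # energy of horizontal stripes
  } else if (params@suppressStripes == "vertical") {
    wgt[1, -1] <- 0
  }
  ft <- stats::fft(padded) * wgt
  out <- Re(stats::fft(ft, inverse = TRUE)) / (n * n)
  off <- floor((n - c(h, w)) / 2)
  out <- out[(off[1] + 1):(off[1] + h), (off[2] + 1):(off[2] + w)]
  out <- .autoscale(out, params@saturationTolerance)
  new("EnFaceImage", pixels = out, mmPerPixel = img@mmPerPixel,
      eyeId = img@eyeId, axialLengthMm = img@axialLengthMm)
}

# frequency (cycles/px) for each index of an n-point transform
.freqAxis <- function(n) {
  i <- 0:(n - 1)
  pmin(i, n - i) / n
}

# center a matrix in an n x n frame, filling the margin by reflection
.mirrorPad <- function(px, n) {
  h <- nrow(px); w <- ncol(px)
  offr <- floor((n - h) / 2); offc <- floor((n - w) / 2)
  reflect <- function(i, m) {
    j <- ((i - 1) %% (2 * m))
    ifelse(j < m, j + 1, 2 * m - j)
  }
  ri <- reflect(seq_len(n) - offr, h)
  ci <- reflect(seq_len(n) - offc, w)
  px[ri, ci, drop = FALSE]
}

#' Percentile-clipped contrast autoscale
#'
#' Clips the lowest and highest \code{tolerance/2} percent of pixel values
#' and maps the remaining range linearly onto 0--255 (the "autoscale after
#' filtering" behavior, with \code{tolerance} percent of pixels saturated).
#' A constant input is returned unchanged.
#'
#' @param img an \code{\linkS4class{EnFaceImage}} or a numeric matrix.
#' @param tolerance saturated fraction, percent, in [0, 50).
#' @return the rescaled input, same type as given.
#' @export
autoscaleSaturate <- function(img, tolerance = 5) {
  if (is(img, "EnFaceImage")) {
    new("EnFaceImage", pixels = .autoscale(pixels(img), tolerance),
        mmPerPixel = img@mmPerPixel, eyeId = img@eyeId,
        axialLengthMm = img@axialLengthMm)
  } else {
    .autoscale(img, tolerance)
  }
}

.autoscale <- function(px, tolerance) {
  stopifnot(tolerance >= 0, tolerance < 50)
  if (min(px) == max(px)) return(px)      # constant input: identity
  q <- stats::quantile(px, c(tolerance / 200, 1 - tolerance / 200),
                       names = FALSE, type = 7)
  clipped <- pmin(pmax(px, q[1]), q[2])
  # clipped range can degenerate when the central mass is constant; the
  # tails are still saturated, to 0
  if (q[2] <= q[1]) return(clipped * 0)
  round((clipped - q[1]) / (q[2] - q[1]) * 255)
}
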