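# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a ground-truth FAZ shape
#'
#' Builds a star-convex region around the image center from a radial
#' harmonic perturbation of a circle (harmonics 2--5 with seeded random
#' phases, total relative amplitude set by \code{fazIrregularity}), then
#' rescales the radius iteratively until the pixel area matches the target
#' physical area to within 2\%.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @return a \code{\linkS4class{RegionMask}}: one simply connected
#'   component containing the image center.
#' @export
makeFazShape <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .fazShapeImpl(spec))
}

.fazShapeImpl <- function(spec) {
  size <- spec@size
  mmpp <- spec@mmExtent / size
  targetPx <- spec@fazAreaMm2 / mmpp^2
  r0 <- sqrt(targetPx / pi)
  if (r0 * (1 + spec@fazIrregularity) > size / 2 - 12)
    stop("target FAZ area unreachable at this image size")
  # radial perturbation: harmonics 2-5, amplitudes ~ 1/m, random phases
  mharm <- 2:5
  amp <- (spec@fazIrregularity / mharm) / sum(1 / mharm)
  phase <- stats::runif(length(mharm), 0, 2 * pi)
  cen <- (size - 1) / 2
  rc <- seq_len(size) - 1 - cen
  dr <- matrix(rc, size, size)
  dc <- matrix(rc, size, size, byrow = TRUE)
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  pert <- 1
  for (i in seq_along(mharm))
    pert <- pert + amp[i] * cos(mharm[i] * theta + phase[i])
  pert <- pmax(pert, 0.2)
  scale <- 1
  for (it in 1:12) {
    inside <- rad <= r0 * scale * pert
    area <- sum(inside)
    if (abs(area - targetPx) / targetPx <= 0.015) break
    scale <- scale * sqrt(targetPx / area)
  }
  if (abs(sum(inside) - targetPx) / targetPx > 0.02)
    stop("FAZ area calibration did not converge")
  RegionMask(inside, mmPerPixel = mmpp,
             eyeId = sprintf("synth%04d", spec@seed))
}

#' Render a synthetic en face OCTA scene
#'
#' Draws a bright capillary network on a dark background around a
#' ground-truth FAZ: procedural quadratic-Bezier vessel strokes avoiding
#' the FAZ interior, a ring of terminal capillaries straddling the FAZ
#' boundary with seeded segment dropouts (rate \code{gapRate}), then
#' multiplicative log-normal speckle, an optional high-brightness shift
#' with mild contrast compression, and clipping to 8 bits. Fully
#' deterministic under \code{seed}.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @return a \code{\linkS4class{SyntheticScene}} bundling the rendered
#'   image, the ground-truth mask and the spec.
#' @examples
#' scene <- renderScene(syntheticSpec(size = 256, seed = 1))
#' scene
#' @export
renderScene <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    truth <- .fazShapeImpl(spec)
    size <- spec@size
    m <- pixels(truth)
    num <- function(x) matrix(as.numeric(x), size, size)
    b5 <- EBImage::makeBrush(5, "box")
    grown <- EBImage::dilate(num(m), b5) > 0.5
    shrunk <- EBImage::erode(num(m), b5) > 0.5
    ring <- grown & !shrunk            # capillary band straddling the rim
    exclude <- grown                   # interior vessels keep out of here
    canvas <- matrix(FALSE, size, size)

    # terminal capillary ring with segment dropouts
    cen <- (size - 1) / 2
    ridx <- which(ring, arr.ind = TRUE)
    ang <- atan2(ridx[, 2] - 1 - cen, ridx[, 1] - 1 - cen)
    perim <- 2 * pi * sqrt(sum(m) / pi)
    nseg <- max(8L, round(perim / 8))
    seg <- pmin(nseg, floor((ang + pi) / (2 * pi) * nseg) + 1L)
    dropped <- stats::runif(nseg) < spec@gapRate
    keep <- !dropped[seg]
    canvas[ridx[keep, , drop = FALSE]] <- TRUE

    # interior vessel strokes until the requested coverage is reached
    allowed <- !exclude
    targetCover <- spec@vesselDensity * sum(allowed)
    covered <- 0L
    offs <- list(cbind(0, 0),
                 as.matrix(expand.grid(-1:1, -1:1)),
                 as.matrix(expand.grid(-2:2, -2:2)))
    tries <- 0L
    while (covered < targetCover && tries < 6000L) {
      tries <- tries + 1L
      p0 <- stats::runif(2, 0, size - 1)
      p2 <- stats::runif(2, 0, size - 1)
      mid <- (p0 + p2) / 2
      d <- p2 - p0
      len <- sqrt(sum(d^2))
      if (len < size / 8) next
      perp <- c(-d[2], d[1]) / len
      p1 <- mid + perp * stats::rnorm(1, 0, len / 4)
      tt <- seq(0, 1, length.out = max(16L, ceiling(1.6 * len)))
      br <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
      bc <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
      pr <- round(br); pc <- round(bc)
      ok <- pr >= 0 & pr < size & pc >= 0 & pc < size
      pr <- pr[ok]; pc <- pc[ok]
      if (!length(pr)) next
      ok <- allowed[cbind(pr + 1, pc + 1)]
      pr <- pr[ok]; pc <- pc[ok]
      if (!length(pr)) next
      o <- offs[[sample.int(3L, 1L, prob = c(0.35, 0.5, 0.15))]]
      er <- rep(pr, each = nrow(o)) + o[, 1]
      ec <- rep(pc, each = nrow(o)) + o[, 2]
      ok <- er >= 0 & er < size & ec >= 0 & ec < size
      lin <- unique((ec[ok]) * size + er[ok] + 1L)
      covered <- covered + sum(!canvas[lin] & allowed[lin])
      canvas[lin] <- TRUE
    }
    vesselFraction <- sum(canvas) / size^2

    img <- matrix(25, size, size)
    img[canvas] <- 205
    img[canvas & ring] <- 215
    if (spec@brightnessShift != 0) {
      # high-brightness capture: additive lift with contrast compression
      # about the scene mean (the flattened, displaced histogram regime)
      mu <- mean(img)
      img <- mu + (img - mu) * 0.55 + spec@brightnessShift
    }
    # speckle is signal-dependent: applied to the acquired signal, so a
    # lifted background carries proportionally larger excursions
    if (spec@noiseSigma > 0)
      img <- img * exp(stats::rnorm(size^2, 0, spec@noiseSigma) -
                         spec@noiseSigma^2 / 2)
    img <- round(pmin(pmax(img, 0), 255))
    scene <- new("SyntheticScene",
      image = EnFaceImage(img, mmPerPixel = spec@mmExtent / size,
                          eyeId = sprintf("synth%04d", spec@seed)),
      truthMask = truth, spec = spec, vesselFraction = vesselFraction)
    scene
  })
}
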