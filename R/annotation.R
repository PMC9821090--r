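#' Batch FAZ extraction over an image stack
#'
#' Applies \code{\link{extractFaz}} to every image of an ordered stack in
#' stable order, grouped into chunks (default 5, the cadence at which a
#' human can confirm extractions before the ROIs are committed). Failures
#' are collected, not fatal: a stack with one unextractable image still
#' yields results for the rest.
#'
#' @param images list of \code{\linkS4class{EnFaceImage}}s.
#' @param chunkSize images per confirmation chunk (>= 1).
#' @param params a \code{\linkS4class{KsmParams}}.
#' @param bandpass a \code{\linkS4class{BandpassParams}} or \code{NULL}.
#' @param reviewHook optional function called once per chunk with
#'   \code{(chunkIndex, results)} after the chunk completes; the batch
#'   never blocks on it.
#' @return list with \code{results} (per-image \code{FazResult} or
#'   \code{NULL} on failure, input order), \code{failures} (data frame of
#'   index + message) and \code{chunks} (list of index vectors).
#' @export
processStack <- function(images, chunkSize = 5L, params = ksmParams(),
                         bandpass = bandpassParams(), reviewHook = NULL) {
  if (length(images) == 0L) stop("empty image stack")
  stopifnot(chunkSize >= 1L)
  idx <- seq_along(images)
  chunks <- split(idx, ceiling(idx / chunkSize))
  results <- vector("list", length(images))
  fails <- list()
  for (ci in seq_along(chunks)) {
    for (i in chunks[[ci]]) {
      r <- tryCatch(extractFaz(images[[i]], params, bandpass),
                    error = function(e) e)
      if (inherits(r, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(index = i, message = conditionMessage(r))
      } else {
        results[[i]] <- r
      }
    }
    if (is.function(reviewHook)) reviewHook(ci, results[chunks[[ci]]])
  }
  list(results = results,
       failures = if (length(fails)) do.call(rbind, fails)
                  else data.frame(index = integer(0), message = character(0)),
       chunks = unname(chunks))
}

#' Create a binary label image
#'
#' The annotation primitive: a raster of the given shape suffused with
#' black (0) and the region filled with white (255) -- the
#' question/answer pair format for supervised segmentation training.
#'
#' @param shape integer vector \code{c(height, width)}.
#' @param region a \code{\linkS4class{RegionMask}} matching \code{shape},
#'   or an \code{\linkS4class{RoiPolygon}} fitting within it.
#' @param mmPerPixel physical scale of the label.
#' @return a \code{\linkS4class{RegionMask}} (serializes to exactly
#'   \{0, 255\}).
#' @export
makeLabelImage <- function(shape, region, mmPerPixel = 3 / 1024) {
  if (is(region, "RoiPolygon"))
    return(polygonToMask(region, shape[1], shape[2], mmPerPixel))
  if (!is(region, "RegionMask"))
    stop("'region' must be a RegionMask or RoiPolygon")
  if (!identical(as.integer(dim(pixels(region))), as.integer(shape)))
    stop("region geometry does not match the requested shape")
  RegionMask(pixels(region), mmPerPixel = mmPerPixel, eyeId = region@eyeId)
}

#' A paired training sample
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param label a \code{\linkS4class{RegionMask}} of the same geometry.
#' @param source source eye identifier.
#' @param transform transform tag (\code{"orig"}, \code{"fliph"}, ...).
#' @return a \code{datasetPair} list.
#' @export
datasetPair <- function(image, label, source = eyeId(image),
                        transform = "orig") {
  if (!identical(dim(pixels(image)), dim(pixels(label))))
    stop("image and label geometry differ")
  structure(list(image = image, label = label, source = source,
                 transform = transform), class = "datasetPair")
}

.tfm <- function(m, op) {
  switch(op,
    orig = m,
    fliph = m[, ncol(m):1, drop = FALSE],
    flipv = m[nrow(m):1, , drop = FALSE],
    rot90 = t(m[nrow(m):1, , drop = FALSE]),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = t(m)[nrow(m):1, , drop = FALSE],
    stop("unknown transform: ", op))
}

#' Amplify a dataset by flips and rotations
#'
#' Applies each requested isometry identically to image and label; the
#' output keeps the originals, so \code{k} transforms multiply the pair
#' count by \code{1 + k}. Quarter turns require square frames.
#'
#' @param pairs list of \code{\link{datasetPair}}s.
#' @param ops subset of \code{c("fliph", "flipv", "rot90", "rot180",
#'   "rot270")}.
#' @return the amplified list of pairs, provenance tags set.
#' @export
amplifyDataset <- function(pairs,
                           ops = c("fliph", "flipv", "rot90", "rot180",
                                   "rot270")) {
  ops <- match.arg(ops, several.ok = TRUE)
  if (!length(ops)) stop("'ops' must name at least one transform")
  out <- pairs
  for (op in ops) {
    for (p in pairs) {
      d <- dim(pixels(p$image))
      if (op %in% c("rot90", "rot270") && d[1] != d[2])
        stop("quarter-turn amplification requires square images")
      img <- p$image
      lab <- p$label
      out[[length(out) + 1L]] <- datasetPair(
        new("EnFaceImage", pixels = .tfm(pixels(img), op),
            mmPerPixel = img@mmPerPixel, eyeId = img@eyeId,
            axialLengthMm = img@axialLengthMm),
        RegionMask(.tfm(pixels(lab), op), mmPerPixel = lab@mmPerPixel,
                   eyeId = lab@eyeId),
        source = p$source, transform = op)
    }
  }
  out
}

# nearest-neighbour index map: no interpolation, value sets preserved
.nnIndex <- function(from, to) {
  pmin(from, floor((seq_len(to) - 0.5) * from / to) + 1L)
}

.nnResize <- function(m, to) {
  m[.nnIndex(nrow(m), to), .nnIndex(ncol(m), to), drop = FALSE]
}

#' Export a training set at network resolution
#'
#' Resizes every pair to \code{resizeTo} px square with nearest-neighbour
#' sampling (interpolation "none": labels stay strictly binary), crops to
#' \code{cropTo} px, and writes matched PNG pairs named
#' \code{<source>__<transform>__\{img,label\}.png} plus a CSV manifest.
#'
#' @param pairs list of \code{\link{datasetPair}}s.
#' @param outDir output directory (created if missing).
#' @param resizeTo resized side, px (default 512).
#' @param cropTo cropped side, px (default 256); must not exceed
#'   \code{resizeTo}.
#' @param cropMode \code{"center"} (keeps the fovea) or \code{"fourtile"}
#'   (four non-overlapping corner tiles, maximizing data).
#' @return the manifest data frame (columns source, transform, img_path,
#'   label_path, faz_px), also written to \code{manifest.csv}.
#' @export
exportTrainingSet <- function(pairs, outDir, resizeTo = 512L, cropTo = 256L,
                              cropMode = c("center", "fourtile")) {
  cropMode <- match.arg(cropMode)
  if (cropTo > resizeTo) stop("'cropTo' must not exceed 'resizeTo'")
  if (cropMode == "fourtile" && 2L * cropTo > resizeTo)
    stop("'fourtile' needs resizeTo >= 2 * cropTo")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in pairs) {
    img <- .nnResize(pixels(p$image), resizeTo)
    lab <- .nnResize(pixels(p$label), resizeTo)
    crops <- if (cropMode == "center") {
      off <- floor((resizeTo - cropTo) / 2)
      list(list(tag = "", r = off, c = off))
    } else {
      list(list(tag = "+tl", r = 0L, c = 0L),
           list(tag = "+tr", r = 0L, c = resizeTo - cropTo),
           list(tag = "+bl", r = resizeTo - cropTo, c = 0L),
           list(tag = "+br", r = resizeTo - cropTo, c = resizeTo - cropTo))
    }
    for (cr in crops) {
      ri <- (cr$r + 1L):(cr$r + cropTo)
      ci <- (cr$c + 1L):(cr$c + cropTo)
      tag <- paste0(p$transform, cr$tag)
      stemOk <- gsub("[^A-Za-z0-9_+-]", "_", paste0(p$source, "__", tag))
      imgPath <- file.path(outDir, paste0(stemOk, "__img.png"))
      labPath <- file.path(outDir, paste0(stemOk, "__label.png"))
      png::writePNG(round(img[ri, ci]) / 255, imgPath)
      png::writePNG((lab[ri, ci]) * 1.0, labPath)
      rows[[length(rows) + 1L]] <- data.frame(
        source = p$source, transform = tag,
        img_path = basename(imgPath), label_path = basename(labPath),
        faz_px = sum(lab[ri, ci]))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
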