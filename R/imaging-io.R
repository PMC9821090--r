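#' Read an en face OCTA image
#'
#' Reads a PNG or TIFF raster into an \code{\linkS4class{EnFaceImage}}.
#' Multi-channel inputs are collapsed by standard luminance weighting
#' (0.299 R + 0.587 G + 0.114 B); inputs deeper than 8 bits are linearly
#' min-max rescaled to 0--255.
#'
#' @param path file path (\code{.png}, \code{.tif}/\code{.tiff}).
#' @param mmPerPixel physical scale, mm/px.
#' @param eyeId optional eye identifier.
#' @param axialLengthMm optional axial length, mm.
#' @return an \code{\linkS4class{EnFaceImage}} with integer intensities
#'   in 0--255.
#' @seealso \code{\link{writeEnFace}}
#' @export
readEnFace <- function(path, mmPerPixel = 3 / 1024, eyeId = NA_character_,
                       axialLengthMm = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff"))
    stop("unsupported image format: .", ext)
  raw <- .toGray(path, ext)
  px <- raw$px
  depth <- raw$depth
  if (length(px) == 0L || nrow(px) == 0L || ncol(px) == 0L)
    stop("zero-size image: ", path)
  if (!is.null(depth) && depth > 8L) {
    rng <- range(px)
    px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  }
  EnFaceImage(round(px * 255), mmPerPixel = mmPerPixel, eyeId = eyeId,
              axialLengthMm = axialLengthMm)
}

# read a PNG/TIFF into a single-channel 0-1 matrix plus its bit depth
.toGray <- function(path, ext) {
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
  } else {
    raw <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  }
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    px <- if (nc >= 3L) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]
    }
  } else {
    px <- raw
  }
  list(px = matrix(as.numeric(px), nrow(px), ncol(px)), depth = depth[1])
}

#' Write an en face image or binary mask to disk
#'
#' Images are written as 8-bit grayscale; masks serialize with background 0
#' and foreground 255. Format is chosen from the file extension
#' (\code{.png} or \code{.tif}/\code{.tiff}).
#'
#' @param img an \code{\linkS4class{EnFaceImage}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeEnFace <- function(img, path) {
  .writeGray(round(pixels(img)) / 255, path)
}

#' @rdname writeEnFace
#' @param mask a \code{\linkS4class{RegionMask}}.
#' @export
writeMask <- function(mask, path) {
  .writeGray(pixels(mask) * 1.0, path)
}

.writeGray <- function(px, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Read a binary mask image
#'
#' @param path PNG or TIFF path; pixels above 127 (of 255) are foreground.
#' @param mmPerPixel physical scale, mm/px.
#' @param eyeId optional eye identifier.
#' @return a \code{\linkS4class{RegionMask}}.
#' @export
readMask <- function(path, mmPerPixel = 3 / 1024, eyeId = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff"))
    stop("unsupported image format: .", ext)
  g <- .toGray(path, ext)
  RegionMask(g$px > 0.5, mmPerPixel = mmPerPixel, eyeId = eyeId)
}

#' Rasterize a polygon to a binary mask
#'
#' Fills the polygon on a \code{height} x \code{width} raster using the
#' even-odd rule sampled at pixel centers (0-based integer coordinates).
#' A pixel whose center lies exactly on the polygon boundary is foreground.
#' Polygons produced by \code{\link{maskToPolygon}} have vertices at pixel
#' corners (half-integer coordinates), so no center ever falls on an edge
#' and the fill is unambiguous.
#'
#' @param poly an \code{\linkS4class{RoiPolygon}}.
#' @param height,width raster geometry, px.
#' @param mmPerPixel physical scale of the result.
#' @return a \code{\linkS4class{RegionMask}}.
#' @export
polygonToMask <- function(poly, height, width, mmPerPixel = 3 / 1024) {
  v <- vertices(poly)
  if (nrow(unique(v)) < 3L) stop("degenerate polygon: fewer than 3 distinct vertices")
  if (any(v[, 1] < -0.5 | v[, 1] > height - 0.5 |
          v[, 2] < -0.5 | v[, 2] > width - 0.5))
    stop("polygon does not fit within the raster bounds")
  y1 <- v[, 1]; x1 <- v[, 2]
  y2 <- c(v[-1, 1], v[1, 1]); x2 <- c(v[-1, 2], v[1, 2])
  out <- matrix(FALSE, height, width)
  cols <- 0:(width - 1)
  r0 <- max(0L, floor(min(y1)))
  r1 <- min(height - 1L, ceiling(max(y1)))
  if (r1 < r0) return(RegionMask(out, mmPerPixel = mmPerPixel,
                                 eyeId = poly@eyeId))
  for (r in r0:r1) {
    crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    inside <- rep(FALSE, width)
    if (any(crosses)) {
      xc <- x1[crosses] + (r - y1[crosses]) *
        (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
      # parity of crossings strictly left of each pixel center
      nleft <- colSums(outer(xc, cols, "<"))
      inside <- nleft %% 2L == 1L
    }
    # centers exactly on an edge count as foreground
    onseg <- .onEdgeCols(r, cols, y1, x1, y2, x2)
    out[r + 1L, ] <- inside | onseg
  }
  RegionMask(out, mmPerPixel = mmPerPixel, eyeId = poly@eyeId)
}

# which pixel centers (r, cols) lie exactly on a polygon edge
.onEdgeCols <- function(r, cols, y1, x1, y2, x2, eps = 1e-9) {
  hit <- rep(FALSE, length(cols))
  for (k in seq_along(y1)) {
    ay <- y1[k]; ax <- x1[k]; by <- y2[k]; bx <- x2[k]
    if (r < min(ay, by) - eps || r > max(ay, by) + eps) next
    if (abs(by - ay) < eps) {        # horizontal edge at this row
      if (abs(r - ay) < eps) {
        lo <- min(ax, bx) - eps; hi <- max(ax, bx) + eps
        hit <- hit | (cols >= lo & cols <= hi)
      }
    } else {
      xc <- ax + (r - ay) * (bx - ax) / (by - ay)
      hit <- hit | (abs(cols - xc) < eps)
    }
  }
  hit
}

#' Trace a mask boundary to a polygon
#'
#' Traces the outer boundary of a single-component mask along pixel edges
#' ("crack following"): vertices sit at pixel corners, i.e. half-integer
#' coordinates in the pixel-center convention. Rasterizing the result with
#' \code{\link{polygonToMask}} reproduces the component exactly for masks
#' without holes.
#'
#' @param mask a \code{\linkS4class{RegionMask}} with exactly one connected
#'   foreground component (8-connectivity) and no holes.
#' @return an \code{\linkS4class{RoiPolygon}} with collinear runs merged.
#' @export
maskToPolygon <- function(mask) {
  m <- pixels(mask)
  if (!any(m)) stop("empty mask: nothing to trace")
  if (.countComponents(m) > 1L)
    stop("mask has multiple connected components")
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  fg <- which(pad, arr.ind = TRUE)
  r <- fg[, 1] - 2L  # 0-based row of each foreground pixel
  c <- fg[, 2] - 2L
  up    <- !pad[cbind(fg[, 1] - 1L, fg[, 2])]
  down  <- !pad[cbind(fg[, 1] + 1L, fg[, 2])]
  left  <- !pad[cbind(fg[, 1], fg[, 2] - 1L)]
  right <- !pad[cbind(fg[, 1], fg[, 2] + 1L)]
  # directed crack edges in doubled coordinates (corner (r-0.5,c-0.5) is
  # (2r-1, 2c-1)); orientation: interior kept on a consistent side
  es <- rbind(
    if (any(up))    cbind(2 * r[up] - 1,    2 * c[up] - 1,
                          2 * r[up] - 1,    2 * c[up] + 1),
    if (any(right)) cbind(2 * r[right] - 1, 2 * c[right] + 1,
                          2 * r[right] + 1, 2 * c[right] + 1),
    if (any(down))  cbind(2 * r[down] + 1,  2 * c[down] + 1,
                          2 * r[down] + 1,  2 * c[down] - 1),
    if (any(left))  cbind(2 * r[left] + 1,  2 * c[left] - 1,
                          2 * r[left] - 1,  2 * c[left] - 1))
  key <- function(rr, cc) (rr + 3) * (2 * w + 5) + (cc + 3)
  startKeys <- key(es[, 1], es[, 2])
  byStart <- split(seq_len(nrow(es)), startKeys)
  used <- rep(FALSE, nrow(es))
  # begin at the top edge of the first foreground pixel in raster order
  first <- which(up)[which.min(r[up] * (w + 1L) + c[up])]
  cur <- which(es[, 1] == 2 * r[first] - 1 & es[, 2] == 2 * c[first] - 1 &
               es[, 3] == 2 * r[first] - 1 & es[, 4] == 2 * c[first] + 1)[1]
  startV <- es[cur, 1:2]
  path <- list(startV)
  repeat {
    used[cur] <- TRUE
    endV <- es[cur, 3:4]
    if (all(endV == startV)) break
    path[[length(path) + 1L]] <- endV
    cand <- byStart[[as.character(key(endV[1], endV[2]))]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) stop("boundary trace failed (open contour)")
    if (length(cand) > 1L) {
      # at a pinch corner prefer the clockwise (right) turn: keeps the
      # trace hugging the current lobe of a diagonally self-touching blob
      dr <- sign(es[cur, 3] - es[cur, 1]); dc <- sign(es[cur, 4] - es[cur, 2])
      pref <- rbind(c(dc, -dr), c(dr, dc), c(-dc, dr))
      for (p in seq_len(nrow(pref))) {
        pick <- cand[sign(es[cand, 3] - es[cand, 1]) == pref[p, 1] &
                     sign(es[cand, 4] - es[cand, 2]) == pref[p, 2]]
        if (length(pick)) { cand <- pick[1]; break }
      }
    }
    cur <- cand[1]
  }
  vmat <- do.call(rbind, path)
  # merge collinear runs
  n <- nrow(vmat)
  prev <- vmat[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- vmat[c(2:n, 1), , drop = FALSE]
  keep <- !(sign(vmat[, 1] - prev[, 1]) == sign(nxt[, 1] - vmat[, 1]) &
            sign(vmat[, 2] - prev[, 2]) == sign(nxt[, 2] - vmat[, 2]))
  vmat <- vmat[keep, , drop = FALSE]
  RoiPolygon(vmat / 2, eyeId = mask@eyeId)
}

# number of 8-connected foreground components
.countComponents <- function(m) {
  if (!any(m)) return(0L)
  lab <- .label8(m)
  max(lab)
}

# 8-connected labeling: EBImage's 4-connected labeling plus a union-find
# merge of labels that touch diagonally
.label8 <- function(m) {
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal pairs
  pa <- c(a1[a1 > 0 & b1 > 0 & a1 != b1], a2[a2 > 0 & b2 > 0 & a2 != b2])
  pb <- c(b1[a1 > 0 & b1 > 0 & a1 != b1], b2[a2 > 0 & b2 > 0 & a2 != b2])
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (length(pa)) for (i in seq_along(pa)) {
    ra <- find(pa[i]); rb <- find(pb[i])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  remap <- c(0L, match(roots, sort(unique(roots))))
  matrix(remap[lab + 1L], h, w)
}

#' Serialize an ROI polygon to JSON
#'
#' Schema: \code{{"eye_id": str, "vertices": [[row, col], ...]}} with
#' 0-based pixel-center coordinates.
#'
#' @param poly an \code{\linkS4class{RoiPolygon}}.
#' @param path destination \code{.json} path.
#' @return \code{path}, invisibly.
#' @export
writeRoiJson <- function(poly, path) {
  v <- vertices(poly)
  obj <- list(eye_id = if (is.na(poly@eyeId)) NULL else poly@eyeId,
              vertices = lapply(seq_len(nrow(v)),
                                function(i) c(v[i, 1], v[i, 2])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJson
#' @export
readRoiJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vertices
  if (is.list(v)) v <- do.call(rbind, v)
  RoiPolygon(v, eyeId = if (is.null(obj$eye_id)) NA_character_ else obj$eye_id)
}
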