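# Brute-force per-pixel reference implementations, independent of the
# package's vectorized/EBImage-backed code paths. Out-of-frame samples
# clamp to the nearest frame pixel (border-replicate), the convention the
# morphology contract states.

bruteMorph3 <- function(m, op, iterations = 1L) {
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      rs <- pmin(pmax(r + (-1:1), 1L), h)
      cs <- pmin(pmax(c + (-1:1), 1L), w)
      nb <- m[rs, cs]
      out[r, c] <- if (op == "dilate") any(nb) else all(nb)
    }
    m <- out
  }
  m
}

# Euclidean enlargement by exhaustive pairwise distances
bruteEnlarge <- function(m, e) {
  fg <- which(m, arr.ind = TRUE)
  out <- m
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (out[r, c]) next
    d2 <- (fg[, 1] - r)^2 + (fg[, 2] - c)^2
    if (min(d2) <= e^2) out[r, c] <- TRUE
  }
  out
}

# 8-connected component labeling by queue flood fill
bruteLabel8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!m[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0L) {
      r <- queue[1, 1]; c <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

nComponents8 <- function(m) max(bruteLabel8(m))

# hole filling: background components (4-connectivity) that do not touch
# the frame border become foreground
bruteLabel4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!m[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0L) {
      r <- queue[1, 1]; c <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (k in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[k]
        cc <- c + c(0L, 0L, -1L, 1L)[k]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

bruteFillHoles <- function(m) {
  h <- nrow(m); w <- ncol(m)
  bg <- !m
  lab <- bruteLabel4(bg)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0]
  out <- m
  out[bg & !(matrix(lab %in% border, h, w))] <- TRUE
  out
}

# particle selection oracle: size gate (scaled to image area), centroid
# nearest center, ties by larger area then lower label; no hole filling
bruteSelect <- function(m, minPx, maxPx) {
  lab <- bruteLabel8(m)
  k <- max(lab)
  if (k == 0L) return(NULL)
  scale <- (nrow(m) * ncol(m)) / 1024^2
  sizes <- tabulate(lab[lab > 0], nbins = k)
  keep <- which(sizes >= minPx * scale & sizes <= maxPx * scale)
  if (!length(keep)) return(NULL)
  center <- c((nrow(m) - 1) / 2, (ncol(m) - 1) / 2)
  best <- NULL; bestKey <- NULL
  for (l in keep) {
    idx <- which(lab == l, arr.ind = TRUE)
    cen <- colMeans(idx) - 1
    key <- c(sqrt(sum((cen - center)^2)), -nrow(idx), l)
    if (is.null(bestKey) ||
        isTRUE(key[1] < bestKey[1] ||
               (key[1] == bestKey[1] && key[2] < bestKey[2]) ||
               (key[1] == bestKey[1] && key[2] == bestKey[2] &&
                key[3] < bestKey[3]))) {
      bestKey <- key; best <- l
    }
  }
  lab == best
}

# even-odd point-in-polygon per pixel center; boundary centers count inside
brutePointInPoly <- function(r, c, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
    # on-edge test
    if (abs(yj - yi) < eps && abs(r - yi) < eps &&
        c >= min(xi, xj) - eps && c <= max(xi, xj) + eps) return(TRUE)
    if (abs(yj - yi) >= eps && r >= min(yi, yj) - eps &&
        r <= max(yi, yj) + eps) {
      xc <- xi + (r - yi) * (xj - xi) / (yj - yi)
      if (abs(c - xc) < eps) return(TRUE)
    }
    if ((yi <= r && yj > r) || (yj <= r && yi > r)) {
      xc <- xi + (r - yi) * (xj - xi) / (yj - yi)
      if (xc < c) inside <- !inside
    }
    j <- i
  }
  inside
}

brutePolyMask <- function(v, h, w) {
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w))
    out[r, c] <- brutePointInPoly(r - 1, c - 1, v)
  out
}

# random connected blob without holes: union of overlapping random disks,
# largest component kept, holes filled (fixture construction only)
randomBlob <- function(seed, size = 48L, ndisks = 6L, rmin = 4, rmax = 9) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  cx <- size / 2 + cumsum(stats::runif(ndisks, -5, 5))
  cy <- size / 2 + cumsum(stats::runif(ndisks, -5, 5))
  rr <- stats::runif(ndisks, rmin, rmax)
  for (i in seq_len(ndisks)) {
    for (r in seq_len(size)) for (c in seq_len(size)) {
      if ((r - cx[i])^2 + (c - cy[i])^2 <= rr[i]^2) m[r, c] <- TRUE
    }
  }
  lab <- bruteLabel8(m)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  m <- EBImage::fillHull(matrix(as.numeric(m), size, size)) > 0.5
  matrix(m, size, size)
}

randomMask <- function(seed, size = 24L, p = 0.4) {
  set.seed(seed)
  matrix(stats::runif(size * size) < p, size, size)
}

diskMask <- function(size, radius, center = (size + 1) / 2) {
  rc <- seq_len(size) - center
  outer(rc, rc, function(a, b) a^2 + b^2 <= radius^2)
}
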