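.checkPair <- function(a, b) {
  if (!identical(dim(pixels(a)), dim(pixels(b))))
    stop("mask geometry mismatch: ", paste(dim(pixels(a)), collapse = "x"),
         " vs ", paste(dim(pixels(b)), collapse = "x"))
  if (!any(pixels(a)) && !any(pixels(b)))
    stop("both masks are empty: overlap is undefined")
}

#' Jaccard index (intersection over union)
#'
#' \code{|A intersect B| / |A union B|} by pixel counts. Values of 0.9 or
#' more are conventionally graded "excellent" agreement for FAZ masks.
#'
#' @param a,b \code{\linkS4class{RegionMask}}s of identical geometry, not
#'   both empty.
#' @return a number in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
  .checkPair(a, b)
  pa <- pixels(a); pb <- pixels(b)
  sum(pa & pb) / sum(pa | pb)
}

#' Dice similarity coefficient
#'
#' \code{2 |A intersect B| / (|A| + |B|)} by pixel counts; always at least
#' the Jaccard index of the same pair (\code{DSC = 2J/(1+J)}).
#'
#' @inheritParams jaccardIndex
#' @return a number in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  .checkPair(a, b)
  pa <- pixels(a); pb <- pixels(b)
  2 * sum(pa & pb) / (sum(pa) + sum(pb))
}

#' False-negative and false-positive pixel rates
#'
#' Quantifies deficiency and excess of an extraction against a target:
#' \code{FN\% = 100 |target \\ result| / |target union result|} (pixels the
#' extraction missed) and
#' \code{FP\% = 100 |result \\ target| / |target union result|} (pixels it
#' added). With this union normalization
#' \code{FN\% + FP\% = (1 - Jaccard) * 100} exactly.
#'
#' @param target the reference \code{\linkS4class{RegionMask}}.
#' @param result the evaluated \code{\linkS4class{RegionMask}}.
#' @return named numeric vector \code{c(fn_pct, fp_pct)}.
#' @export
fnFpRates <- function(target, result) {
  .checkPair(target, result)
  pt <- pixels(target); pr <- pixels(result)
  u <- sum(pt | pr)
  c(fn_pct = 100 * sum(pt & !pr) / u, fp_pct = 100 * sum(!pt & pr) / u)
}

#' Magnification-corrected FAZ area
#'
#' Pixel count times the squared pixel scale, optionally corrected for
#' ocular magnification by the squared ratio of the measured axial length
#' to a device reference length. The correction factor is returned
#' alongside the area so exact Littmann--Bennett coefficients can be
#' substituted externally if preferred.
#'
#' @param mask a \code{\linkS4class{RegionMask}}.
#' @param axialLengthMm measured axial length (mm), or \code{NA} for no
#'   correction.
#' @param referenceAlMm device reference axial length (mm); default 24.2.
#' @return list with \code{areaMm2} and the applied \code{factor}.
#' @examples
#' m <- RegionMask(matrix(rep(c(TRUE, FALSE), c(31459, 1024^2 - 31459)),
#'                        1024, 1024))
#' correctedArea(m)$areaMm2   # 0.2700 at 3/1024 mm/px
#' @export
correctedArea <- function(mask, axialLengthMm = NA_real_,
                          referenceAlMm = 24.2) {
  if (!is.na(axialLengthMm) && axialLengthMm <= 0)
    stop("'axialLengthMm' must be positive")
  if (referenceAlMm <= 0) stop("'referenceAlMm' must be positive")
  factor <- if (is.na(axialLengthMm)) 1 else (axialLengthMm / referenceAlMm)^2
  list(areaMm2 = sum(pixels(mask)) * mmPerPixel(mask)^2 * factor,
       factor = factor)
}

#' Between-method coefficient of variation for one subject
#'
#' 100 times the sample standard deviation over the mean of the areas a
#' subject's eye received from the different methods.
#'
#' @param areas numeric vector of at least two per-method areas with a
#'   positive mean.
#' @return CV in percent.
#' @export
cvBetween <- function(areas) {
  if (length(areas) < 2L) stop("need at least two areas")
  m <- mean(areas)
  if (m <= 0) stop("mean area must be positive")
  100 * stats::sd(areas) / m
}

#' Nonparametric method-comparison battery on a value matrix
#'
#' The rank-statistic battery applied to one metric measured for every
#' block (eye) under every condition (method or method pair): Shapiro--Wilk
#' normality per condition (narrative gating only), a Friedman test across
#' conditions, and pairwise paired Wilcoxon signed-rank post-hoc tests with
#' Bonferroni adjustment (\code{p_adj = min(1, p * m)}).
#'
#' @param values numeric matrix, rows = blocks (eyes), columns =
#'   conditions; complete cases required.
#' @return list with \code{shapiro} (per-condition p), \code{friedman}
#'   (\code{htest}), and \code{posthoc} (data frame of pairwise raw and
#'   Bonferroni-adjusted p-values).
#' @export
methodComparisonTests <- function(values) {
  values <- as.matrix(values)
  if (any(!stats::complete.cases(values)))
    stop("incomplete blocks: every block needs a value for every condition")
  if (nrow(values) < 3L) stop("need at least 3 blocks")
  if (ncol(values) < 2L) stop("need at least 2 conditions")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  shap <- vapply(seq_len(ncol(values)), function(j) {
    x <- values[, j]
    if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  names(shap) <- colnames(values)
  fr <- if (stats::sd(as.vector(values)) == 0 ||
            all(apply(values, 1, stats::sd) == 0)) {
    list(statistic = c(`Friedman chi-squared` = 0), p.value = 1,
         method = "Friedman rank sum test (degenerate: constant blocks)")
  } else {
    stats::friedman.test(values)
  }
  combs <- utils::combn(ncol(values), 2)
  m <- ncol(combs)
  post <- data.frame(
    a = colnames(values)[combs[1, ]],
    b = colnames(values)[combs[2, ]],
    p_raw = vapply(seq_len(m), function(i) {
      x <- values[, combs[1, i]]; y <- values[, combs[2, i]]
      if (all(x == y)) return(1)
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    }, numeric(1)))
  post$p_adj <- pmin(1, post$p_raw * m)
  list(shapiro = shap, friedman = fr, posthoc = post)
}

#' Compare FAZ extraction methods across a cohort
#'
#' Builds the full agreement evaluation for three or more extraction
#' methods applied to the same eyes: per-pair Jaccard, Dice, FN\%/FP\% and
#' per-eye between-method CV; per-method (optionally magnification
#' corrected) areas with a Friedman test and Bonferroni post-hocs; per-pair
#' CV and similarity summaries with 95\% confidence intervals and Friedman
#' tests across pairs; Spearman rank correlation of areas per pair; and a
#' paired Wilcoxon test of FN against FP per pair. Masks of unequal
#' geometry are reconciled by nearest-neighbour resampling of the larger
#' mask onto the smaller grid before comparison.
#'
#' @param masks named list (one element per method, >= 3) of named lists of
#'   \code{\linkS4class{RegionMask}}s (one per eye); every method must
#'   cover the same eyes.
#' @param axialLengthsMm optional named vector of per-eye axial lengths for
#'   magnification correction.
#' @param referenceAlMm device reference axial length, mm.
#' @return a \code{\linkS4class{ComparisonReport}}.
#' @export
compareMethods <- function(masks, axialLengthsMm = NULL,
                           referenceAlMm = 24.2) {
  if (length(masks) < 3L) stop("need at least 3 methods")
  methods <- names(masks)
  if (is.null(methods) || any(methods == ""))
    stop("'masks' must be a named list of methods")
  eyes <- names(masks[[1]])
  if (is.null(eyes)) stop("each method needs a named list of eyes")
  for (m in methods)
    if (!identical(sort(names(masks[[m]])), sort(eyes)))
      stop("incomplete blocks: method '", m, "' does not cover every eye")
  if (length(eyes) < 3L) stop("need at least 3 eyes")

  areaOf <- function(m, e) {
    al <- if (!is.null(axialLengthsMm)) unname(axialLengthsMm[e])
          else NA_real_
    if (is.null(al) || length(al) != 1L) al <- NA_real_
    correctedArea(masks[[m]][[e]], al, referenceAlMm)$areaMm2
  }
  areas <- matrix(NA_real_, length(eyes), length(methods),
                  dimnames = list(eyes, methods))
  for (m in methods) for (e in eyes) areas[e, m] <- areaOf(m, e)

  pairs <- utils::combn(methods, 2)
  rec <- list()
  for (i in seq_len(ncol(pairs))) {
    ma <- pairs[1, i]; mb <- pairs[2, i]
    for (e in eyes) {
      ab <- .reconcile(masks[[ma]][[e]], masks[[mb]][[e]])
      j <- jaccardIndex(ab[[1]], ab[[2]])
      ff <- fnFpRates(ab[[1]], ab[[2]])
      rec[[length(rec) + 1L]] <- data.frame(
        eye_id = e, method_a = ma, method_b = mb,
        area_a_mm2 = areas[e, ma], area_b_mm2 = areas[e, mb],
        jaccard = j, dsc = diceCoefficient(ab[[1]], ab[[2]]),
        fn_pct = unname(ff["fn_pct"]), fp_pct = unname(ff["fp_pct"]),
        cv_pct = cvBetween(c(areas[e, ma], areas[e, mb])))
    }
  }
  records <- do.call(rbind, rec)

  areaTests <- methodComparisonTests(areas)
  areaTable <- data.frame(
    method = methods,
    mean_mm2 = colMeans(areas),
    sd_mm2 = apply(areas, 2, stats::sd))
  areaTable$friedman_p <- areaTests$friedman$p.value

  pairName <- paste(records$method_a, "vs", records$method_b)
  byPair <- function(v) matrix(v, nrow = length(eyes),
                               dimnames = list(eyes, unique(pairName)))
  cvMat <- byPair(records$cv_pct)
  jMat <- byPair(records$jaccard)
  dMat <- byPair(records$dsc)

  ci <- function(x) {
    se <- stats::sd(x) / sqrt(length(x))
    mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) * se
  }
  pairLabels <- unique(pairName)
  rho <- p_rho <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    ct <- suppressWarnings(
      stats::cor.test(areas[, pairs[1, i]], areas[, pairs[2, i]],
                      method = "spearman"))
    rho[i] <- unname(ct$estimate); p_rho[i] <- ct$p.value
  }
  cvTests <- methodComparisonTests(cvMat)
  cvTable <- data.frame(
    pair = pairLabels,
    cv_mean_pct = colMeans(cvMat),
    cv_lo = apply(cvMat, 2, function(x) ci(x)[1]),
    cv_hi = apply(cvMat, 2, function(x) ci(x)[2]),
    rho = rho, rho_p = p_rho)
  cvTable$friedman_p <- cvTests$friedman$p.value

  jTests <- methodComparisonTests(jMat)
  dTests <- methodComparisonTests(dMat)
  similarityTable <- data.frame(
    pair = pairLabels,
    jaccard_mean = colMeans(jMat),
    jaccard_lo = apply(jMat, 2, function(x) ci(x)[1]),
    jaccard_hi = apply(jMat, 2, function(x) ci(x)[2]),
    dsc_mean = colMeans(dMat),
    dsc_lo = apply(dMat, 2, function(x) ci(x)[1]),
    dsc_hi = apply(dMat, 2, function(x) ci(x)[2]))
  similarityTable$jaccard_friedman_p <- jTests$friedman$p.value
  similarityTable$dsc_friedman_p <- dTests$friedman$p.value

  fnfp_p <- vapply(pairLabels, function(pl) {
    r <- records[pairName == pl, ]
    if (all(r$fn_pct == r$fp_pct)) return(1)
    suppressWarnings(
      stats::wilcox.test(r$fn_pct, r$fp_pct, paired = TRUE)$p.value)
  }, numeric(1))
  fnFpTable <- data.frame(
    pair = pairLabels,
    fn_mean_pct = colMeans(byPair(records$fn_pct)),
    fp_mean_pct = colMeans(byPair(records$fp_pct)),
    wilcoxon_p = unname(fnfp_p))

  new("ComparisonReport", records = records, areaTable = areaTable,
      cvTable = cvTable, similarityTable = similarityTable,
      fnFpTable = fnFpTable,
      tests = list(area = areaTests, cv = cvTests, jaccard = jTests,
                   dsc = dTests))
}

# nearest-neighbour resample the larger mask onto the smaller grid
.reconcile <- function(a, b) {
  da <- dim(pixels(a)); db <- dim(pixels(b))
  if (identical(da, db)) return(list(a, b))
  if (prod(da) > prod(db)) list(.resampleMask(a, db[1], db[2]), b)
  else list(a, .resampleMask(b, da[1], da[2]))
}

.resampleMask <- function(mask, h, w) {
  m <- pixels(mask)
  ri <- pmin(nrow(m), floor((seq_len(h) - 0.5) * nrow(m) / h) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(w) - 0.5) * ncol(m) / w) + 1L)
  RegionMask(m[ri, ci, drop = FALSE],
             mmPerPixel = mmPerPixel(mask) * nrow(m) / h,
             eyeId = mask@eyeId)
}
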