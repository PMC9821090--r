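maskFromCounts <- function(nA, nB, nAB, size = 24L) {
  # A occupies the first nA cells, B the last nB such that |A&B| = nAB
  a <- b <- rep(FALSE, size * size)
  a[seq_len(nA)] <- TRUE
  b[(nA - nAB + 1):(nA - nAB + nB)] <- TRUE
  list(RegionMask(matrix(a, size, size)), RegionMask(matrix(b, size, size)))
}

test_that("Jaccard, Dice and FN/FP follow the set-count arithmetic", {
  ab <- maskFromCounts(100, 80, 60)
  expect_equal(jaccardIndex(ab[[1]], ab[[2]]), 0.5)
  expect_equal(diceCoefficient(ab[[1]], ab[[2]]), 120 / 180)
  ff <- fnFpRates(ab[[1]], ab[[2]])
  expect_equal(unname(ff["fn_pct"]), 100 * 40 / 120)
  expect_equal(unname(ff["fp_pct"]), 100 * 20 / 120)

  same <- RegionMask(randomBlob(1))
  expect_equal(jaccardIndex(same, same), 1.0)
  expect_equal(diceCoefficient(same, same), 1.0)

  disjoint <- maskFromCounts(50, 40, 0)
  expect_equal(jaccardIndex(disjoint[[1]], disjoint[[2]]), 0.0)

  sub <- maskFromCounts(100, 60, 60)     # result strictly inside target
  ff <- fnFpRates(sub[[1]], sub[[2]])
  expect_equal(unname(ff["fp_pct"]), 0)
  expect_gt(unname(ff["fn_pct"]), 0)
})

test_that("similarity metrics are symmetric; FN/FP swap on reversal", {
  a <- RegionMask(randomMask(31, 20))
  b <- RegionMask(randomMask(32, 20))
  expect_equal(jaccardIndex(a, b), jaccardIndex(b, a))
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_equal(unname(fnFpRates(a, b)["fn_pct"]),
               unname(fnFpRates(b, a)["fp_pct"]))
})

test_that("geometry mismatches and empty unions are rejected", {
  a <- RegionMask(matrix(TRUE, 8, 8))
  b <- RegionMask(matrix(TRUE, 9, 9))
  expect_error(jaccardIndex(a, b), "mismatch")
  e <- RegionMask(matrix(FALSE, 8, 8))
  expect_error(jaccardIndex(e, e), "empty")
})

test_that("area arithmetic and magnification correction are exact", {
  m <- RegionMask(matrix(seq_len(1024^2) <= 31459, 1024, 1024),
                  mmPerPixel = 3 / 1024)
  expect_equal(signif(correctedArea(m)$areaMm2, 4), 0.27)
  expect_equal(correctedArea(m, axialLengthMm = 24.2)$factor, 1)
  expect_equal(correctedArea(m, axialLengthMm = 24.2)$areaMm2,
               correctedArea(m)$areaMm2)
  ca <- correctedArea(m, axialLengthMm = 26.0)
  expect_equal(ca$factor, (26 / 24.2)^2)
  expect_equal(ca$areaMm2, correctedArea(m)$areaMm2 * (26 / 24.2)^2)
  expect_error(correctedArea(m, axialLengthMm = -1), "positive")
})

test_that("area is invariant under the amplification isometries", {
  truth <- truthMask(renderScene(syntheticSpec(size = 256, seed = 9)))
  img <- EnFaceImage(matrix(0, 256, 256), mmPerPixel = mmPerPixel(truth))
  base <- correctedArea(truth)$areaMm2
  amp <- amplifyDataset(list(datasetPair(img, truth)),
                        c("fliph", "flipv", "rot90", "rot180", "rot270"))
  for (p in amp[-1])
    expect_equal(correctedArea(p$label)$areaMm2, base, info = p$transform)
})

test_that("between-method CV follows the two-point SD formula", {
  expect_equal(cvBetween(c(0.271, 0.265)),
               100 * (0.006 / sqrt(2)) / 0.268, tolerance = 1e-9)
  expect_equal(round(cvBetween(c(0.271, 0.265)), 3), 1.583)
  expect_equal(cvBetween(c(0.25, 0.25, 0.25)), 0)
  expect_equal(cvBetween(c(0.2, 0.3)), 100 * 0.0707107 / 0.25,
               tolerance = 1e-4)
  expect_error(cvBetween(0.3), "two")
  expect_error(cvBetween(c(0, 0)), "positive")
})

test_that("the rank-test battery behaves on degenerate and known input", {
  x <- matrix(rep(c(0.2, 0.25, 0.3), each = 10), 10, 3)
  same <- methodComparisonTests(cbind(a = x[, 1], b = x[, 1], c = x[, 1]))
  expect_equal(unname(same$friedman$statistic), 0)
  expect_equal(same$friedman$p.value, 1)
  expect_true(all(same$posthoc$p_adj == 1))

  set.seed(7)
  y <- cbind(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  out <- methodComparisonTests(y)
  expect_equal(out$posthoc$p_adj, pmin(1, out$posthoc$p_raw * 3))
  expect_true(all(out$posthoc$p_adj >= out$posthoc$p_raw))
  expect_length(out$shapiro, 3L)

  y[3, 2] <- NA
  expect_error(methodComparisonTests(y), "incomplete")
  expect_error(methodComparisonTests(y[1:2, ]), "3 blocks")
})

test_that("compareMethods reproduces the per-record metric identities", {
  masks <- list()
  for (meth in c("ksm", "manual1", "manual2")) {
    masks[[meth]] <- list()
    for (e in 1:5) {
      m <- randomBlob(e * 10 + match(meth, c("ksm", "manual1", "manual2")),
                      size = 64L, ndisks = 4L, rmin = 6, rmax = 12)
      masks[[meth]][[paste0("eye", e)]] <- RegionMask(m, mmPerPixel = 3 / 64)
    }
  }
  rep <- compareMethods(masks)
  rec <- evalRecords(rep)
  expect_equal(nrow(rec), 3 * 5)
  expect_equal(rec$dsc, 2 * rec$jaccard / (1 + rec$jaccard), tolerance = 1e-12)
  expect_equal(rec$fn_pct + rec$fp_pct, (1 - rec$jaccard) * 100,
               tolerance = 1e-9)
  expect_true(all(rec$jaccard <= rec$dsc))
  expect_equal(nrow(rep@similarityTable), 3L)
  expect_equal(nrow(rep@areaTable), 3L)
  # summaries recompute from the record table
  pair1 <- rec$method_a == "ksm" & rec$method_b == "manual1"
  expect_equal(rep@similarityTable$jaccard_mean[1], mean(rec$jaccard[pair1]))
  expect_equal(rep@fnFpTable$fn_mean_pct[1], mean(rec$fn_pct[pair1]))
})

test_that("identical methods give unit similarity and null tests", {
  one <- lapply(1:4, function(e)
    RegionMask(randomBlob(e, size = 48L), mmPerPixel = 3 / 48))
  names(one) <- paste0("eye", 1:4)
  masks <- list(a = one, b = one, c = one)
  rep <- compareMethods(masks)
  expect_true(all(evalRecords(rep)$jaccard == 1))
  expect_equal(rep@areaTable$friedman_p[1], 1)
  expect_true(all(rep@fnFpTable$wilcoxon_p == 1))
})

test_that("masks of different grids are reconciled to the smaller one", {
  big <- truthMask(renderScene(syntheticSpec(size = 512, seed = 11)))
  small <- truthMask(renderScene(syntheticSpec(size = 256, seed = 11)))
  j <- jaccardIndex(fazkit:::.reconcile(big, small)[[1]],
                    fazkit:::.reconcile(big, small)[[2]])
  expect_gt(j, 0.9)
  masks <- list(
    a = list(e1 = big, e2 = big, e3 = big),
    b = list(e1 = small, e2 = small, e3 = small),
    c = list(e1 = small, e2 = big, e3 = small))
  rep <- compareMethods(masks)
  expect_true(all(evalRecords(rep)$jaccard > 0.9))
})

test_that("incomplete method/eye blocks are rejected", {
  one <- lapply(1:3, function(e) RegionMask(randomBlob(e, size = 32L)))
  names(one) <- paste0("eye", 1:3)
  two <- one[1:2]
  expect_error(compareMethods(list(a = one, b = two, c = one)),
               "incomplete")
  expect_error(compareMethods(list(a = one, b = one)), "3 methods")
})
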