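plantedMatrix <- function(nLow, nHigh, nCol, muLow = 0.1, muHigh = 0.7,
                          sd = 0.02, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(pmin(pmax(rnorm(nLow * nCol, muLow, sd), 0), 1), nLow),
             matrix(pmin(pmax(rnorm(nHigh * nCol, muHigh, sd), 0), 1), nHigh))
  rownames(m) <- sprintf("S%03d", seq_len(nLow + nHigh))
  colnames(m) <- if (nCol == 8) promoterMarkers() else repeatMarkers()
  m
}

test_that("planted two-component cohorts are recovered perfectly", {
  m <- plantedMatrix(30, 30, 8)
  res <- callTsgHypermethylation(m)
  expect_equal(unname(res$calls), rep(c(FALSE, TRUE), each = 30))
  r <- plantedMatrix(25, 35, 3, seed = 2)
  hypo <- callGlobalHypomethylationCluster(r)
  # the LOW-methylation cluster is the hypomethylated (positive) one
  expect_equal(unname(hypo$calls), rep(c(TRUE, FALSE), c(25, 35)))
})

test_that("a two-sample cohort yields exactly one positive call", {
  m <- matrix(c(rep(0.1, 8), rep(0.9, 8)), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), promoterMarkers()))
  expect_equal(sum(callTsgHypermethylation(m)$calls), 1)
  r <- matrix(c(rep(0.1, 3), rep(0.9, 3)), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), repeatMarkers()))
  expect_equal(sum(callGlobalHypomethylationCluster(r)$calls), 1)
})

test_that("degenerate all-equal input errors and calls are order-invariant", {
  flat <- matrix(0.4, 6, 3, dimnames = list(letters[1:6], repeatMarkers()))
  expect_error(callGlobalHypomethylationCluster(flat), "degenerate")
  m <- plantedMatrix(10, 10, 8, seed = 3)
  base <- callTsgHypermethylation(m)$calls
  perm <- sample(nrow(m))
  shuf <- callTsgHypermethylation(m[perm, ])$calls
  expect_equal(shuf[names(base)], base)
})

test_that("missing promoter values are mean-imputed with a message", {
  m <- plantedMatrix(10, 10, 8, seed = 4)
  m[3, "APC"] <- NA
  expect_message(res <- callTsgHypermethylation(m), "imputing")
  expect_equal(unname(res$calls), rep(c(FALSE, TRUE), each = 10))
})

test_that("zscoreSum matches direct arithmetic and is strictly monotone", {
  calib <- ZScoreCalibration(0.36, 0.25, -0.01217)
  expect_equal(zscoreSum(c(0.36, 0.36, 0.36), calib), 0)
  expect_equal(zscoreSum(c(0.11, 0.36, 0.36), calib), -1)
  set.seed(5)
  for (i in 1:20) {
    v <- runif(3)
    oracle <- (v[1] - 0.36) / 0.25 + (v[2] - 0.36) / 0.25 + (v[3] - 0.36) / 0.25
    expect_equal(zscoreSum(v, calib), oracle, tolerance = 1e-12)
    bump <- v; bump[sample(3, 1)] <- bump[sample(3, 1)] + 0.01
  }
  # monotone: raising any one marker raises the sum
  v <- c(0.3, 0.4, 0.5)
  for (j in 1:3) {
    v2 <- v; v2[j] <- v2[j] + 1e-6
    expect_gt(zscoreSum(v2, calib), zscoreSum(v, calib))
  }
})

test_that("the Z-score hypomethylation call is strictly below-threshold", {
  calib <- ZScoreCalibration(0.36, 0.25, -0.01217)
  low <- c(0.36, 0.36, 0.36 - 0.25 * 0.02)  # sum = -0.02
  expect_equal(zscoreSum(low, calib), -0.02)
  expect_true(callGlobalHypomethylationZscore(low, calib))
  expect_false(callGlobalHypomethylationZscore(c(0.36, 0.36, 0.36), calib))
  # boundary: sum exactly at the threshold is NOT hypomethylated
  calib0 <- ZScoreCalibration(0.5, 0.25, 0)
  expect_false(callGlobalHypomethylationZscore(c(0.5, 0.5, 0.5), calib0))
  # lower methylation can never flip positive -> negative
  m <- plantedMatrix(20, 20, 3, seed = 6)
  calls <- vapply(seq_len(nrow(m)), function(i)
    callGlobalHypomethylationZscore(m[i, ], calib), logical(1))
  lower <- pmax(m - 0.05, 0)
  calls2 <- vapply(seq_len(nrow(m)), function(i)
    callGlobalHypomethylationZscore(lower[i, ], calib), logical(1))
  expect_true(all(calls2[calls]))
})

test_that("calibration pools all three markers and separates planted labels", {
  # constant training values -> sd = 0 -> error
  flat <- matrix(0.4, 6, 3)
  expect_error(fitZscoreCalibration(flat, rep(c(TRUE, FALSE), 3)),
               "not positive")
  expect_error(fitZscoreCalibration(plantedMatrix(4, 4, 3), rep(TRUE, 8)),
               "constant labels")
  m <- plantedMatrix(15, 15, 3, muLow = 0.1, muHigh = 0.7, seed = 7)
  labels <- rep(c(TRUE, FALSE), each = 15)  # low = hypomethylated
  calib <- fitZscoreCalibration(m, labels)
  expect_equal(calib@mean, mean(m))          # pooled, not per-marker
  expect_equal(calib@sd, sd(as.numeric(m)))
  sums <- apply(m, 1, zscoreSum, calib = calib)
  expect_gt(threshold(calib), max(sums[labels]))
  expect_lt(threshold(calib), min(sums[!labels]))
  pred <- sums < threshold(calib)
  expect_equal(pred, setNames(labels, rownames(m)))
})

test_that("Z-score calibration reproduces cluster labels on a simulated cohort", {
  gen <- generateCohort(generatorConfig(n = 125, seed = 1))
  rm <- repeatMeth(gen$cohort)
  labels <- callGlobalHypomethylationCluster(rm)$calls
  calib <- fitZscoreCalibration(rm, labels)
  pred <- vapply(seq_len(nrow(rm)), function(i)
    callGlobalHypomethylationZscore(rm[i, ], calib), logical(1))
  expect_gte(mean(pred == labels), 0.95)
})
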