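randomFeatures <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             ctnnb1_mut = runif(n) < 0.25, tp53_mut = runif(n) < 0.22,
             tertp_mut = runif(n) < 0.68, tsg_hyper = runif(n) < 0.65,
             global_hypo = runif(n) < 0.54, fal_high = runif(n) < 0.54)
}

test_that("disjunctive coding gives 12 columns with row sums of 6", {
  f <- randomFeatures(10)
  ind <- buildIndicatorMatrix(f)
  expect_equal(dim(ind), c(10, 12))
  expect_true(all(rowSums(ind) == 6))
  allFalse <- f[1, ]; allFalse[, 2:7] <- FALSE
  row <- buildIndicatorMatrix(allFalse)
  expect_equal(sum(row[1, grepl("absent", colnames(row))]), 6)
  expect_equal(sum(row[1, grepl("present", colnames(row))]), 0)
  # 4-sample toy set against a hand-built table
  toy <- data.frame(sample_id = c("a", "b", "c", "d"),
                    ctnnb1_mut = c(TRUE, FALSE, FALSE, TRUE),
                    tp53_mut = c(FALSE, TRUE, FALSE, FALSE),
                    tertp_mut = c(TRUE, TRUE, FALSE, FALSE),
                    tsg_hyper = c(TRUE, FALSE, TRUE, TRUE),
                    global_hypo = c(FALSE, FALSE, FALSE, TRUE),
                    fal_high = c(FALSE, TRUE, FALSE, TRUE))
  hand <- matrix(c(
    1,0, 0,1, 1,0, 1,0, 0,1, 0,1,
    0,1, 1,0, 1,0, 0,1, 0,1, 1,0,
    0,1, 0,1, 0,1, 1,0, 0,1, 0,1,
    1,0, 0,1, 0,1, 1,0, 1,0, 1,0), 4, 12, byrow = TRUE)
  expect_equal(unname(buildIndicatorMatrix(toy)), hand)
  toy$tp53_mut[2] <- NA
  expect_error(buildIndicatorMatrix(toy), "sample b")
})

test_that("correspondence analysis satisfies centering and inertia identities", {
  f <- randomFeatures(20, seed = 3)
  ind <- buildIndicatorMatrix(f)
  map <- correspondenceAnalysis(ind)
  r <- rowSums(ind) / sum(ind)
  expect_lt(max(abs(colSums(rowCoords(map) * r))), 1e-9)  # mass-weighted mean 0
  E <- outer(rowSums(ind), colSums(ind)) / sum(ind)
  chisq <- sum((ind - E)^2 / E)
  expect_equal(totalInertia(map), chisq / sum(ind), tolerance = 1e-9)
  expect_equal(sum(singularValues(map)^2), totalInertia(map), tolerance = 1e-12)
})

test_that("row coordinates match the independent SVD oracle up to axis sign", {
  for (seed in 1:5) {
    ind <- buildIndicatorMatrix(randomFeatures(20, seed = seed))
    map <- correspondenceAnalysis(ind)
    or <- MASS::corresp(ind, nf = 2)
    oracle <- or$rscore %*% diag(or$cor[1:2])
    for (k in 1:2) {
      d <- min(max(abs(rowCoords(map)[, k] - oracle[, k])),
               max(abs(rowCoords(map)[, k] + oracle[, k])))
      expect_lt(d, 1e-8)
    }
  }
})

test_that("CA coordinates are stable under row permutation and table duplication", {
  f <- randomFeatures(15, seed = 4)
  ind <- buildIndicatorMatrix(f)
  map <- correspondenceAnalysis(ind)
  perm <- sample(nrow(ind))
  mapP <- correspondenceAnalysis(ind[perm, ])
  expect_equal(rowCoords(mapP)[rownames(ind), ], rowCoords(map),
               tolerance = 1e-9)
  dup <- rbind(ind, ind)
  rownames(dup) <- make.unique(rownames(dup))
  mapD <- correspondenceAnalysis(dup)
  expect_equal(unname(rowCoords(mapD)[seq_len(nrow(ind)), ]),
               unname(rowCoords(map)), tolerance = 1e-9)
  # identical feature vectors map to identical coordinates
  two <- buildIndicatorMatrix(rbind(f[1, ], transform(f[1, ], sample_id = "dup")))
  m2 <- suppressMessages(correspondenceAnalysis(rbind(two, ind[2:8, ])))
  expect_equal(unname(rowCoords(m2)[1, ]), unname(rowCoords(m2)[2, ]))
})

test_that("constant columns are dropped and rank deficiency is an error", {
  f <- randomFeatures(12, seed = 5)
  f$tertp_mut <- TRUE
  expect_message(map <- correspondenceAnalysis(buildIndicatorMatrix(f)),
                 "constant")
  expect_false(any(grepl("tertp", rownames(colCoords(map)))))
  one <- data.frame(sample_id = c("a", "b"),
                    ctnnb1_mut = c(TRUE, FALSE), tp53_mut = c(TRUE, FALSE),
                    tertp_mut = c(TRUE, FALSE), tsg_hyper = c(TRUE, FALSE),
                    global_hypo = c(TRUE, FALSE), fal_high = c(TRUE, FALSE))
  expect_error(correspondenceAnalysis(buildIndicatorMatrix(one)),
               "cannot embed")
})

test_that("planted 4-cloud maps are clustered perfectly and deterministically", {
  set.seed(9)
  centers <- matrix(c(-5, -5, -5, 5, 5, -5, 5, 5), 4, 2, byrow = TRUE)
  xy <- centers[rep(1:4, each = 25), ] + matrix(rnorm(200, sd = 0.1), 100, 2)
  rownames(xy) <- sprintf("S%03d", 1:100)
  map <- new("CorrespondenceMap", rowCoords = xy,
             colCoords = matrix(0, 2, 2, dimnames = list(c("x", "y"), NULL)),
             singularValues = c(1, 1), totalInertia = 2)
  cl <- clusterSubclasses(map, k = 4)
  expect_equal(length(unique(cl)), 4)
  truth <- rep(1:4, each = 25)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)
  # input order invariance
  perm <- sample(100)
  map2 <- new("CorrespondenceMap", rowCoords = xy[perm, ],
              colCoords = map@colCoords, singularValues = c(1, 1),
              totalInertia = 2)
  cl2 <- clusterSubclasses(map2, k = 4)
  expect_equal(cl2[names(cl)], cl)
  # k = 1 puts everyone together
  expect_true(all(clusterSubclasses(map, k = 1) == 1))
  degen <- map; degen@rowCoords <- xy[rep(1, 100), ]
  rownames(degen@rowCoords) <- rownames(xy)
  expect_error(clusterSubclasses(degen, k = 4), "distinct")
})

test_that("subclass labels follow the hypermethylation/FAL prevalence rule", {
  # published profile: hyper (0.22, 0.10, 0.95, 0.94), FAL (0.70, 0.14, 0.90, 0.22)
  f <- featuresWithPrevalence(sizes = c(100, 100, 100, 100),
                              hyperCounts = c(22, 10, 95, 94),
                              falCounts = c(70, 14, 90, 22))
  clusters <- setNames(rep(1:4, each = 100), f$sample_id)
  lab <- labelSubclasses(clusters, f)
  byCluster <- tapply(as.character(lab$subclass), clusters, unique)
  expect_equal(as.vector(byCluster), c("A1", "A2", "B1", "B2"))
  # swapping cluster ids leaves sample labels unchanged
  swapped <- setNames(c(3L, 4L, 1L, 2L)[clusters], names(clusters))
  lab2 <- labelSubclasses(swapped, f)
  expect_equal(lab2$subclass, lab$subclass)
})

test_that("a non-2+2 hypermethylation split falls back to ranking with a warning", {
  f <- featuresWithPrevalence(sizes = rep(50, 4),
                              hyperCounts = c(40, 35, 30, 5),
                              falCounts = c(45, 5, 40, 5))
  clusters <- setNames(rep(1:4, each = 50), f$sample_id)
  expect_warning(lab <- labelSubclasses(clusters, f), "2\\+2")
  byCluster <- tapply(as.character(lab$subclass), clusters, unique)
  expect_equal(sort(as.vector(byCluster)), c("A1", "A2", "B1", "B2"))
  expect_equal(as.vector(byCluster[1]), "B1")  # highest hyper, highest FAL
})

test_that("subclassify is deterministic end to end", {
  f <- randomFeatures(60, seed = 6)
  s1 <- suppressWarnings(subclassify(f))
  s2 <- suppressWarnings(subclassify(f))
  expect_identical(s1$subclass, s2$subclass)
  expect_identical(s1$axis1, s2$axis1)
  expect_equal(nlevels(droplevels(s1$subclass)), 4)
})
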