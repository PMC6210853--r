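.clusterCall <- function(mat, positive = c("high", "low")) {
  positive <- match.arg(positive)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  if (nrow(mat) < 2) stop("need at least 2 samples to cluster")
  # mean-impute missing values per marker
  if (anyNA(mat)) {
    for (j in seq_len(ncol(mat))) {
      na <- is.na(mat[, j])
      if (any(na)) {
        message(sprintf("mean-imputing %d missing value(s) for marker %s",
                        sum(na), colnames(mat)[j]))
        mat[na, j] <- mean(mat[!na, j])
      }
    }
  }
  # deterministic under sample permutation: cluster on id-sorted rows
  ord <- order(rownames(mat))
  m <- mat[ord, , drop = FALSE]
  if (all(apply(m, 2, function(x) diff(range(x)) == 0)))
    stop("degenerate clustering input: all samples identical")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  means <- tapply(rowMeans(m), grp, mean)
  if (means[["1"]] == means[["2"]]) {
    # equal grand means: larger cluster is the negative call
    posGrp <- names(which.min(table(grp)))[1]
  } else if (positive == "high") {
    posGrp <- names(which.max(means))
  } else {
    posGrp <- names(which.min(means))
  }
  calls <- stats::setNames(grp == as.integer(posGrp), rownames(m))
  list(calls = calls[rownames(mat)], tree = hc,
       clusterMeans = stats::setNames(as.numeric(means), names(means)),
       positiveCluster = as.integer(posGrp))
}

#' Call TSG-promoter hypermethylation by hierarchical clustering
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance) of the
#' 8-dimensional promoter methylation vectors, tree cut at k = 2; the cluster
#' with the higher grand-mean methylation is labeled hypermethylated.
#' Missing values are mean-imputed per marker (with a message). The result is
#' invariant to sample order: rows are sorted by sample id before distances
#' are computed, and equal-mean clusters are broken by size (the larger
#' cluster is the negative call).
#'
#' @param promoterMat samples x 8 matrix of promoter methylation fractions
#'   (rownames = sample ids), e.g. \code{promoterMeth(cohort)}.
#' @return list with \code{calls} (named logical, input order), \code{tree}
#'   (the \code{hclust} object), \code{clusterMeans} and
#'   \code{positiveCluster}.
#' @export
callTsgHypermethylation <- function(promoterMat) {
  .clusterCall(promoterMat, positive = "high")
}

#' Call global hypomethylation by hierarchical clustering
#'
#' As \code{\link{callTsgHypermethylation}} but on the three repetitive
#' elements (Alu, LINE-1, SAT2), with the \emph{lower}-mean cluster labeled
#' as carrying significant global hypomethylation.
#'
#' @param repeatMat samples x 3 matrix of repetitive-element methylation
#'   fractions.
#' @return as \code{\link{callTsgHypermethylation}}.
#' @export
callGlobalHypomethylationCluster <- function(repeatMat) {
  .clusterCall(repeatMat, positive = "low")
}

#' Calibrate the Z-score rule for global hypomethylation
#'
#' Computes one pooled mean and standard deviation over \emph{all} training
#' values of Alu, LINE-1 and SAT2 (a single pair, as the 0.36 / 0.25 reference
#' calibration implies), then selects the threshold on the per-sample sum of
#' the three Z-scores that best discriminates the cluster-derived
#' hypomethylation labels (Youden's J via \code{\link{rocBestThreshold}},
#' hypomethylated = sum \emph{below} threshold).
#'
#' @param repeatMat samples x 3 training matrix of repeat methylation
#'   fractions.
#' @param labels logical training labels from
#'   \code{\link{callGlobalHypomethylationCluster}}.
#' @return a \linkS4class{ZScoreCalibration}.
#' @export
fitZscoreCalibration <- function(repeatMat, labels) {
  repeatMat <- as.matrix(repeatMat)
  stopifnot(nrow(repeatMat) == length(labels))
  if (length(unique(labels)) < 2)
    stop("constant labels: ROC threshold undefined")
  v <- as.numeric(repeatMat)
  mu <- mean(v)
  sg <- stats::sd(v)
  if (!is.finite(sg) || sg <= 0)
    stop("pooled standard deviation is not positive")
  sums <- rowSums((repeatMat - mu) / sg)
  thr <- rocBestThreshold(sums, labels, positiveIsLow = TRUE)
  ZScoreCalibration(mu, sg, thr)
}

#' Sum of repeat-element methylation Z-scores
#'
#' \code{sum((value - mean) / sd)} over Alu, LINE-1 and SAT2; strictly
#' increasing in each marker value.
#'
#' @param repeatValues numeric vector of the three repeat methylation
#'   fractions.
#' @param calib a \linkS4class{ZScoreCalibration}.
#' @return scalar Z-score sum.
#' @examples
#' calib <- ZScoreCalibration(0.36, 0.25, -0.01217)
#' zscoreSum(c(0.36, 0.36, 0.36), calib)  # 0
#' zscoreSum(c(0.11, 0.36, 0.36), calib)  # -1
#' @export
zscoreSum <- function(repeatValues, calib) {
  repeatValues <- as.numeric(repeatValues)
  if (length(repeatValues) != 3 || anyNA(repeatValues))
    stop("need the three repeat-element methylation values")
  sum((repeatValues - calib@mean) / calib@sd)
}

#' Z-score-based global hypomethylation call
#'
#' \code{TRUE} iff the Z-score sum falls strictly below the calibrated
#' threshold (a sum exactly at the threshold is \emph{not} hypomethylated).
#'
#' @inheritParams zscoreSum
#' @return logical.
#' @export
callGlobalHypomethylationZscore <- function(repeatValues, calib) {
  zscoreSum(repeatValues, calib) < calib@threshold
}
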