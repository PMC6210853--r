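.FEATURE_FLAGS <- c("ctnnb1_mut", "tp53_mut", "tertp_mut", "tsg_hyper",
                    "global_hypo", "fal_high")

#' Complete disjunctive coding of the six binary events
#'
#' Builds the indicator table for correspondence analysis: each of the six
#' molecular events contributes a \code{.present} and a \code{.absent}
#' column, so every row sums to 6.
#'
#' @param features data.frame with the six logical feature columns and
#'   \code{sample_id}.
#' @return samples x 12 binary matrix (rownames = sample ids).
#' @export
buildIndicatorMatrix <- function(features) {
  miss <- setdiff(.FEATURE_FLAGS, colnames(features))
  if (length(miss))
    stop("features lack columns: ", paste(miss, collapse = ", "))
  n <- nrow(features)
  out <- matrix(0L, n, 2L * length(.FEATURE_FLAGS))
  cn <- character(0)
  for (i in seq_along(.FEATURE_FLAGS)) {
    f <- .FEATURE_FLAGS[i]
    v <- features[[f]]
    if (anyNA(v))
      stop(sprintf("undefined flag %s for sample %s", f,
                   features$sample_id[which(is.na(v))[1]]))
    out[, 2 * i - 1] <- as.integer(v)
    out[, 2 * i] <- as.integer(!v)
    cn <- c(cn, paste0(f, ".present"), paste0(f, ".absent"))
  }
  colnames(out) <- cn
  rownames(out) <- as.character(features$sample_id)
  out
}

#' Correspondence analysis of the indicator table
#'
#' Simple correspondence analysis of the complete disjunctive table (the
#' indicator route to multiple correspondence analysis): with correspondence
#' matrix \eqn{P = N / n_{++}}, row and column masses \eqn{r, c}, the SVD of
#' the standardized residuals \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}
#' gives row principal coordinates \eqn{D_r^{-1/2} U \Sigma} (first two
#' axes kept). Constant columns are dropped (with a message) before the
#' analysis. Axis signs, which are arbitrary in the SVD, are anchored so that
#' the \code{tp53_mut.present} column has a nonnegative coordinate on each
#' axis (falling back to the first column with a nonzero coordinate).
#'
#' The mass-weighted mean of the row coordinates is 0 on each axis, and the
#' squared singular values sum to the total inertia (the Pearson chi-square
#' statistic of the table divided by its grand total).
#'
#' @param indicator nonnegative matrix without all-zero rows (typically from
#'   \code{\link{buildIndicatorMatrix}}).
#' @return a \linkS4class{CorrespondenceMap}.
#' @export
correspondenceAnalysis <- function(indicator) {
  N <- as.matrix(indicator)
  if (any(N < 0)) stop("indicator table must be nonnegative")
  if (any(rowSums(N) == 0)) stop("all-zero row in indicator table")
  const <- apply(N, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    message("dropping constant column(s): ",
            paste(colnames(N)[const], collapse = ", "))
    N <- N[, !const, drop = FALSE]
  }
  if (ncol(N) < 2) stop("cannot embed in 2-D: fewer than 2 varying columns")
  P <- N / sum(N)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  if (length(keep) < 2) stop("cannot embed in 2-D: table rank < 2")
  d <- sv$d[keep]
  row <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*% diag(d)
  col <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cc), "/") %*% diag(d)
  rownames(row) <- rownames(N)
  rownames(col) <- colnames(N)
  anchor <- if ("tp53_mut.present" %in% rownames(col)) "tp53_mut.present"
            else rownames(col)[1]
  for (k in 1:2) {
    s <- sign(col[anchor, k])
    if (s == 0) {
      nz <- which(col[, k] != 0)
      s <- if (length(nz)) sign(col[nz[1], k]) else 1
    }
    row[, k] <- s * row[, k]
    col[, k] <- s * col[, k]
  }
  new("CorrespondenceMap",
      rowCoords = row[, 1:2, drop = FALSE],
      colCoords = col[, 1:2, drop = FALSE],
      singularValues = d, totalInertia = sum(d^2))
}

#' Cluster samples on the correspondence map
#'
#' Ward-linkage agglomeration (Euclidean distance) on the two-dimensional row
#' coordinates, cut at \code{k} clusters. Cluster ids are relabeled
#' deterministically by the lexicographic order of the cluster centroids, so
#' the assignment is invariant to input order.
#'
#' @param map a \linkS4class{CorrespondenceMap}.
#' @param k number of clusters (the reference procedure uses 4).
#' @return named integer vector of cluster ids in 1..k.
#' @export
clusterSubclasses <- function(map, k = 4) {
  xy <- rowCoords(map)
  if (nrow(xy) < k) stop("fewer samples than clusters")
  if (nrow(unique(xy)) < k)
    stop("fewer than k distinct coordinate points; lower k")
  ord <- order(rownames(xy))
  m <- xy[ord, , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  cx <- tapply(m[, 1], grp, mean)
  cy <- tapply(m[, 2], grp, mean)
  # relabel so cluster 1 has the lexicographically smallest centroid
  grp <- stats::setNames(match(grp, order(cx, cy)), names(grp))
  grp[rownames(xy)]
}

#' Label raw clusters as molecular subclasses A1/A2/B1/B2
#'
#' Deterministic post-hoc labeling rule mirroring the published subclass
#' profiles: clusters whose TSG-hypermethylation prevalence is >= 50\% form
#' group B (the published B clusters sit at >= 94\%, the A clusters at
#' <= 22\%), the rest group A; within each group the cluster with the higher
#' prevalence of high FAL gets subscript 1 (the chromosomally unstable,
#' aggressive member of the pair). If the hypermethylation rule does not
#' split 2 + 2, the clusters are ranked and the top two form group B, with a
#' warning.
#'
#' @param clusters named integer vector from \code{\link{clusterSubclasses}}
#'   (4 clusters).
#' @param features the feature data.frame the clusters were derived from.
#' @return data.frame with \code{sample_id}, \code{raw_cluster},
#'   \code{subclass} (factor A1/A2/B1/B2); per-cluster feature prevalences
#'   attached as attribute \code{"profile"}.
#' @export
labelSubclasses <- function(clusters, features) {
  ids <- as.character(features$sample_id)
  stopifnot(all(ids %in% names(clusters)))
  cl <- clusters[ids]
  uc <- sort(unique(cl))
  if (length(uc) != 4) stop("expected exactly 4 raw clusters")
  prof <- t(vapply(uc, function(g) {
    colMeans(features[cl == g, .FEATURE_FLAGS, drop = FALSE])
  }, numeric(length(.FEATURE_FLAGS))))
  rownames(prof) <- uc
  hyper <- prof[, "tsg_hyper"]
  isB <- hyper >= 0.5
  if (sum(isB) != 2) {
    warning("hypermethylation prevalences do not split clusters 2+2; ",
            "taking the top two as group B")
    isB <- rank(-hyper, ties.method = "first") <= 2
  }
  lab <- character(4)
  names(lab) <- as.character(uc)
  for (g in c("A", "B")) {
    members <- uc[if (g == "B") isB else !isB]
    fal <- prof[as.character(members), "fal_high"]
    one <- members[order(-fal, members)][1]
    lab[as.character(one)] <- paste0(g, "1")
    lab[as.character(setdiff(members, one))] <- paste0(g, "2")
  }
  out <- data.frame(sample_id = ids, raw_cluster = unname(cl),
                    subclass = factor(unname(lab[as.character(cl)]),
                                      levels = c("A1", "A2", "B1", "B2")),
                    row.names = NULL)
  attr(out, "profile") <- prof
  out
}

#' Full molecular subclassification
#'
#' Composes \code{\link{buildIndicatorMatrix}},
#' \code{\link{correspondenceAnalysis}}, \code{\link{clusterSubclasses}} and
#' \code{\link{labelSubclasses}}.
#'
#' @param features feature data.frame from \code{\link{callFeatures}}.
#' @param k number of clusters.
#' @return data.frame with \code{sample_id}, \code{axis1}, \code{axis2},
#'   \code{raw_cluster}, \code{subclass}; the
#'   \linkS4class{CorrespondenceMap} is attached as attribute \code{"map"}
#'   and the cluster profile as \code{"profile"}.
#' @export
subclassify <- function(features, k = 4) {
  ind <- buildIndicatorMatrix(features)
  map <- correspondenceAnalysis(ind)
  cl <- clusterSubclasses(map, k = k)
  lab <- labelSubclasses(cl, features)
  xy <- rowCoords(map)[as.character(features$sample_id), , drop = FALSE]
  out <- data.frame(sample_id = lab$sample_id, axis1 = xy[, 1],
                    axis2 = xy[, 2], raw_cluster = lab$raw_cluster,
                    subclass = lab$subclass, row.names = NULL)
  attr(out, "map") <- map
  attr(out, "profile") <- attr(lab, "profile")
  out
}

#' Plot the correspondence map
#'
#' Samples as points (optionally colored by subclass), event categories as
#' labeled crosses.
#'
#' @param map a \linkS4class{CorrespondenceMap}.
#' @param subclass optional factor of subclass labels, sample order matching
#'   the map rows.
#' @export
plotCorrespondenceMap <- function(map, subclass = NULL) {
  xy <- rowCoords(map)
  col <- if (is.null(subclass)) "grey30" else as.integer(as.factor(subclass)) + 1L
  graphics::plot(xy, col = col, pch = 16, xlab = "axis 1", ylab = "axis 2",
                 main = "Correspondence map of molecular events")
  cc <- colCoords(map)
  graphics::points(cc, pch = 3, col = "black")
  graphics::text(cc, labels = rownames(cc), pos = 3, cex = 0.6)
  invisible(map)
}
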