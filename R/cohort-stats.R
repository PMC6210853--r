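#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction — the
#' convention all the reference association tables follow), statistic
#' \eqn{\sum (O - E)^2 / E} with \eqn{(r-1)(c-1)} degrees of freedom and an
#' upper-tail p-value. A warning is issued when any expected count is below
#' 5 (Fisher's exact test is then the better choice).
#'
#' @param counts r x c matrix of nonnegative integer counts, r, c >= 2.
#' @return \code{htest} object with \code{statistic}, \code{parameter} (df)
#'   and \code{p.value}.
#' @examples
#' pearsonChiSquare(matrix(c(28, 3, 62, 32), 2))$p.value  # 0.0088
#' @export
pearsonChiSquare <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("expected count below 5; consider fisherExact")
  suppressWarnings(stats::chisq.test(counts, correct = FALSE))
}

#' Fisher's exact test of a 2 x 2 table
#'
#' Two-sided exact p-value by summation of hypergeometric probabilities no
#' larger than that of the observed table.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return \code{htest} object.
#' @export
fisherExact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("fisherExact is defined for 2 x 2 tables only")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  stats::fisher.test(counts)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators (1 = recurrence/death, 0 = censored).
#' @return object of class \code{"kmCurve"}: data.frame with one row per
#'   distinct event time (\code{time}, \code{nRisk}, \code{nEvent},
#'   \code{survival}); \eqn{S(0) = 1} and the curve is a right-continuous
#'   step function, nonincreasing in \[0, 1\].
#' @examples
#' kmEstimate(c(2, 5, 7, 9), c(1, 0, 0, 0))  # S drops to 0.75 at t = 2
#' @export
kmEstimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(events)
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  evTimes <- sort(unique(times[events == 1L]))
  nRisk <- vapply(evTimes, function(t) sum(times >= t), numeric(1))
  nEvent <- vapply(evTimes, function(t) sum(times == t & events == 1L), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  out <- data.frame(time = evTimes, nRisk = nRisk, nEvent = nEvent,
                    survival = surv)
  class(out) <- c("kmCurve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a \code{kmCurve}.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities.
#' @export
kmSurvival <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- curve$time <= ti
    if (!any(idx)) 1 else curve$survival[max(which(idx))]
  }, numeric(1))
}

#' @describeIn kmEstimate step-function plot of the curve.
#' @param x a \code{kmCurve}.
#' @param ... passed to \code{plot}.
#' @export
plot.kmCurve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
                 ylim = c(0, 1), xlab = "months", ylab = "survival",
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with 1 degree of freedom,
#' comparing event-time distributions between two groups using the
#' hypergeometric mean and variance of the group-1 event count at each
#' distinct event time.
#'
#' @param timesA,eventsA follow-up and 0/1 event indicator, group A.
#' @param timesB,eventsB same for group B.
#' @return \code{htest}-style list with \code{statistic}, \code{parameter}
#'   (df = 1), \code{p.value} and the observed/expected event counts.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) stop("both groups must be non-empty")
  times <- c(as.numeric(timesA), as.numeric(timesB))
  events <- c(as.integer(eventsA), as.integer(eventsB))
  grp1 <- rep(c(TRUE, FALSE), c(length(timesA), length(timesB)))
  if (any(times < 0)) stop("negative follow-up time")
  if (sum(events) == 0) stop("log-rank test undefined: no events")
  evTimes <- sort(unique(times[events == 1L]))
  O1 <- E1 <- V <- 0
  for (t in evTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & grp1)
    d <- sum(times == t & events == 1L)
    d1 <- sum(times == t & events == 1L & grp1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  res <- list(statistic = c(chisq = stat), parameter = c(df = 1),
              p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
              observed = O1, expected = E1,
              method = "Two-group log-rank test")
  class(res) <- "htest"
  res
}

#' ROC-optimal threshold (Youden's J)
#'
#' Scans all candidate cuts (midpoints between adjacent sorted unique scores)
#' and returns the one maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken toward the cut with the higher sensitivity, then
#' deterministically by cut value. With \code{positiveIsLow = TRUE} a sample
#' is predicted positive when its score falls \emph{below} the cut (the
#' direction used for the global-hypomethylation Z-score sum).
#'
#' @param scores numeric scores.
#' @param labels logical class labels (both classes must occur).
#' @param positiveIsLow direction of the positive prediction.
#' @return the selected threshold (a midpoint).
#' @examples
#' rocBestThreshold(c(-3, -2, 2, 3), c(TRUE, TRUE, FALSE, FALSE),
#'                  positiveIsLow = TRUE)  # 0
#' @export
rocBestThreshold <- function(scores, labels, positiveIsLow = FALSE) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both label classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores identical: no candidate cut")
  cuts <- (u[-1] + u[-length(u)]) / 2
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  eval1 <- function(cut) {
    pred <- if (positiveIsLow) scores < cut else scores > cut
    sens <- sum(pred & labels) / nPos
    spec <- sum(!pred & !labels) / nNeg
    c(j = sens + spec - 1, sens = sens)
  }
  perf <- t(vapply(cuts, eval1, c(j = 0, sens = 0)))
  best <- order(-perf[, "j"], -perf[, "sens"], cuts)[1]
  cuts[best]
}

.COVARIATE_DEFS <- function(afpCut = 200, sizeCut = 3, ageCut = 60) list(
  sex = function(cl) factor(cl$sex, levels = c("male", "female")),
  age = function(cl) factor(ifelse(cl$age_years > ageCut, "gt", "le"),
                            levels = c("gt", "le")),
  hbv = function(cl) factor(cl$hbsag, levels = c("positive", "negative")),
  hcv = function(cl) factor(cl$hcvab, levels = c("positive", "negative")),
  nbnc = function(cl) factor(ifelse(cl$hbsag == "negative" & cl$hcvab == "negative",
                                    "yes", "no"), levels = c("yes", "no")),
  afp = function(cl) factor(ifelse(cl$afp_ng_ml >= afpCut, "high", "low"),
                            levels = c("high", "low")),
  tumor_size = function(cl) factor(ifelse(cl$tumor_size_cm >= sizeCut, "ge", "lt"),
                                   levels = c("ge", "lt")),
  vascular_invasion = function(cl) factor(as.character(cl$vascular_invasion),
                                          levels = c("presence", "absence")),
  tumor_number = function(cl) factor(as.character(cl$tumor_number),
                                     levels = c("solitary", "multiple")),
  differentiation = function(cl) factor(as.character(cl$differentiation),
                                        levels = c("well", "moderately_poorly"))
)

#' Association scan: molecular features vs clinical covariates
#'
#' Recreates the layout of the published association tables: for each
#' molecular feature (the six binary events, or a subclass factor) crossed
#' with each binarized clinical covariate, builds the contingency table with
#' missing values dropped pairwise, and applies the uncorrected Pearson
#' chi-square test. Covariates: sex, age (> 60), HBsAg, HCVAb, NBNC
#' (negative for both), serum AFP (>= \code{afpCut} ng/mL), tumor size
#' (>= 3 cm), vascular invasion, tumor number and differentiation (the last
#' three have an explicit missing level that is excluded per test).
#'
#' @param cohort an \linkS4class{HccCohort}.
#' @param features data.frame from \code{\link{callFeatures}}, optionally
#'   with a \code{subclass} column from \code{\link{subclassify}}.
#' @param featureCols which feature columns to scan.
#' @param afpCut AFP dichotomization in ng/mL.
#' @return data.frame with \code{feature}, \code{covariate},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{n}; the underlying
#'   tables are attached as attribute \code{"tables"} (named list).
#' @export
associationScan <- function(cohort, features,
                            featureCols = c("ctnnb1_mut", "tp53_mut",
                                            "tertp_mut", "tsg_hyper",
                                            "global_hypo", "fal_high"),
                            afpCut = 200) {
  cl <- clinicalData(cohort)
  stopifnot(identical(cl$sample_id, features$sample_id))
  covs <- .COVARIATE_DEFS(afpCut = afpCut)
  rows <- list()
  tables <- list()
  for (f in featureCols) {
    fv <- features[[f]]
    if (is.logical(fv)) fv <- factor(fv, levels = c(TRUE, FALSE),
                                     labels = c("present", "absent"))
    fv <- droplevels(as.factor(fv))
    for (cv in names(covs)) {
      cvv <- covs[[cv]](cl)
      keep <- !is.na(fv) & !is.na(cvv)
      if (!sum(keep)) {
        warning(sprintf("skipping %s x %s: no complete pairs", f, cv))
        next
      }
      tab <- table(feature = fv[keep], covariate = droplevels(cvv[keep]))
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        warning(sprintf("skipping %s x %s: degenerate table", f, cv))
        next
      }
      res <- suppressWarnings(pearsonChiSquare(tab))
      key <- paste(f, cv, sep = "|")
      tables[[key]] <- tab
      rows[[key]] <- data.frame(feature = f, covariate = cv,
                                statistic = unname(res$statistic),
                                df = unname(res$parameter),
                                p_value = res$p.value, n = sum(keep))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "tables") <- tables
  out
}
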