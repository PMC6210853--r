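#' Fractional allelic loss (FAL)
#'
#' FAL is the percentage of informative microsatellite loci showing allelic
#' imbalance: \code{100 * imbalanced / informative}. Non-informative loci
#' (homozygous in the matched normal) carry no information and are excluded
#' from both numerator and denominator. With fewer informative loci than
#' \code{minInformative} the score is undefined (\code{NA} with a warning);
#' such samples are excluded from the cohort median and cannot be risk-scored
#' on the microsatellite route.
#'
#' @param informative logical vector, one entry per typed locus.
#' @param imbalance logical vector, same length; imbalance implies
#'   informative.
#' @param minInformative minimum informative loci for a defined score.
#' @return FAL as percent in \[0, 100\], or \code{NA}.
#' @examples
#' computeFAL(rep(TRUE, 20), rep(FALSE, 20))          # 0
#' computeFAL(rep(c(TRUE, FALSE), c(100, 300)),
#'            rep(c(TRUE, FALSE), c(21, 379)))        # 21
#' @export
computeFAL <- function(informative, imbalance, minInformative = 10) {
  stopifnot(length(informative) == length(imbalance))
  if (any(imbalance & !informative))
    stop("allelic imbalance recorded at a non-informative locus")
  nInf <- sum(informative)
  if (nInf < minInformative) {
    warning(sprintf("only %d informative loci (< %d): FAL undefined",
                    nInf, minInformative))
    return(NA_real_)
  }
  100 * sum(imbalance & informative) / nInf
}

#' Per-sample FAL for a cohort
#'
#' @param cohort an \linkS4class{HccCohort}.
#' @param minInformative see \code{\link{computeFAL}}.
#' @return named numeric vector of FAL percentages (NA where undefined or no
#'   microsatellite data).
#' @export
cohortFAL <- function(cohort, minInformative = 10) {
  ms <- microsatellites(cohort)
  ids <- sampleIDs(cohort)
  fal <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (nrow(ms)) {
    if (any(ms$imbalance & !ms$informative))
      stop("allelic imbalance recorded at a non-informative locus")
    nInf <- rowsum(as.integer(ms$informative), ms$sample_id)
    nImb <- rowsum(as.integer(ms$imbalance & ms$informative), ms$sample_id)
    ok <- nInf[, 1] >= minInformative
    vals <- ifelse(ok, 100 * nImb[, 1] / nInf[, 1], NA_real_)
    fal[rownames(nInf)] <- vals
  }
  und <- names(fal)[ids %in% unique(ms$sample_id) & is.na(fal)]
  if (length(und))
    warning("FAL undefined (too few informative loci) for: ",
            paste(und, collapse = ", "))
  fal
}

#' Cohort FAL threshold (median split)
#'
#' The binarization cut for "high FAL" is the cohort median of the defined
#' FAL scores (21\% in the reference resection cohort).
#'
#' @param falValues numeric FAL percentages; NAs are dropped.
#' @return the median.
#' @examples
#' falThresholdFromCohort(c(2, 21, 64))  # 21
#' @export
falThresholdFromCohort <- function(falValues) {
  v <- falValues[!is.na(falValues)]
  if (length(v) < 2) stop("need at least 2 defined FAL values")
  stats::median(v)
}

#' Copy-number alteration fraction (TCGA-style FAL surrogate)
#'
#' When microsatellite data are unavailable, the percentage of genes with an
#' altered copy-number state stands in for FAL. A gene counts as altered when
#' its thresholded state differs from 0, or when \code{|log-ratio| >=
#' logRatioCut} for continuous input.
#'
#' @param cn gene x sample matrix.
#' @param sampleId column to evaluate.
#' @param valueKind \code{"thresholded"} or \code{"log_ratio"}.
#' @param logRatioCut absolute log-ratio cut for continuous input.
#' @return percent of genes altered, in \[0, 100\].
#' @export
cnAlterationFraction <- function(cn, sampleId, valueKind = "thresholded",
                                 logRatioCut = 0.2) {
  if (!sampleId %in% colnames(cn)) stop("unknown sample: ", sampleId)
  v <- cn[, sampleId]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no copy-number values for sample ", sampleId)
  altered <- if (valueKind == "log_ratio") abs(v) >= logRatioCut else v != 0
  100 * sum(altered) / length(v)
}

#' Binarize a copy-number alteration fraction
#'
#' High-FAL surrogate call: \code{percent >= threshold}, default 39\% (the
#' value bracketing the TCGA cohort's mean 40\% and median 37\%).
#'
#' @param percent alteration fraction in \[0, 100\].
#' @param threshold cut in percent.
#' @return logical.
#' @export
binarizeCnFraction <- function(percent, threshold = 39) {
  stopifnot(all(percent >= 0 & percent <= 100, na.rm = TRUE))
  percent >= threshold
}

#' Call the six binary molecular features for a cohort
#'
#' Produces the per-sample \code{MolecularFeatureVector} table: the three
#' mutation flags as given, TSG-promoter hypermethylation and global
#' hypomethylation from hierarchical clustering of the methylation panels
#' (or, for \code{hypoMethod = "zscore"}, from a frozen
#' \linkS4class{ZScoreCalibration}), the FAL percentage from the
#' microsatellite panel, and \code{fal_high = fal_percent >= threshold} with
#' the threshold taken as the cohort median by default.
#'
#' @param cohort an \linkS4class{HccCohort}.
#' @param hypoMethod \code{"cluster"} (de novo clustering of Alu/LINE-1/SAT2)
#'   or \code{"zscore"} (apply \code{calibration}).
#' @param calibration \linkS4class{ZScoreCalibration}, required for
#'   \code{hypoMethod = "zscore"}.
#' @param falThreshold \code{"median"} or a numeric percent.
#' @param minInformative minimum informative loci for a defined FAL.
#' @return data.frame with columns \code{sample_id}, the six logical flags
#'   and \code{fal_percent}; the applied FAL threshold is attached as
#'   attribute \code{"fal_threshold"}.
#' @seealso \code{\link{callTsgHypermethylation}},
#'   \code{\link{callGlobalHypomethylationCluster}},
#'   \code{\link{fitZscoreCalibration}}
#' @export
callFeatures <- function(cohort, hypoMethod = c("cluster", "zscore"),
                         calibration = NULL, falThreshold = "median",
                         minInformative = 10) {
  hypoMethod <- match.arg(hypoMethod)
  ids <- sampleIDs(cohort)
  mut <- mutationCalls(cohort)

  hyper <- callTsgHypermethylation(promoterMeth(cohort))$calls
  hypo <- if (hypoMethod == "cluster") {
    callGlobalHypomethylationCluster(repeatMeth(cohort))$calls
  } else {
    if (is.null(calibration)) stop("hypoMethod = 'zscore' needs a calibration")
    rm <- repeatMeth(cohort)
    vapply(ids, function(id)
      callGlobalHypomethylationZscore(rm[id, ], calibration), logical(1))
  }

  fal <- cohortFAL(cohort, minInformative)
  thr <- if (identical(falThreshold, "median")) {
    falThresholdFromCohort(fal)
  } else {
    as.numeric(falThreshold)
  }

  out <- data.frame(sample_id = ids,
                    ctnnb1_mut = mut$ctnnb1_mut,
                    tp53_mut = mut$tp53_mut,
                    tertp_mut = mut$tertp_mut,
                    tsg_hyper = unname(hyper[ids]),
                    global_hypo = unname(hypo[ids]),
                    fal_high = unname(fal[ids] >= thr),
                    fal_percent = unname(fal[ids]),
                    row.names = NULL)
  attr(out, "fal_threshold") <- thr
  out
}
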