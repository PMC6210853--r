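#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

#' Marker panels
#'
#' The eight tumor-suppressor-gene promoters assayed for regional
#' hypermethylation and the three repetitive DNA elements assayed for global
#' hypomethylation.
#'
#' @return Character vector of marker names.
#' @examples
#' promoterMarkers()
#' repeatMarkers()
#' @export
promoterMarkers <- function() {
  c("APC", "CDKN2A", "RASSF1A", "HIC1", "GSTP1", "RUNX3", "SOCS1", "PRDM2")
}

#' @rdname promoterMarkers
#' @export
repeatMarkers <- function() c("Alu", "LINE1", "SAT2")

.CLINICAL_COLS <- c("sample_id", "sex", "age_years", "hbsag", "hcvab",
                    "afp_ng_ml", "tumor_size_cm", "vascular_invasion",
                    "tumor_number", "differentiation", "treatment",
                    "rfs_months", "recurrence_event")
.MUTATION_COLS <- c("ctnnb1_mut", "tp53_mut", "tertp_mut")

#' HccCohort: a molecularly profiled tumor cohort
#'
#' An S4 container for a hepatocellular-carcinoma cohort, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"methylation"}
#' holds the 11 methylation markers (8 promoters, 3 repetitive elements) as
#' fractions in \[0, 1\], markers in rows and samples in columns;
#' \code{colData} carries the clinical covariates and the three binary
#' mutation calls. Microsatellite allelic-imbalance calls (the raw material of
#' the fractional-allelic-loss score) and an optional gene-by-sample copy
#' number matrix ride along in dedicated slots.
#'
#' @slot microsatellites \code{DataFrame} with columns \code{sample_id},
#'   \code{locus_id}, \code{informative}, \code{imbalance} (logical); an
#'   imbalanced locus must be informative.
#' @slot copyNumber numeric matrix, genes in rows and samples in columns
#'   (0 rows when absent).
#' @slot cnValueKind \code{"thresholded"} (integer states -2..2) or
#'   \code{"log_ratio"}.
#' @slot provenance free-text description of where the data came from.
#'
#' @seealso \code{\link{HccCohort}} (constructor), \code{\link{readCohort}},
#'   \code{\link{generateCohort}}
#' @export
setClass("HccCohort",
  contains = "SummarizedExperiment",
  representation(
    microsatellites = "DataFrame",
    copyNumber = "matrix",
    cnValueKind = "character",
    provenance = "character"
  )
)

setValidity("HccCohort", function(object) {
  msg <- character()
  markers <- c(promoterMarkers(), repeatMarkers())
  if (!identical(assayNames(object), "methylation"))
    msg <- c(msg, "assay must be a single matrix named 'methylation'")
  else {
    m <- assay(object, "methylation")
    if (!identical(rownames(m), markers))
      msg <- c(msg, sprintf("methylation rows must be exactly: %s",
                            paste(markers, collapse = ", ")))
    bad <- !is.na(m) & (m < 0 | m > 1)
    if (any(bad))
      msg <- c(msg, "methylation fractions must lie in [0, 1]")
  }
  ids <- colnames(object)
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate sample_id")
  need <- setdiff(c(.CLINICAL_COLS, .MUTATION_COLS), "sample_id")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, sprintf("colData lacks columns: %s", paste(miss, collapse = ", ")))
  ms <- object@microsatellites
  if (nrow(ms)) {
    if (!all(c("sample_id", "locus_id", "informative", "imbalance") %in% colnames(ms)))
      msg <- c(msg, "microsatellites needs sample_id, locus_id, informative, imbalance")
    else {
      if (any(ms$imbalance & !ms$informative))
        msg <- c(msg, "allelic imbalance is only defined on informative loci")
      if (!all(ms$sample_id %in% ids))
        msg <- c(msg, "microsatellite rows refer to unknown samples")
    }
  }
  if (ncol(object@copyNumber) > 0 && !all(colnames(object@copyNumber) %in% ids))
    msg <- c(msg, "copy-number columns refer to unknown samples")
  if (!object@cnValueKind %in% c("thresholded", "log_ratio"))
    msg <- c(msg, "cnValueKind must be 'thresholded' or 'log_ratio'")
  if (length(msg)) msg else TRUE
})

#' Z-score calibration for the global-hypomethylation call
#'
#' Freezes the pooled mean and standard deviation of the repetitive-element
#' methylation fractions of a training cohort, together with the ROC-selected
#' threshold on the per-sample sum of the three Z-scores. A sample is called
#' hypomethylated when its Z-score sum falls strictly below
#' \code{threshold(x)}. The published calibration (training mean 0.36, SD
#' 0.25, threshold -0.01217) can be reconstructed with
#' \code{ZScoreCalibration(0.36, 0.25, -0.01217)}.
#'
#' @slot mean pooled training mean of Alu/LINE-1/SAT2 methylation fractions.
#' @slot sd pooled training standard deviation (> 0).
#' @slot threshold cut on the Z-score sum; below is hypomethylated.
#' @seealso \code{\link{fitZscoreCalibration}}, \code{\link{zscoreSum}}
#' @export
setClass("ZScoreCalibration",
  representation(mean = "numeric", sd = "numeric", threshold = "numeric"))

setValidity("ZScoreCalibration", function(object) {
  if (length(object@mean) != 1 || length(object@sd) != 1 ||
      length(object@threshold) != 1)
    return("mean, sd and threshold must be scalars")
  if (!is.finite(object@sd) || object@sd <= 0)
    return("sd must be a positive number")
  TRUE
})

#' @rdname ZScoreCalibration-class
#' @param mean,sd,threshold scalar calibration parameters.
#' @return A \code{ZScoreCalibration} object.
#' @export
ZScoreCalibration <- function(mean, sd, threshold) {
  new("ZScoreCalibration", mean = as.numeric(mean), sd = as.numeric(sd),
      threshold = as.numeric(threshold))
}

#' Correspondence-analysis map of the binary molecular events
#'
#' Result of simple correspondence analysis of the complete disjunctive
#' (indicator) table of the six binary events: row (sample) and column
#' (event-level) principal coordinates on the first two axes, all non-trivial
#' singular values, and the total inertia (Pearson chi-square statistic of the
#' table divided by its grand total).
#'
#' @slot rowCoords samples x 2 matrix of row principal coordinates.
#' @slot colCoords categories x 2 matrix of column principal coordinates.
#' @slot singularValues non-trivial singular values, decreasing.
#' @slot totalInertia sum of squared singular values.
#' @seealso \code{\link{correspondenceAnalysis}}
#' @export
setClass("CorrespondenceMap",
  representation(rowCoords = "matrix", colCoords = "matrix",
                 singularValues = "numeric", totalInertia = "numeric"))
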