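.CATEGORICAL_LEVELS <- list(
  sex = c("male", "female"),
  hbsag = c("positive", "negative"),
  hcvab = c("positive", "negative"),
  vascular_invasion = c("presence", "absence", "missing"),
  tumor_number = c("solitary", "multiple", "missing"),
  differentiation = c("well", "moderately_poorly", "missing"),
  treatment = c("resection", "transplantation")
)

.emptyMicrosatellites <- function() {
  DataFrame(sample_id = character(), locus_id = character(),
            informative = logical(), imbalance = logical())
}

.checkClinical <- function(clinical) {
  miss <- setdiff(.CLINICAL_COLS, colnames(clinical))
  if (length(miss))
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  for (col in names(.CATEGORICAL_LEVELS)) {
    lv <- .CATEGORICAL_LEVELS[[col]]
    v <- as.character(clinical[[col]])
    v[is.na(v) | v == ""] <- if ("missing" %in% lv) "missing" else NA
    bad <- which(!is.na(v) & !v %in% lv)
    if (length(bad))
      stop(sprintf("invalid %s value '%s' (sample %s)", col, v[bad[1]],
                   clinical$sample_id[bad[1]]))
    clinical[[col]] <- factor(v, levels = lv)
  }
  for (col in c("age_years", "afp_ng_ml", "tumor_size_cm", "rfs_months")) {
    clinical[[col]] <- as.numeric(clinical[[col]])
  }
  if (any(clinical$afp_ng_ml < 0, na.rm = TRUE)) stop("afp_ng_ml must be >= 0")
  if (any(clinical$rfs_months < 0, na.rm = TRUE)) stop("rfs_months must be >= 0")
  ev <- clinical$recurrence_event
  if (!all(is.na(ev) | ev %in% c(0, 1))) stop("recurrence_event must be 0/1")
  clinical$recurrence_event <- as.integer(ev)
  clinical
}

#' Construct an HccCohort
#'
#' Assembles the per-sample tables into a validated \linkS4class{HccCohort}.
#' Methylation is supplied as fractions in \[0, 1\] (the TSV readers convert
#' from file percent exactly once).
#'
#' @param clinical data.frame with columns \code{sample_id, sex, age_years,
#'   hbsag, hcvab, afp_ng_ml, tumor_size_cm, vascular_invasion, tumor_number,
#'   differentiation, treatment, rfs_months, recurrence_event}. Empty cells in
#'   \code{vascular_invasion}, \code{tumor_number} and \code{differentiation}
#'   become the explicit level \code{"missing"}.
#' @param mutations data.frame with \code{sample_id} and logical/0-1 columns
#'   \code{ctnnb1_mut, tp53_mut, tertp_mut}, or \code{NULL} for all-NA.
#' @param methylation data.frame/matrix of fractions with \code{sample_id}
#'   rows and the 11 marker columns (see \code{\link{promoterMarkers}}), or
#'   \code{NULL}.
#' @param microsatellites data.frame with \code{sample_id, locus_id,
#'   informative, imbalance}, or \code{NULL}.
#' @param copyNumber optional gene x sample numeric matrix.
#' @param cnValueKind \code{"thresholded"} or \code{"log_ratio"}.
#' @param provenance free-text provenance note.
#' @return An \linkS4class{HccCohort}.
#' @examples
#' clin <- data.frame(sample_id = "T1", sex = "male", age_years = 63,
#'   hbsag = "negative", hcvab = "positive", afp_ng_ml = 12,
#'   tumor_size_cm = 3.6, vascular_invasion = "absence",
#'   tumor_number = "solitary", differentiation = "well",
#'   treatment = "resection", rfs_months = 24, recurrence_event = 0)
#' mut <- data.frame(sample_id = "T1", ctnnb1_mut = TRUE, tp53_mut = FALSE,
#'   tertp_mut = TRUE)
#' HccCohort(clin, mut)
#' @export
HccCohort <- function(clinical, mutations = NULL, methylation = NULL,
                      microsatellites = NULL, copyNumber = NULL,
                      cnValueKind = "thresholded", provenance = "") {
  clinical <- .checkClinical(as.data.frame(clinical))
  ids <- as.character(clinical$sample_id)
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  markers <- c(promoterMarkers(), repeatMarkers())

  meth <- matrix(NA_real_, length(markers), length(ids),
                 dimnames = list(markers, ids))
  if (!is.null(methylation) && nrow(methylation)) {
    methylation <- as.data.frame(methylation)
    miss <- setdiff(markers, colnames(methylation))
    if (length(miss))
      stop("methylation table lacks markers: ", paste(miss, collapse = ", "))
    mid <- as.character(methylation$sample_id)
    unknown <- setdiff(mid, ids)
    if (length(unknown))
      stop("methylation rows for unknown samples: ", paste(unknown, collapse = ", "))
    meth[, mid] <- t(as.matrix(methylation[, markers, drop = FALSE]))
  }

  mut <- matrix(NA, length(ids), 3, dimnames = list(ids, .MUTATION_COLS))
  if (!is.null(mutations) && nrow(mutations)) {
    mutations <- as.data.frame(mutations)
    miss <- setdiff(c("sample_id", .MUTATION_COLS), colnames(mutations))
    if (length(miss))
      stop("mutation table lacks columns: ", paste(miss, collapse = ", "))
    mid <- as.character(mutations$sample_id)
    unknown <- setdiff(mid, ids)
    if (length(unknown))
      stop("mutation rows for unknown samples: ", paste(unknown, collapse = ", "))
    for (col in .MUTATION_COLS)
      mut[mid, col] <- as.logical(as.integer(mutations[[col]]) > 0)
  }

  cd <- DataFrame(clinical[, setdiff(.CLINICAL_COLS, "sample_id")],
                  row.names = ids)
  for (col in .MUTATION_COLS) cd[[col]] <- mut[, col]

  ms <- if (is.null(microsatellites) || !nrow(microsatellites)) {
    .emptyMicrosatellites()
  } else {
    m <- as.data.frame(microsatellites)
    DataFrame(sample_id = as.character(m$sample_id),
              locus_id = as.character(m$locus_id),
              informative = as.logical(as.integer(m$informative) > 0),
              imbalance = as.logical(as.integer(m$imbalance) > 0))
  }

  cn <- if (is.null(copyNumber)) {
    matrix(numeric(), 0, 0)
  } else {
    as.matrix(copyNumber)
  }

  se <- SummarizedExperiment(assays = list(methylation = meth), colData = cd)
  new("HccCohort", se, microsatellites = ms, copyNumber = cn,
      cnValueKind = cnValueKind, provenance = provenance)
}

#' Accessors for HccCohort
#'
#' @param x an \linkS4class{HccCohort}.
#' @return \code{sampleIDs}: character vector; \code{clinicalData},
#'   \code{mutationCalls}, \code{microsatellites}: data.frame;
#'   \code{promoterMeth}, \code{repeatMeth}: samples x markers matrix of
#'   fractions; \code{copyNumber}: gene x sample matrix (0 rows if absent).
#' @name cohort-accessors
#' @aliases sampleIDs clinicalData mutationCalls promoterMeth repeatMeth
#'   microsatellites copyNumber
#' @examples
#' cohort <- generateCohort(generatorConfig(n = 4, seed = 1))$cohort
#' sampleIDs(cohort)
#' head(mutationCalls(cohort))
NULL

#' @rdname cohort-accessors
#' @export
sampleIDs <- function(x) colnames(x)

#' @rdname cohort-accessors
#' @export
clinicalData <- function(x) {
  cd <- as.data.frame(colData(x)[, setdiff(.CLINICAL_COLS, "sample_id")])
  data.frame(sample_id = colnames(x), cd, row.names = NULL)
}

#' @rdname cohort-accessors
#' @export
mutationCalls <- function(x) {
  data.frame(sample_id = colnames(x),
             as.data.frame(colData(x)[, .MUTATION_COLS]),
             row.names = NULL)
}

#' @rdname cohort-accessors
#' @export
promoterMeth <- function(x) t(assay(x, "methylation")[promoterMarkers(), , drop = FALSE])

#' @rdname cohort-accessors
#' @export
repeatMeth <- function(x) t(assay(x, "methylation")[repeatMarkers(), , drop = FALSE])

#' @rdname cohort-accessors
#' @export
microsatellites <- function(x) as.data.frame(x@microsatellites)

#' @rdname cohort-accessors
#' @export
copyNumber <- function(x) x@copyNumber

#' @describeIn HccCohort-class compact display.
#' @param object an \code{HccCohort}.
#' @export
setMethod("show", "HccCohort", function(object) {
  cat(sprintf("HccCohort with %d samples\n", ncol(object)))
  nmut <- sum(!is.na(colData(object)$ctnnb1_mut))
  cat(sprintf("  mutation calls: %d samples; methylation: %d markers; microsatellite rows: %d\n",
              nmut, nrow(object), nrow(object@microsatellites)))
  if (ncol(object@copyNumber))
    cat(sprintf("  copy number: %d genes x %d samples (%s)\n",
                nrow(object@copyNumber), ncol(object@copyNumber),
                object@cnValueKind))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' @describeIn ZScoreCalibration-class compact display.
#' @param object a \code{ZScoreCalibration}.
#' @export
setMethod("show", "ZScoreCalibration", function(object) {
  cat(sprintf("ZScoreCalibration(mean = %.4g, sd = %.4g, threshold = %.6g)\n",
              object@mean, object@sd, object@threshold))
})

#' @describeIn CorrespondenceMap-class compact display.
#' @param object a \code{CorrespondenceMap}.
#' @export
setMethod("show", "CorrespondenceMap", function(object) {
  cat(sprintf("CorrespondenceMap: %d samples, %d categories, total inertia %.4f\n",
              nrow(object@rowCoords), nrow(object@colCoords),
              object@totalInertia))
})

#' @rdname CorrespondenceMap-class
#' @param x a \code{CorrespondenceMap}.
#' @return \code{rowCoords}/\code{colCoords}: two-column coordinate matrices;
#'   \code{singularValues}: numeric vector; \code{totalInertia}: scalar.
#' @export
rowCoords <- function(x) x@rowCoords

#' @rdname CorrespondenceMap-class
#' @export
colCoords <- function(x) x@colCoords

#' @rdname CorrespondenceMap-class
#' @export
singularValues <- function(x) x@singularValues

#' @rdname CorrespondenceMap-class
#' @export
totalInertia <- function(x) x@totalInertia

#' @rdname ZScoreCalibration-class
#' @param x a \code{ZScoreCalibration}.
#' @export
threshold <- function(x) x@threshold
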