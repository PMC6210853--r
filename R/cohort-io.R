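.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.numOrNA <- function(x) suppressWarnings(as.numeric(x))

#' Read a cohort from a directory of TSV files
#'
#' Expects UTF-8 tab-separated files with header rows (decimal point
#' \code{"."}, missing = empty cell): \code{samples.tsv} (clinical table),
#' and optionally \code{mutations.tsv}, \code{methylation.tsv} (marker values
#' as percent 0-100, divided by 100 on read), \code{microsatellites.tsv} and
#' \code{copynumber.tsv} (gene_id column then one column per sample). Clinical
#' rows with malformed numeric fields are rejected with their line numbers
#' (header = line 1) and reported; every input row is either accepted or
#' listed as rejected.
#'
#' @param dir directory containing the files.
#' @param cnValueKind interpretation of copynumber.tsv values:
#'   \code{"thresholded"} integer states or \code{"log_ratio"}.
#' @param verbose emit per-file row counts with \code{message()}.
#' @return A validated \linkS4class{HccCohort}.
#' @seealso \code{\link{writeCohort}}
#' @export
readCohort <- function(dir, cnValueKind = "thresholded", verbose = FALSE) {
  clin <- .readTsv(file.path(dir, "samples.tsv"))
  miss <- setdiff(.CLINICAL_COLS, colnames(clin))
  if (length(miss))
    stop("samples.tsv lacks columns: ", paste(miss, collapse = ", "))
  numCols <- c("age_years", "afp_ng_ml", "tumor_size_cm", "rfs_months",
               "recurrence_event")
  bad <- rep(FALSE, nrow(clin))
  for (col in numCols) {
    v <- clin[[col]]
    bad <- bad | (nzchar(v) & is.na(.numOrNA(v)))
  }
  if (any(bad)) {
    warning(sprintf("samples.tsv: rejected %d malformed row(s) at line(s) %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    clin <- clin[!bad, , drop = FALSE]
  }
  if (verbose)
    message(sprintf("samples.tsv: %d row(s) accepted, %d rejected",
                    nrow(clin), sum(bad)))
  for (col in numCols) clin[[col]] <- .numOrNA(clin[[col]])
  if (anyDuplicated(clin$sample_id))
    stop("duplicate sample_id in samples.tsv: ",
         clin$sample_id[duplicated(clin$sample_id)][1])

  mutPath <- file.path(dir, "mutations.tsv")
  mut <- NULL
  if (file.exists(mutPath)) {
    mut <- .readTsv(mutPath)
    for (col in .MUTATION_COLS) mut[[col]] <- as.integer(mut[[col]])
  }

  methPath <- file.path(dir, "methylation.tsv")
  meth <- NULL
  if (file.exists(methPath)) {
    meth <- .readTsv(methPath)
    markers <- c(promoterMarkers(), repeatMarkers())
    miss <- setdiff(markers, colnames(meth))
    if (length(miss))
      stop("methylation.tsv lacks markers: ", paste(miss, collapse = ", "))
    for (mk in markers) {
      v <- .numOrNA(meth[[mk]])
      out <- which(!is.na(v) & (v < 0 | v > 100))
      if (length(out))
        stop(sprintf("methylation value %s for %s out of [0, 100] (sample %s)",
                     meth[[mk]][out[1]], mk, meth$sample_id[out[1]]))
      meth[[mk]] <- v / 100  # file stores percent; fractions internally
    }
  }

  msPath <- file.path(dir, "microsatellites.tsv")
  ms <- if (file.exists(msPath)) .readTsv(msPath) else NULL

  # rows referring to samples absent from the accepted clinical table (for
  # instance because their clinical row was rejected) are dropped, not errors
  dropUnknown <- function(tab, what) {
    if (is.null(tab)) return(NULL)
    unknown <- !tab$sample_id %in% clin$sample_id
    if (any(unknown)) {
      message(sprintf("%s: dropping %d row(s) for sample(s) not in samples.tsv",
                      what, sum(unknown)))
      tab <- tab[!unknown, , drop = FALSE]
    }
    tab
  }
  mut <- dropUnknown(mut, "mutations.tsv")
  meth <- dropUnknown(meth, "methylation.tsv")
  ms <- dropUnknown(ms, "microsatellites.tsv")

  cnPath <- file.path(dir, "copynumber.tsv")
  cn <- NULL
  if (file.exists(cnPath)) {
    cnTab <- .readTsv(cnPath)
    if (colnames(cnTab)[1] != "gene_id")
      stop("copynumber.tsv must start with a gene_id column")
    cn <- as.matrix(vapply(cnTab[-1], .numOrNA, numeric(nrow(cnTab))))
    if (nrow(cnTab) == 1L) cn <- matrix(cn, nrow = 1, dimnames = list(NULL, colnames(cnTab)[-1]))
    rownames(cn) <- cnTab$gene_id
  }

  HccCohort(clin, mutations = mut, methylation = meth, microsatellites = ms,
            copyNumber = cn, cnValueKind = cnValueKind,
            provenance = paste("read from", dir))
}

#' Write a cohort to a directory of TSV files
#'
#' Inverse of \code{\link{readCohort}}: emits \code{samples.tsv},
#' \code{mutations.tsv} (0/1 flags), \code{methylation.tsv} (fractions
#' multiplied by 100 to percent on write), \code{microsatellites.tsv} and,
#' when a copy-number matrix is attached, \code{copynumber.tsv}. Reading the
#' directory back yields an identical cohort.
#'
#' @param cohort an \linkS4class{HccCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clin <- clinicalData(cohort)
  .writeTsv(clin, file.path(dir, "samples.tsv"))

  mut <- mutationCalls(cohort)
  for (col in .MUTATION_COLS) mut[[col]] <- as.integer(mut[[col]])
  .writeTsv(mut, file.path(dir, "mutations.tsv"))

  markers <- c(promoterMarkers(), repeatMarkers())
  meth <- t(assay(cohort, "methylation")) * 100
  methDf <- data.frame(sample_id = sampleIDs(cohort),
                       as.data.frame(meth), check.names = FALSE)
  .writeTsv(methDf, file.path(dir, "methylation.tsv"))

  ms <- microsatellites(cohort)
  ms$informative <- as.integer(ms$informative)
  ms$imbalance <- as.integer(ms$imbalance)
  .writeTsv(ms, file.path(dir, "microsatellites.tsv"))

  cn <- copyNumber(cohort)
  if (ncol(cn)) {
    cnDf <- data.frame(gene_id = rownames(cn), as.data.frame(cn),
                       check.names = FALSE)
    .writeTsv(cnDf, file.path(dir, "copynumber.tsv"))
  }
  invisible(dir)
}

#' Write / read the per-sample molecular feature table
#'
#' Deterministic column order \code{sample_id, ctnnb1_mut, tp53_mut,
#' tertp_mut, tsg_hyper, global_hypo, fal_high, fal_percent}; boolean flags
#' serialized as 0/1 and the fractional-allelic-loss percentage with one
#' decimal.
#'
#' @param features data.frame as returned by \code{\link{callFeatures}}.
#' @param path output (input) TSV path.
#' @return \code{writeFeatureTable}: \code{path} invisibly;
#'   \code{readFeatureTable}: the feature data.frame.
#' @export
writeFeatureTable <- function(features, path) {
  cols <- c("sample_id", .MUTATION_COLS, "tsg_hyper", "global_hypo",
            "fal_high", "fal_percent")
  miss <- setdiff(cols, colnames(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  out <- features[, cols, drop = FALSE]
  for (col in cols[2:7]) out[[col]] <- as.integer(out[[col]])
  out$fal_percent <- ifelse(is.na(out$fal_percent), "",
                            sprintf("%.1f", out$fal_percent))
  .writeTsv(out, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- .readTsv(path)
  for (col in c(.MUTATION_COLS, "tsg_hyper", "global_hypo", "fal_high"))
    tab[[col]] <- as.integer(tab[[col]]) > 0
  tab$fal_percent <- .numOrNA(tab$fal_percent)
  tab
}

#' Persist a Z-score calibration as YAML
#'
#' @param calib a \linkS4class{ZScoreCalibration}.
#' @param path YAML file path.
#' @return \code{writeCalibration}: \code{path} invisibly;
#'   \code{readCalibration}: the calibration object.
#' @export
writeCalibration <- function(calib, path) {
  yaml::write_yaml(list(mean = calib@mean, sd = calib@sd,
                        threshold = calib@threshold), path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  y <- yaml::read_yaml(path)
  ZScoreCalibration(y$mean, y$sd, y$threshold)
}
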