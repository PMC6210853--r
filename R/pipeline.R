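.configHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(x)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full molecular risk pipeline
#'
#' Orchestrates the stages end to end and writes every intermediate table to
#' \code{outDir}: simulate (or read) the cohort, call the six features,
#' subclassify by correspondence analysis + clustering, compute the risk
#' score, run the feature-covariate association scan, and compare
#' recurrence-free survival between the aggressive and mild patterns by
#' Kaplan-Meier / log-rank. A \code{manifest.tsv} records per-stage row
#' counts and the configuration hash; outputs are deterministic given the
#' same inputs and configuration, and no stage mutates its inputs.
#'
#' @param outDir output directory.
#' @param config a \code{\link{generatorConfig}} (the cohort is simulated),
#'   or \code{NULL} when \code{inputDir} is given.
#' @param inputDir optional directory of cohort TSVs to analyze instead of
#'   simulating.
#' @param mode risk-score mode.
#' @return invisibly, a list with \code{features}, \code{subclasses},
#'   \code{scores}, \code{associations}, \code{survival} (the log-rank
#'   result) and \code{manifest}.
#' @export
runPipeline <- function(outDir, config = generatorConfig(),
                        inputDir = NULL, mode = "four_factor") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(inputDir)) {
    gen <- generateCohort(config)
    cohort <- gen$cohort
    cohortDir <- file.path(outDir, "cohort")
    writeCohort(cohort, cohortDir)
    .writeTsv(gen$truth, file.path(outDir, "ground_truth.tsv"))
  } else {
    cohort <- readCohort(inputDir)
  }

  features <- callFeatures(cohort)
  writeFeatureTable(features, file.path(outDir, "feature_table.tsv"))

  subclasses <- subclassify(features)
  sub <- subclasses
  sub$axis1 <- sprintf("%.6f", sub$axis1)
  sub$axis2 <- sprintf("%.6f", sub$axis2)
  .writeTsv(sub, file.path(outDir, "subclasses.tsv"))

  scores <- suppressMessages(scoreCohort(features, mode = mode))
  .writeTsv(scores, file.path(outDir, "scores.tsv"))

  assoc <- suppressWarnings(associationScan(cohort, features))
  assocOut <- assoc
  assocOut$statistic <- sprintf("%.6f", assocOut$statistic)
  assocOut$p_value <- sprintf("%.6g", assocOut$p_value)
  .writeTsv(assocOut, file.path(outDir, "associations.tsv"))

  cl <- clinicalData(cohort)
  agg <- scores$pattern == "aggressive"
  lr <- NULL
  if (any(agg) && any(!agg) && sum(cl$recurrence_event, na.rm = TRUE) > 0) {
    lr <- logrankTest(cl$rfs_months[agg], cl$recurrence_event[agg],
                      cl$rfs_months[!agg], cl$recurrence_event[!agg])
    kmA <- kmEstimate(cl$rfs_months[agg], cl$recurrence_event[agg])
    kmM <- kmEstimate(cl$rfs_months[!agg], cl$recurrence_event[!agg])
    km <- rbind(cbind(group = "aggressive", kmA),
                cbind(group = "mild", kmM))
    km$survival <- sprintf("%.6f", km$survival)
    .writeTsv(km, file.path(outDir, "km.tsv"))
  }

  manifest <- data.frame(
    stage = c("cohort", "features", "subclasses", "scores", "associations"),
    rows = c(length(sampleIDs(cohort)), nrow(features), nrow(subclasses),
             nrow(scores), nrow(assoc)),
    config_hash = .configHash(config),
    package_version = as.character(utils::packageVersion("HCCrisk")))
  .writeTsv(manifest, file.path(outDir, "manifest.tsv"))

  invisible(list(cohort = cohort, features = features,
                 subclasses = subclasses, scores = scores,
                 associations = assoc, survival = lr, manifest = manifest))
}
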