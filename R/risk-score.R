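#' Molecular risk score of a single tumor
#'
#' Counts the molecular risk factors: absence of CTNNB1 mutation, presence of
#' TP53 mutation, high FAL, and (four-factor mode only) global
#' hypomethylation. TERT-promoter mutation and TSG-promoter hypermethylation
#' never contribute — they are common to hepatocarcinogenesis rather than
#' markers of the aggressive phenotype. The pattern is \code{"aggressive"}
#' when the count reaches 3 of 4 (four-factor mode) or 2 of 3 (three-factor
#' mode, the variant used when repeat-element methylation is unavailable and
#' the copy-number alteration fraction stands in for FAL), otherwise
#' \code{"mild"}.
#'
#' @param ctnnb1Mut,tp53Mut,falHigh,globalHypo logical flags;
#'   \code{globalHypo} may be \code{NA} only in three-factor mode.
#' @param mode \code{"four_factor"} or \code{"three_factor"}.
#' @return list with \code{factors} (character subset of
#'   \code{ctnnb1_wildtype, tp53_mutant, fal_high, global_hypo}),
#'   \code{count} and \code{pattern}.
#' @examples
#' computeRiskScore(FALSE, TRUE, TRUE, TRUE)$pattern   # aggressive (4/4)
#' computeRiskScore(TRUE, FALSE, FALSE, FALSE)$count   # 0
#' @export
computeRiskScore <- function(ctnnb1Mut, tp53Mut, falHigh, globalHypo = NA,
                             mode = c("four_factor", "three_factor")) {
  mode <- match.arg(mode)
  if (mode == "four_factor" && is.na(globalHypo))
    stop("four-factor mode requires a defined global hypomethylation call")
  if (anyNA(c(ctnnb1Mut, tp53Mut, falHigh)))
    stop("undefined risk-factor flag")
  factors <- c(if (!ctnnb1Mut) "ctnnb1_wildtype",
               if (tp53Mut) "tp53_mutant",
               if (falHigh) "fal_high",
               if (mode == "four_factor" && isTRUE(globalHypo)) "global_hypo")
  count <- length(factors)
  cut <- if (mode == "four_factor") 3L else 2L
  list(mode = mode, factors = factors, count = count,
       pattern = if (count >= cut) "aggressive" else "mild")
}

#' Score a whole cohort
#'
#' Applies \code{\link{computeRiskScore}} per sample and logs the pattern
#' counts.
#'
#' @param features feature data.frame from \code{\link{callFeatures}} (or the
#'   TCGA-mode variant with the copy-number-derived \code{fal_high}).
#' @param mode \code{"four_factor"} or \code{"three_factor"}.
#' @param falSource provenance note recorded in the output
#'   (\code{"microsatellite"} or \code{"copy_number"}).
#' @return data.frame with \code{sample_id}, \code{risk_count},
#'   \code{pattern} (factor aggressive/mild) and \code{fal_source}.
#' @export
scoreCohort <- function(features, mode = c("four_factor", "three_factor"),
                        falSource = "microsatellite") {
  mode <- match.arg(mode)
  n <- nrow(features)
  counts <- integer(n)
  patterns <- character(n)
  for (i in seq_len(n)) {
    rs <- tryCatch(
      computeRiskScore(features$ctnnb1_mut[i], features$tp53_mut[i],
                       features$fal_high[i],
                       if ("global_hypo" %in% colnames(features))
                         features$global_hypo[i] else NA,
                       mode = mode),
      error = function(e) stop(sprintf("sample %s: %s",
                                       features$sample_id[i],
                                       conditionMessage(e)), call. = FALSE))
    counts[i] <- rs$count
    patterns[i] <- rs$pattern
  }
  out <- data.frame(sample_id = features$sample_id, risk_count = counts,
                    pattern = factor(patterns, levels = c("aggressive", "mild")),
                    fal_source = rep(falSource, n), row.names = NULL)
  if (n)
    message(sprintf("scoreCohort (%s): %d aggressive, %d mild", mode,
                    sum(out$pattern == "aggressive"),
                    sum(out$pattern == "mild")))
  out
}
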