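.SUBCLASSES <- c("A1", "A2", "B1", "B2")

.defaultEventPrevalence <- function() {
  # per-subclass prevalence of the six events in the 125-tumor resection cohort
  m <- rbind(
    ctnnb1_mut  = c(1, 0, 13, 17) / c(27, 21, 41, 36),
    tp53_mut    = c(3, 0, 23, 1) / c(27, 21, 41, 36),
    tertp_mut   = c(5, 15, 31, 34) / c(27, 21, 41, 36),
    tsg_hyper   = c(6, 2, 39, 34) / c(27, 21, 41, 36),
    global_hypo = c(16, 2, 38, 11) / c(27, 21, 41, 36),
    fal_high    = c(19, 3, 37, 8) / c(27, 21, 41, 36))
  colnames(m) <- .SUBCLASSES
  m
}

.defaultCovariatePrevalence <- function() {
  m <- rbind(
    male      = c(20, 12, 30, 28) / c(27, 21, 41, 36),
    age_gt60  = c(11, 14, 20, 21) / c(27, 21, 41, 36),
    hbsag_pos = c(10, 2, 12, 5) / c(27, 21, 41, 36),
    hcv_pos   = c(10, 15, 25, 27) / c(27, 21, 41, 36),
    afp_high  = c(14, 4, 23, 5) / c(27, 21, 41, 36),
    vascular  = c(17, 5, 25, 11) / c(27, 21, 41, 36),
    multiple  = c(14, 10, 19, 15) / c(27, 21, 41, 36),
    mod_poor  = c(22, 12, 31, 21) / c(27, 21, 41, 36))
  colnames(m) <- .SUBCLASSES
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions of the 125-tumor resection cohort:
#' subclass proportions 21.6/16.8/32.8/28.8\%, subclass-conditional
#' prevalences of the six molecular events and the clinical covariates taken
#' from the published subclass profiles, Beta-distributed methylation levels
#' centered near the printed per-marker medians (hyper/normal promoter
#' components shifted +/- 0.18 around each median; hypo/normal repeat
#' components +/- 0.15), a 400-locus microsatellite panel at 35\%
#' informativeness with per-sample target FAL drawn from Beta components
#' with means 10\% / 35\%, and an exponential recurrence model whose hazard
#' scales with the true risk-factor count (hazard ratio 2.2 per factor,
#' uniform censoring over 0-106 months).
#'
#' @param n number of samples.
#' @param seed integer RNG seed; per-sample substreams are derived from it so
#'   sample i's draws are stable when n changes.
#' @param subclassProportions 4 probabilities summing to 1 (A1, A2, B1, B2).
#' @param eventPrevalence 6 x 4 matrix of per-subclass event probabilities.
#' @param covariatePrevalence 8 x 4 matrix of per-subclass covariate
#'   probabilities.
#' @param promoterMedians,repeatMedians per-marker central methylation
#'   fractions the Beta components straddle.
#' @param promoterShift,repeatShift half-distance between the two component
#'   means.
#' @param promoterKappa,repeatKappa Beta concentration (a + b).
#' @param panelSize,informativeRate microsatellite panel.
#' @param falMeans,falKappa Beta components for the per-sample target FAL
#'   (fractions), low/high.
#' @param baselineHazard exponential recurrence hazard per month at risk
#'   count 0.
#' @param hazardRatio multiplicative hazard per risk factor.
#' @param censorMax upper bound of the uniform censoring window (months).
#' @return validated config list of class \code{"hccGeneratorConfig"}.
#' @export
generatorConfig <- function(n = 125, seed = 1,
                            subclassProportions = c(0.216, 0.168, 0.328, 0.288),
                            eventPrevalence = .defaultEventPrevalence(),
                            covariatePrevalence = .defaultCovariatePrevalence(),
                            promoterMedians = c(APC = 0.52, CDKN2A = 0.23,
                                                RASSF1A = 0.39, HIC1 = 0.297,
                                                GSTP1 = 0.42, RUNX3 = 0.09,
                                                SOCS1 = 0.384, PRDM2 = 0.139),
                            repeatMedians = c(Alu = 0.318, LINE1 = 0.28,
                                              SAT2 = 0.349),
                            promoterShift = 0.18, repeatShift = 0.15,
                            promoterKappa = 40, repeatKappa = 50,
                            panelSize = 400, informativeRate = 0.35,
                            falMeans = c(low = 0.10, high = 0.35),
                            falKappa = 100,
                            baselineHazard = 0.004, hazardRatio = 2.2,
                            censorMax = 106) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              subclassProportions = subclassProportions,
              eventPrevalence = eventPrevalence,
              covariatePrevalence = covariatePrevalence,
              promoterMedians = promoterMedians,
              repeatMedians = repeatMedians,
              promoterShift = promoterShift, repeatShift = repeatShift,
              promoterKappa = promoterKappa, repeatKappa = repeatKappa,
              panelSize = as.integer(panelSize),
              informativeRate = informativeRate,
              falMeans = falMeans, falKappa = falKappa,
              baselineHazard = baselineHazard, hazardRatio = hazardRatio,
              censorMax = censorMax)
  if (cfg$n < 0) stop("n must be >= 0")
  if (abs(sum(cfg$subclassProportions) - 1) > 1e-8)
    stop("subclass proportions must sum to 1")
  probs <- c(cfg$subclassProportions, cfg$eventPrevalence,
             cfg$covariatePrevalence, cfg$informativeRate, cfg$falMeans)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$hazardRatio <= 0) stop("hazard ratio must be > 0")
  if (cfg$baselineHazard <= 0) stop("baseline hazard must be > 0")
  class(cfg) <- "hccGeneratorConfig"
  cfg
}

.sampleSeed <- function(seed, i) (seed + i * 2654435761) %% 2147483647

.rbetaMean <- function(k, mean, kappa) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  stats::rbeta(k, mean * kappa, (1 - mean) * kappa)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws, per sample: a subclass; the six binary events and clinical
#' covariates from subclass-conditional Bernoullis; 8 promoter and 3
#' repetitive-element methylation levels from the Beta component selected by
#' the sample's true hypermethylation / hypomethylation state; a
#' microsatellite panel whose informative loci are imbalanced with the
#' sample's target-FAL probability (drawn from the high or low Beta
#' component according to the true \code{fal_high}); and a recurrence time
#' from an exponential whose hazard is
#' \code{baselineHazard * hazardRatio^riskCount}, censored uniformly. Event
#' draws are conditionally independent given the subclass.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{cohort} (an \linkS4class{HccCohort}) and
#'   \code{truth} (data.frame of per-sample true subclass, events, target FAL
#'   and risk count).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "hccGeneratorConfig"))
  n <- config$n
  ev <- config$eventPrevalence
  cv <- config$covariatePrevalence
  promMeans <- rbind(hyper = pmin(config$promoterMedians + config$promoterShift, 0.95),
                     normal = pmax(config$promoterMedians - config$promoterShift, 0.04))
  repMeans <- rbind(normal = pmin(config$repeatMedians + config$repeatShift, 0.95),
                    hypo = pmax(config$repeatMedians - config$repeatShift, 0.04))

  ids <- sprintf("S%04d", seq_len(n))
  subcl <- character(n)
  events <- matrix(NA, n, nrow(ev), dimnames = list(NULL, rownames(ev)))
  covs <- matrix(NA, n, nrow(cv), dimnames = list(NULL, rownames(cv)))
  age <- afp <- size <- rfs <- targetFal <- numeric(n)
  recEvent <- riskCount <- integer(n)
  methMat <- matrix(NA_real_, n, 11,
                    dimnames = list(NULL, c(promoterMarkers(), repeatMarkers())))
  msInformative <- msImbalance <- matrix(FALSE, n, config$panelSize)

  for (i in seq_len(n)) {
    set.seed(.sampleSeed(config$seed, i))
    sub <- sample(.SUBCLASSES, 1, prob = config$subclassProportions)
    subcl[i] <- sub
    e <- stats::rbinom(nrow(ev), 1, ev[, sub]) == 1
    names(e) <- rownames(ev)
    events[i, ] <- e
    cvd <- stats::rbinom(nrow(cv), 1, cv[, sub]) == 1
    names(cvd) <- rownames(cv)
    covs[i, ] <- cvd

    age[i] <- round(if (cvd["age_gt60"]) stats::runif(1, 61, 84)
                    else stats::runif(1, 35, 60))
    afp[i] <- if (cvd["afp_high"]) max(200, exp(stats::rnorm(1, log(1500), 1)))
              else min(199, exp(stats::rnorm(1, log(20), 1.2)))
    size[i] <- round(exp(stats::rnorm(1, log(3.6), 0.45)), 1)

    riskCount[i] <- sum(!e["ctnnb1_mut"], e["tp53_mut"], e["fal_high"],
                        e["global_hypo"])
    hazard <- config$baselineHazard * config$hazardRatio^riskCount[i]
    evTime <- stats::rexp(1, hazard)
    cens <- stats::runif(1, 0, config$censorMax)
    rfs[i] <- round(min(evTime, cens), 2)
    recEvent[i] <- as.integer(evTime <= cens)

    promRow <- if (e[["tsg_hyper"]]) promMeans["hyper", ] else promMeans["normal", ]
    prom <- vapply(seq_along(promRow), function(j)
      .rbetaMean(1, promRow[j], config$promoterKappa), numeric(1))
    repRow <- if (e[["global_hypo"]]) repMeans["hypo", ] else repMeans["normal", ]
    reps <- vapply(seq_along(repRow), function(j)
      .rbetaMean(1, repRow[j], config$repeatKappa), numeric(1))
    methMat[i, ] <- round(c(prom, reps), 4)

    targetFal[i] <- .rbetaMean(1, config$falMeans[[if (e[["fal_high"]]) "high" else "low"]],
                               config$falKappa)
    informative <- stats::rbinom(config$panelSize, 1, config$informativeRate) == 1
    msInformative[i, ] <- informative
    msImbalance[i, ] <- informative &
      (stats::rbinom(config$panelSize, 1, targetFal[i]) == 1)
  }

  if (n == 0) {
    cohort <- HccCohort(
      clinical = stats::setNames(
        as.data.frame(matrix(character(), 0, length(.CLINICAL_COLS))),
        .CLINICAL_COLS),
      provenance = "synthetic (empty)")
    truthDf <- data.frame(sample_id = character(), subclass = character(),
                          ctnnb1_mut = logical(), tp53_mut = logical(),
                          tertp_mut = logical(), tsg_hyper = logical(),
                          global_hypo = logical(), fal_high = logical(),
                          target_fal = numeric(), risk_count = integer())
    return(list(cohort = cohort, truth = truthDf))
  }

  clin <- data.frame(
    sample_id = ids,
    sex = ifelse(covs[, "male"], "male", "female"),
    age_years = age,
    hbsag = ifelse(covs[, "hbsag_pos"], "positive", "negative"),
    hcvab = ifelse(covs[, "hcv_pos"], "positive", "negative"),
    afp_ng_ml = round(afp, 1),
    tumor_size_cm = size,
    vascular_invasion = ifelse(covs[, "vascular"], "presence", "absence"),
    tumor_number = ifelse(covs[, "multiple"], "multiple", "solitary"),
    differentiation = ifelse(covs[, "mod_poor"], "moderately_poorly", "well"),
    treatment = "resection",
    rfs_months = rfs,
    recurrence_event = recEvent)
  mut <- data.frame(sample_id = ids,
                    ctnnb1_mut = events[, "ctnnb1_mut"],
                    tp53_mut = events[, "tp53_mut"],
                    tertp_mut = events[, "tertp_mut"])
  meth <- data.frame(sample_id = ids, as.data.frame(methMat),
                     check.names = FALSE)
  ms <- data.frame(
    sample_id = rep(ids, each = config$panelSize),
    locus_id = rep(sprintf("D%03d", seq_len(config$panelSize)), n),
    informative = as.vector(t(msInformative)),
    imbalance = as.vector(t(msImbalance)))
  truth <- data.frame(sample_id = ids, subclass = subcl,
                      as.data.frame(events), target_fal = 100 * targetFal,
                      risk_count = riskCount)
  cohort <- HccCohort(
    clinical = clin, mutations = mut, methylation = meth,
    microsatellites = ms,
    provenance = sprintf("synthetic cohort (n = %d, seed = %d)", n, config$seed))
  list(cohort = cohort, truth = truth)
}

#' Generate a TCGA-style fixture: copy-number matrix, MAF subset, survival
#'
#' Emulates the three-factor validation inputs: per sample, the altered-gene
#' fraction is drawn from a two-component Beta mixture (default means 20\%
#' and 55\%, bracketing the 39\% binarization cut), altered genes get a
#' thresholded state in \{-2, -1, 1, 2\}; a MAF subset consistent with the
#' drawn CTNNB1/TP53/TERT flags is emitted; recurrence times follow the same
#' exponential-hazard model on the three-factor risk count.
#'
#' @param n samples.
#' @param seed RNG seed.
#' @param geneCount genes in the matrix (a scaled-down stand-in for genome
#'   wide coverage).
#' @param mixtureMeans low/high altered-fraction component means (fractions).
#' @param mixtureKappa Beta concentration.
#' @param highFraction probability of the high component.
#' @param mutPrev named prevalences for \code{ctnnb1}, \code{tp53},
#'   \code{tert}.
#' @param baselineHazard,hazardRatio,censorMax survival model (see
#'   \code{\link{generatorConfig}}).
#' @return list with \code{copyNumber} (gene x sample matrix), \code{maf}
#'   (data.frame), \code{survival} (data.frame with \code{sample_id,
#'   rfs_months, recurrence_event}) and \code{truth} (per-sample flags,
#'   altered fraction, component, risk count).
#' @export
generateTcgaFixture <- function(n = 168, seed = 1, geneCount = 1000,
                                mixtureMeans = c(low = 0.20, high = 0.55),
                                mixtureKappa = 150, highFraction = 0.5,
                                mutPrev = c(ctnnb1 = 0.26, tp53 = 0.31,
                                            tert = 0.44),
                                baselineHazard = 0.006, hazardRatio = 2.2,
                                censorMax = 90) {
  if (geneCount < 1) stop("geneCount must be >= 1")
  if (any(c(mixtureMeans, highFraction, mutPrev) < 0) ||
      any(c(mixtureMeans, highFraction, mutPrev) > 1))
    stop("probabilities must lie in [0, 1]")
  genes <- sprintf("G%05d", seq_len(geneCount))
  cn <- matrix(0, geneCount, n,
               dimnames = list(genes, sprintf("TCGA%04d", seq_len(n))))
  mafRows <- list()
  surv <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.sampleSeed(seed, i))
    id <- colnames(cn)[i]
    high <- stats::runif(1) < highFraction
    frac <- .rbetaMean(1, mixtureMeans[[if (high) "high" else "low"]],
                       mixtureKappa)
    altered <- stats::rbinom(geneCount, 1, frac) == 1
    cn[altered, i] <- sample(c(-2, -1, 1, 2), sum(altered), replace = TRUE)
    ctnnb1 <- stats::runif(1) < mutPrev[["ctnnb1"]]
    tp53 <- stats::runif(1) < mutPrev[["tp53"]]
    tert <- stats::runif(1) < mutPrev[["tert"]]
    if (ctnnb1)
      mafRows[[length(mafRows) + 1]] <- data.frame(
        Hugo_Symbol = "CTNNB1", Variant_Classification = "Missense_Mutation",
        Tumor_Sample_Barcode = id, Chromosome = "3", Start_Position = 41224610)
    if (tp53)
      mafRows[[length(mafRows) + 1]] <- data.frame(
        Hugo_Symbol = "TP53", Variant_Classification = "Missense_Mutation",
        Tumor_Sample_Barcode = id, Chromosome = "17", Start_Position = 7675088)
    if (tert)
      mafRows[[length(mafRows) + 1]] <- data.frame(
        Hugo_Symbol = "TERT", Variant_Classification = "5'Flank",
        Tumor_Sample_Barcode = id, Chromosome = "5", Start_Position = 1295113)
    riskCount <- sum(!ctnnb1, tp53, 100 * sum(altered) / geneCount >= 39)
    hazard <- baselineHazard * hazardRatio^riskCount
    evTime <- stats::rexp(1, hazard)
    cens <- stats::runif(1, 0, censorMax)
    surv[[i]] <- data.frame(sample_id = id,
                            rfs_months = round(min(evTime, cens), 2),
                            recurrence_event = as.integer(evTime <= cens))
    truth[[i]] <- data.frame(sample_id = id, ctnnb1_mut = ctnnb1,
                             tp53_mut = tp53, tertp_mut = tert,
                             high_component = high,
                             altered_fraction = 100 * sum(altered) / geneCount,
                             risk_count = riskCount)
  }
  maf <- if (length(mafRows)) do.call(rbind, mafRows) else
    data.frame(Hugo_Symbol = character(), Variant_Classification = character(),
               Tumor_Sample_Barcode = character(), Chromosome = character(),
               Start_Position = numeric())
  list(copyNumber = cn, maf = maf,
       survival = do.call(rbind, surv), truth = do.call(rbind, truth))
}
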