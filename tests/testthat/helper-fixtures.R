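# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdirs

tinyClinical <- function(ids) {
  n <- length(ids)
  data.frame(sample_id = ids,
             sex = rep(c("male", "female"), length.out = n),
             age_years = seq(50, by = 3, length.out = n),
             hbsag = rep("negative", n),
             hcvab = rep(c("positive", "negative"), length.out = n),
             afp_ng_ml = seq(10, by = 150, length.out = n),
             tumor_size_cm = rep(3.6, n),
             vascular_invasion = rep(c("presence", "absence"), length.out = n),
             tumor_number = rep("solitary", n),
             differentiation = rep(c("well", "moderately_poorly"), length.out = n),
             treatment = rep("resection", n),
             rfs_months = seq(12, by = 6, length.out = n),
             recurrence_event = rep(c(1, 0), length.out = n))
}

tinyMethylation <- function(ids, level = 0.4) {
  m <- data.frame(sample_id = ids)
  for (mk in c(promoterMarkers(), repeatMarkers())) m[[mk]] <- level
  m
}

tinyMutations <- function(ids) {
  data.frame(sample_id = ids,
             ctnnb1_mut = rep(c(TRUE, FALSE), length.out = length(ids)),
             tp53_mut = rep(FALSE, length(ids)),
             tertp_mut = rep(TRUE, length(ids)))
}

# the published per-subclass event counts, rebuilt independently of the
# generator's own defaults
.defaultEventPrevalenceForTest <- function() {
  n <- c(27, 21, 41, 36)
  rbind(ctnnb1_mut = c(1, 0, 13, 17) / n,
        tp53_mut = c(3, 0, 23, 1) / n,
        tertp_mut = c(5, 15, 31, 34) / n,
        tsg_hyper = c(6, 2, 39, 34) / n,
        global_hypo = c(16, 2, 38, 11) / n,
        fal_high = c(19, 3, 37, 8) / n)
}

# features table with exact per-cluster prevalences (counts out of size)
featuresWithPrevalence <- function(sizes, hyperCounts, falCounts) {
  rows <- list()
  k <- 0
  for (g in seq_along(sizes)) {
    n <- sizes[g]
    rows[[g]] <- data.frame(
      sample_id = sprintf("C%d_%03d", g, seq_len(n)),
      ctnnb1_mut = FALSE, tp53_mut = FALSE, tertp_mut = FALSE,
      tsg_hyper = seq_len(n) <= hyperCounts[g],
      global_hypo = FALSE,
      fal_high = seq_len(n) <= falCounts[g])
  }
  do.call(rbind, rows)
}
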