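.NONSYNONYMOUS <- c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
                    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                    "In_Frame_Ins", "Splice_Site", "Translation_Start_Site")
.SILENT_LIKE <- c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
                  "IGR", "RNA")
.TERT_PROMOTER_CLASSES <- c("5'Flank", "5'UTR", "Upstream", "Promoter")

.inRegion <- function(chrom, pos, region) {
  !is.na(pos) & sub("^chr", "", as.character(chrom)) ==
    sub("^chr", "", region$chrom) & pos >= region$start & pos <= region$end
}

#' Derive the three mutation flags from a MAF-subset file
#'
#' Reads a tab-separated MAF subset (columns \code{Hugo_Symbol},
#' \code{Variant_Classification}, \code{Tumor_Sample_Barcode}; optionally
#' \code{Chromosome}/\code{Start_Position}) and derives per-sample calls:
#' \code{ctnnb1_mut} for a nonsynonymous CTNNB1 call, \code{tp53_mut} for a
#' nonsynonymous TP53 call, and \code{tertp_mut} for a TERT promoter-region
#' variant (classifications \code{5'Flank}/\code{5'UTR}/\code{Upstream}/
#' \code{Promoter}; the recurrent hotspots sit at -124 and -146 bp from the
#' ATG). When a \code{regions} entry is supplied and coordinates are present,
#' calls are additionally restricted to that genomic window (e.g. CTNNB1
#' exon 3, TP53 exons 5-8, the TERT promoter); without coordinates the filter
#' is gene-level.
#'
#' @param path MAF-subset TSV path.
#' @param sampleIds optional full sample list; samples without any qualifying
#'   call get \code{FALSE} flags.
#' @param regions optional named list (\code{ctnnb1}, \code{tp53},
#'   \code{tert}) of lists with \code{chrom}, \code{start}, \code{end}.
#' @return data.frame with \code{sample_id, ctnnb1_mut, tp53_mut, tertp_mut}.
#' @export
readMafMutations <- function(path, sampleIds = NULL, regions = NULL) {
  maf <- .readTsv(path)
  need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  miss <- setdiff(need, colnames(maf))
  if (length(miss))
    stop("MAF lacks mandatory columns: ", paste(miss, collapse = ", "))
  hasPos <- all(c("Chromosome", "Start_Position") %in% colnames(maf))
  pos <- if (hasPos) .numOrNA(maf$Start_Position) else rep(NA_real_, nrow(maf))

  known <- c(.NONSYNONYMOUS, .SILENT_LIKE, "Targeted_Region", "De_novo_Start_InFrame",
             "De_novo_Start_OutOfFrame")
  unk <- !maf$Variant_Classification %in% known
  if (any(unk))
    message(sprintf("readMafMutations: %d call(s) with unknown variant classification treated as non-calls (%s)",
                    sum(unk),
                    paste(unique(maf$Variant_Classification[unk]), collapse = ", ")))

  nonsyn <- maf$Variant_Classification %in% .NONSYNONYMOUS
  geneCall <- function(gene, classes, region) {
    hit <- maf$Hugo_Symbol == gene & classes
    if (!is.null(region) && hasPos) {
      withPos <- hit & !is.na(pos)
      hit[withPos] <- .inRegion(maf$Chromosome[withPos], pos[withPos], region)
    }
    unique(maf$Tumor_Sample_Barcode[hit])
  }
  ctnnb1 <- geneCall("CTNNB1", nonsyn, regions$ctnnb1)
  tp53 <- geneCall("TP53", nonsyn, regions$tp53)
  tertCls <- maf$Variant_Classification %in% .TERT_PROMOTER_CLASSES
  tert <- geneCall("TERT", tertCls, regions$tert)

  ids <- if (is.null(sampleIds)) {
    sort(unique(maf$Tumor_Sample_Barcode))
  } else {
    as.character(sampleIds)
  }
  data.frame(sample_id = ids,
             ctnnb1_mut = ids %in% ctnnb1,
             tp53_mut = ids %in% tp53,
             tertp_mut = ids %in% tert,
             row.names = NULL)
}
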