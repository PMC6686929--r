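# Simplified gffcompare-style novelty classification: assembled transcripts
# are matched to a reference annotation by exact intron-chain equality
# (multi-exon) or exact exon interval (single-exon); otherwise any same-strand
# exonic overlap makes them "overlapping", else "intergenic".

tx_keys <- function(model) {
  chrom <- as.character(GenomicRanges::seqnames(model)[1])
  strand <- as.character(GenomicRanges::strand(model)[1])
  st <- sort(GenomicRanges::start(model))
  en <- sort(GenomicRanges::end(model))
  strands <- if (strand == "*") c("+", "-") else strand
  if (length(st) == 1) {
    paste(chrom, strands, st, en, sep = "|")
  } else {
    # intron chain: ordered donor/acceptor boundary coordinates
    chain <- paste(c(rbind(en[-length(en)], st[-1])), collapse = ",")
    paste(chrom, strands, chain, sep = "|")
  }
}

#' Classify assembled transcripts against a reference annotation
#'
#' A multi-exon transcript whose ordered intron chain (donor/acceptor
#' coordinates, same chromosome and strand) exactly equals a reference
#' transcript's is an \code{annotated_match}; a single-exon transcript
#' matching a reference single-exon interval exactly likewise. Any remaining
#' transcript with at least 1 bp of same-strand exonic overlap with the
#' reference is \code{overlapping}; the rest are \code{intergenic}.
#' Strand-unknown transcripts are compared against both strands.
#'
#' @param assembled,reference \code{GRangesList} transcript sets from
#'   \code{\link{read_annotation}}, in the same genome coordinates.
#' @return Data frame: \code{transcript_id}, \code{class} (factor with levels
#'   annotated_match, overlapping, intergenic).
#' @export
classify_vs_reference <- function(assembled, reference) {
  ids <- names(assembled)
  lv <- c("annotated_match", "overlapping", "intergenic")
  if (length(reference) == 0) {
    warning("empty reference annotation: all transcripts classified intergenic")
    return(data.frame(transcript_id = ids,
                      class = factor("intergenic", levels = lv)))
  }
  ref_keys <- unique(unlist(lapply(seq_along(reference), function(i)
    tx_keys(reference[[i]]))))
  ref_exons <- unlist(methods::as(reference, "GRangesList"), use.names = FALSE)
  cls <- character(length(assembled))
  for (i in seq_along(assembled)) {
    m <- assembled[[i]]
    if (any(tx_keys(m) %in% ref_keys)) {
      cls[i] <- "annotated_match"
      next
    }
    # strand "*" matches either strand under findOverlaps' strand rules;
    # a query chromosome absent from the reference is simply no overlap
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(m, ref_exons, minoverlap = 1L))
    cls[i] <- if (length(ov) > 0) "overlapping" else "intergenic"
  }
  data.frame(transcript_id = ids, class = factor(cls, levels = lv))
}

#' Novelty report for predicted lncRNAs
#'
#' Counts, among the lncRNA-flagged transcripts, those absent from the
#' reference annotation ("novel" = not \code{annotated_match}) and those in
#' intergenic space, as percentages of all predicted lncRNAs.
#'
#' @param classes Data frame from \code{\link{classify_vs_reference}}.
#' @param lnc_flags Named logical (or "lncRNA"/"other" character) vector keyed
#'   by transcript id.
#' @return One-row data frame: \code{total_lncrna}, \code{novel_lncrna},
#'   \code{pct_novel}, \code{pct_intergenic}. All zero when no lncRNAs.
#' @export
novelty_report <- function(classes, lnc_flags) {
  if (is.character(lnc_flags)) lnc_flags <- lnc_flags == "lncRNA"
  miss <- setdiff(names(lnc_flags)[lnc_flags], classes$transcript_id)
  if (length(miss))
    stop("lncRNA-flagged transcripts not classified: ",
         paste(utils::head(miss, 5), collapse = ", "))
  lnc <- classes[lnc_flags[classes$transcript_id] %in% TRUE, ]
  total <- nrow(lnc)
  if (total == 0)
    return(data.frame(total_lncrna = 0L, novel_lncrna = 0L,
                      pct_novel = 0, pct_intergenic = 0))
  novel <- sum(lnc$class != "annotated_match")
  interg <- sum(lnc$class == "intergenic")
  data.frame(total_lncrna = total, novel_lncrna = novel,
             pct_novel = 100 * novel / total,
             pct_intergenic = 100 * interg / total)
}
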