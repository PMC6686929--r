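# Molecular trait extraction: spliced transcript sequences from genome FASTA +
# GFF3/GTF exon models, the four traits used for phylogenetic signal analysis
# (spliced length, exon count, GC fraction, maximal ORF length), and
# per-species class-mean aggregation.

#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   reverseComplement alphabetFrequency subseq
#' @importFrom GenomicRanges GRanges seqnames strand start end width mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors split
NULL

#' Read transcript exon models from GFF3/GTF
#'
#' Imports an annotation file and returns one exon set per transcript as a
#' \code{GRangesList}. Exons are grouped by the GTF \code{transcript_id}
#' attribute or the GFF3 \code{Parent}, sorted by start, and validated to lie
#' on a single chromosome and strand.
#'
#' @param path GFF3 or GTF file (format detected by \code{rtracklayer} from
#'   the extension).
#' @return A \code{GRangesList}, one element per transcript, names =
#'   transcript ids.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) stop("no exon features found in ", path)
  mc <- GenomicRanges::mcols(gr)
  tx_id <- if ("transcript_id" %in% names(mc) && !all(is.na(mc$transcript_id))) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    par <- mc$Parent
    if (any(lengths(par) == 0)) {
      bad <- which(lengths(par) == 0)[1]
      stop("exon without transcript grouping (no Parent) at ",
           as.character(GenomicRanges::seqnames(gr)[bad]), ":",
           GenomicRanges::start(gr)[bad], "-", GenomicRanges::end(gr)[bad])
    }
    vapply(par, `[[`, character(1), 1L)
  } else {
    stop("exons carry neither transcript_id (GTF) nor Parent (GFF3) attributes")
  }
  models <- S4Vectors::split(gr, tx_id)
  models <- methods::as(models, "GRangesList")
  chroms <- unique(GenomicRanges::seqnames(models))
  strands <- unique(GenomicRanges::strand(models))
  multi_chrom <- names(models)[lengths(chroms) > 1]
  if (length(multi_chrom))
    stop("transcript(s) with exons on multiple chromosomes: ",
         paste(multi_chrom, collapse = ", "))
  multi_strand <- names(models)[lengths(strands) > 1]
  if (length(multi_strand))
    stop("transcript(s) with mixed strands: ",
         paste(multi_strand, collapse = ", "))
  sort(models)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon substrings of the genome in genomic order and
#' reverse-complements the whole if the transcript is on the minus strand,
#' returning the sense-strand sequence in uppercase.
#'
#' @param model A \code{GRanges} of one transcript's exons (one element of
#'   \code{\link{read_annotation}}'s result).
#' @param genome A named \code{DNAStringSet} (or named character vector).
#' @return A character string.
#' @export
spliced_sequence <- function(model, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom <- as.character(unique(GenomicRanges::seqnames(model)))
  if (length(chrom) != 1) stop("exons span multiple chromosomes")
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chrom_seq <- genome[[chrom]]
  st <- GenomicRanges::start(model); en <- GenomicRanges::end(model)
  o <- order(st)
  st <- st[o]; en <- en[o]
  if (any(st < 1) || any(en > length(chrom_seq)))
    stop("exon out of bounds on ", chrom, " (length ", length(chrom_seq),
         "): ", paste(st[st < 1 | en > length(chrom_seq)],
                      en[st < 1 | en > length(chrom_seq)],
                      sep = "-", collapse = ", "))
  pieces <- vapply(seq_along(st), function(i)
    as.character(Biostrings::subseq(chrom_seq, st[i], en[i])), character(1))
  s <- Biostrings::DNAString(paste(pieces, collapse = ""))
  strand <- as.character(unique(GenomicRanges::strand(model)))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' GC content of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T), case-insensitive; IUPAC ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param seq Character string or \code{DNAString}.
#' @return GC fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  if (!inherits(seq, "DNAString")) seq <- Biostrings::DNAString(toupper(as.character(seq)))
  f <- Biostrings::alphabetFrequency(seq)
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0) stop("no unambiguous bases in sequence")
  sum(f[c("G", "C")]) / denom
}

#' Length of the maximal open reading frame
#'
#' Longest ATG-initiated, in-frame, stop-terminated (TAA/TAG/TGA) reading
#' frame on the sense strand, scanned over the three forward frames. The
#' length is in nucleotides and includes the stop codon; 0 when no complete
#' ORF exists. Ties go to the 5'-most ORF (length is unaffected).
#'
#' @param seq Character string or \code{DNAString} (sense strand).
#' @return ORF length in nt (a multiple of 3), or 0.
#' @export
max_orf_length <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 6) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    k <- (n - frame) %/% 3
    if (k < 2) next
    codons <- substring(s, frame + 1 + 3 * (seq_len(k) - 1),
                        frame + 3 * seq_len(k))
    open <- NA_integer_  # earliest unclosed ATG (codon index)
    for (i in seq_len(k)) {
      if (codons[i] %in% stops) {
        if (!is.na(open)) {
          len <- (i - open + 1L) * 3L
          if (len > best) best <- len
          open <- NA_integer_
        }
      } else if (is.na(open) && codons[i] == "ATG") {
        open <- i
      }
    }
  }
  as.integer(best)
}

#' Four molecular traits of one transcript
#'
#' Computes the spliced length, exon count, GC fraction and maximal ORF length
#' of a transcript model on its sense strand.
#'
#' @param model A \code{GRanges} of one transcript's exons.
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param transcript_id Optional id for the output row.
#' @return One-row data frame: \code{transcript_id}, \code{length},
#'   \code{n_exons}, \code{gc}, \code{orf_len}.
#' @export
transcript_traits <- function(model, genome, transcript_id = NA_character_) {
  if (length(model) == 0) stop("transcript has no exons")
  s <- spliced_sequence(model, genome)
  data.frame(transcript_id = transcript_id,
             length = nchar(s),
             n_exons = length(model),
             gc = gc_content(s),
             orf_len = max_orf_length(s))
}

#' Trait table for a whole transcript set
#'
#' @param models A \code{GRangesList} from \code{\link{read_annotation}}.
#' @param genome Named \code{DNAStringSet} or character vector.
#' @return Data frame with one row per transcript.
#' @export
transcriptome_traits <- function(models, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  rows <- lapply(names(models), function(id)
    transcript_traits(models[[id]], genome, id))
  do.call(rbind, rows)
}

#' Per-species class means of the four traits
#'
#' Averages each trait over the transcripts of each species, separately for
#' the lncRNA and other classes, and appends the difference
#' (lncRNA mean - other mean) as a third class — the three tip-trait series
#' fed to the signal statistics.
#'
#' @param records Data frame with columns \code{species},
#'   \code{transcript_id}, \code{length}, \code{n_exons}, \code{gc},
#'   \code{orf_len}.
#' @param lnc_flags Named logical (or "lncRNA"/"other" character) vector keyed
#'   by transcript id: TRUE/"lncRNA" marks predicted lncRNAs.
#' @return Data frame: \code{species}, \code{class} in
#'   \{lncRNA, other, difference\}, \code{n}, \code{mean_length},
#'   \code{mean_exons}, \code{mean_gc}, \code{mean_orf}. Species lacking one
#'   class are dropped from that class and from \code{difference}, with a
#'   warning.
#' @export
aggregate_species_means <- function(records, lnc_flags) {
  need <- c("species", "transcript_id", "length", "n_exons", "gc", "orf_len")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("no transcript records")
  if (is.character(lnc_flags)) lnc_flags <- lnc_flags == "lncRNA"
  unflagged <- setdiff(records$transcript_id, names(lnc_flags))
  if (length(unflagged))
    stop("transcripts without an lncRNA flag: ",
         paste(utils::head(unflagged, 5), collapse = ", "),
         if (length(unflagged) > 5) " ...")
  records$class <- ifelse(lnc_flags[records$transcript_id], "lncRNA", "other")
  traits <- c(mean_length = "length", mean_exons = "n_exons",
              mean_gc = "gc", mean_orf = "orf_len")
  agg <- do.call(rbind, lapply(split(records, records[c("species", "class")],
                                     drop = TRUE), function(d) {
    out <- data.frame(species = d$species[1], class = d$class[1], n = nrow(d))
    for (nm in names(traits)) out[[nm]] <- mean(d[[traits[nm]]])
    out
  }))
  rownames(agg) <- NULL
  tab <- table(agg$species)
  incomplete <- names(tab)[tab < 2]
  if (length(incomplete))
    warning("species lacking one class, excluded from difference series: ",
            paste(incomplete, collapse = ", "))
  complete <- setdiff(unique(agg$species), incomplete)
  diffs <- do.call(rbind, lapply(complete, function(sp) {
    l <- agg[agg$species == sp & agg$class == "lncRNA", ]
    o <- agg[agg$species == sp & agg$class == "other", ]
    data.frame(species = sp, class = "difference", n = l$n + o$n,
               mean_length = l$mean_length - o$mean_length,
               mean_exons = l$mean_exons - o$mean_exons,
               mean_gc = l$mean_gc - o$mean_gc,
               mean_orf = l$mean_orf - o$mean_orf)
  }))
  out <- rbind(agg, diffs)
  out[order(out$species, out$class), , drop = FALSE]
}
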