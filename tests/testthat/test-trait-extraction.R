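write_lines_tmp <- function(lines, ext) {
  p <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("annotation readers group exons by transcript for GTF and GFF3", {
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\texon\t7\t9\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t1\t3\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";'),
    ".gtf")
  models <- read_annotation(gtf)
  expect_named(models, "t1")
  expect_length(models[["t1"]], 2)
  # out-of-order input comes back sorted by start
  expect_equal(GenomicRanges::start(models[["t1"]]), c(1, 7))

  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t9\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=mRNA1;Parent=gene1",
    "chr1\tsrc\texon\t1\t3\t.\t+\t.\tParent=mRNA1",
    "chr1\tsrc\texon\t7\t9\t.\t+\t.\tParent=mRNA1"), ".gff3")
  models <- read_annotation(gff)
  expect_named(models, "mRNA1")
  expect_length(models[["mRNA1"]], 2)

  mixed <- write_lines_tmp(c(
    'chr1\tsrc\texon\t1\t3\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t7\t9\t.\t-\t.\ttranscript_id "t1"; gene_id "g1";'),
    ".gtf")
  expect_error(read_annotation(mixed), "mixed strands")
})

test_that("spliced sequences concatenate exons and reverse-complement on minus strand", {
  genome <- c(chr1 = "AAACCCGGGTTT")
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 7), c(3, 9)),
                                 strand = "+")
  expect_equal(spliced_sequence(plus, genome), "AAAGGG")
  minus <- plus
  GenomicRanges::strand(minus) <- "-"
  expect_equal(spliced_sequence(minus, genome), "CCCTTT")

  set.seed(1)
  for (rep in 1:5) {
    s <- random_dna_seq(60)
    rc2 <- as.character(Biostrings::reverseComplement(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
    expect_equal(rc2, s)
  }

  oob <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 20), strand = "+")
  expect_error(spliced_sequence(oob, genome), "out of bounds")
  other <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 3), strand = "+")
  expect_error(spliced_sequence(other, genome), "chromosome not in genome")
})

test_that("GC content excludes ambiguity codes and is strand-symmetric", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_error(gc_content("NNNN"), "no unambiguous bases")
  set.seed(2)
  for (rep in 1:10) {
    s <- random_dna_seq(sample(10:200, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_content(s), gc_content(rc), tolerance = 1e-12)
  }
})

test_that("maximal ORF length matches the exhaustive enumeration oracle", {
  expect_equal(max_orf_length("ATGTAA"), 6L)
  expect_equal(max_orf_length("CCCCCC"), 0L)
  expect_equal(orf_oracle("ATGATGTGATAA"), 9L)  # ATG-ATG-TGA
  expect_equal(max_orf_length("ATGATGTGATAA"), 9L)

  set.seed(4)
  for (rep in 1:500) {
    s <- random_dna_seq(sample(6:150, 1))
    expect_equal(max_orf_length(s), orf_oracle(s))
  }
})

test_that("transcript traits compose the sub-operations", {
  genome <- c(chr1 = "AAACCCGGGTTT")
  model <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 7), c(3, 9)),
                                  strand = "+")
  tr <- transcript_traits(model, genome, "t1")
  expect_equal(tr$length, 6)
  expect_equal(tr$n_exons, 2)
  expect_equal(tr$gc, 0.5)
  expect_equal(tr$orf_len, 0)

  g2 <- c(chr1 = "ATGTAA")
  m2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6), strand = "+")
  tr2 <- transcript_traits(m2, g2)
  expect_equal(tr2$length, 6)
  expect_equal(tr2$n_exons, 1)
  expect_equal(tr2$orf_len, 6)

  empty <- GenomicRanges::GRanges()
  expect_error(transcript_traits(empty, genome), "no exons")

  # invariants on generated transcripts: length = sum of exon widths,
  # orf multiple of 3 and <= length
  cfg <- fixture_config(n_transcripts = 20)
  res <- generate_transcriptome(cfg, "spT", withr::local_tempdir(), seed = 9)
  genome <- Biostrings::readDNAStringSet(res$paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- read_annotation(res$paths$assembled)
  tt <- transcriptome_traits(models, genome)
  widths <- sum(GenomicRanges::width(models))
  expect_equal(tt$length, unname(widths[tt$transcript_id]))
  expect_true(all(tt$orf_len %% 3 == 0))
  expect_true(all(tt$orf_len <= tt$length))
})

test_that("species class means aggregate correctly and handle missing classes", {
  rec <- data.frame(
    species = "sp1",
    transcript_id = c("a", "b", "c"),
    length = c(100, 200, 300), n_exons = c(1, 1, 2),
    gc = c(0.3, 0.5, 0.6), orf_len = c(0, 30, 300))
  flags <- c(a = TRUE, b = TRUE, c = FALSE)
  agg <- aggregate_species_means(rec, flags)
  expect_equal(agg$mean_gc[agg$class == "lncRNA"], 0.4)
  expect_equal(agg$mean_gc[agg$class == "other"], 0.6)
  expect_equal(agg$mean_gc[agg$class == "difference"], -0.2)

  # permuting record order leaves means unchanged
  agg2 <- aggregate_species_means(rec[c(3, 1, 2), ], flags)
  expect_equal(agg2, agg)

  # a species with only lncRNAs drops out of other/difference with a warning
  rec$species <- c("sp1", "sp1", "sp2")
  flags2 <- c(a = TRUE, b = TRUE, c = TRUE)
  expect_warning(agg3 <- aggregate_species_means(rec, flags2),
                 "lacking one class")
  expect_false("difference" %in% agg3$class)

  expect_error(aggregate_species_means(rec, c(a = TRUE)), "without an lncRNA flag")
  expect_error(aggregate_species_means(rec[0, ], flags), "no transcript records")
})
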