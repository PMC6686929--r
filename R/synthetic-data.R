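# Seeded generators for study fixtures: pure-birth trees and per-species
# synthetic transcriptomes (genome FASTA + assembled GTF + reference GFF3 +
# lncRNA score TSV) whose class structure mimics the observed contrast
# between predicted lncRNAs and the remaining transcripts: lower GC, fewer
# exons, shorter ORFs.

#' Generate a pure-birth ultrametric tree scaled to unit depth
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate of the Yule process (default 1).
#' @param seed Optional RNG seed (same seed, same newick).
#' @return A \code{"phylo"} with tips \code{sp01, sp02, ...} and depth 1.
#' @export
generate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 3) stop("need at least 3 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  normalize_depth(tree, tol = 1e-6)
}

class_defaults <- function() list(
  lncRNA = list(gc_mean = 0.38, gc_sd = 0.05, exon_lambda = 0.3,
                len_meanlog = log(500), len_sdlog = 0.5, orf_mean = 90,
                score_shape1 = 20, score_shape2 = 4),
  other = list(gc_mean = 0.44, gc_sd = 0.05, exon_lambda = 4,
               len_meanlog = log(1500), len_sdlog = 0.5, orf_mean = 900,
               score_shape1 = 4, score_shape2 = 20))

#' Fixture configuration for the synthetic study
#'
#' Defaults emulate the study's structure at desk scale: a few percent of
#' transcripts are lncRNAs, whose GC, exon counts and ORF lengths sit below
#' those of the other transcripts; about half of all transcripts are withheld
#' from the reference annotation so novelty classification has work to do.
#'
#' @param n_transcripts Transcripts per species (default 200).
#' @param lnc_fraction Fraction of transcripts that are true lncRNAs
#'   (default 0.064, the study-wide mean percentage of predicted lncRNAs).
#' @param novel_fraction Fraction of transcripts withheld from the reference
#'   GFF3 (default 0.5).
#' @param lncRNA,other Per-class distribution parameters; partial lists are
#'   merged over the defaults: \code{gc_mean}/\code{gc_sd} (normal GC target),
#'   \code{exon_lambda} (exon count = 1 + Poisson), \code{len_meanlog}/
#'   \code{len_sdlog} (log-normal spliced length), \code{orf_mean} (gamma
#'   planted-ORF length, shape 4), \code{score_shape1}/\code{score_shape2}
#'   (Beta prediction-score noise).
#' @param intron_range,spacer_range Uniform bounds (nt) for intron lengths and
#'   intergenic spacers.
#' @param background_gc GC of intergenic/intronic sequence (default 0.36).
#' @return A validated list of class \code{"fixture_config"}.
#' @export
fixture_config <- function(n_transcripts = 200, lnc_fraction = 0.064,
                           novel_fraction = 0.5, lncRNA = list(),
                           other = list(), intron_range = c(50, 500),
                           spacer_range = c(200, 2000), background_gc = 0.36) {
  def <- class_defaults()
  cfg <- list(n_transcripts = n_transcripts, lnc_fraction = lnc_fraction,
              novel_fraction = novel_fraction,
              lncRNA = utils::modifyList(def$lncRNA, lncRNA),
              other = utils::modifyList(def$other, other),
              intron_range = intron_range, spacer_range = spacer_range,
              background_gc = background_gc)
  validate_fixture_config(cfg)
}

validate_fixture_config <- function(cfg) {
  if (cfg$n_transcripts < 2) stop("need at least 2 transcripts per species")
  for (f in c("lnc_fraction", "novel_fraction", "background_gc"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  for (cl in c("lncRNA", "other")) {
    p <- cfg[[cl]]
    if (p$gc_mean <= 0 || p$gc_mean >= 1) stop(cl, ": gc_mean outside (0, 1)")
    if (p$orf_mean >= exp(p$len_meanlog))
      stop(cl, ": infeasible config, mean planted ORF (", p$orf_mean,
           " nt) exceeds the typical transcript length (",
           round(exp(p$len_meanlog)), " nt)")
  }
  structure(cfg, class = "fixture_config")
}

#' Write / read a fixture configuration as YAML
#'
#' @param cfg A \code{"fixture_config"}.
#' @param path YAML file path.
#' @return \code{path} invisibly / the validated config.
#' @export
write_fixture_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_fixture_config
#' @export
read_fixture_config <- function(path) {
  validate_fixture_config(yaml::read_yaml(path))
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Internal codons drawn with per-base GC bias so the planted ORF tracks the
# transcript's GC target instead of pinning it near 50%.
orf_string <- function(orf_len, gc = 0.5) {
  stopifnot(orf_len %% 3 == 0, orf_len >= 6)
  n_mid <- orf_len / 3 - 2
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  n_gc <- vapply(strsplit(sense, ""), function(b) sum(b %in% c("G", "C")),
                 integer(1))
  w <- (gc / 2)^n_gc * ((1 - gc) / 2)^(3 - n_gc)
  paste0("ATG",
         if (n_mid > 0) paste(sample(sense, n_mid, replace = TRUE, prob = w),
                              collapse = "") else "",
         sample(STOP_CODONS, 1))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Build one spliced sense sequence of length L with a planted ORF of length O
# at a random position; non-ORF bases are Bernoulli draws tuned so the whole
# transcript hits the GC target in expectation.
build_transcript_seq <- function(len, orf_len, gc_target) {
  if (orf_len > 0) {
    orf <- orf_string(orf_len, gc = gc_target)
    gc_orf <- gc_content(orf)
    rest <- len - orf_len
    if (rest == 0) return(orf)
    g <- (gc_target * len - gc_orf * orf_len) / rest
    g <- min(max(g, 0.02), 0.98)
    pos <- sample.int(rest + 1, 1)  # ORF start offset
    paste0(random_dna(pos - 1, g), orf, random_dna(rest - pos + 1, g))
  } else {
    random_dna(len, gc_target)
  }
}

draw_class_traits <- function(p, n) {
  len <- pmax(200L, as.integer(round(stats::rlnorm(n, p$len_meanlog, p$len_sdlog))))
  orf <- as.integer(3 * round(stats::rgamma(n, shape = 4,
                                            scale = p$orf_mean / 4) / 3))
  orf[orf < 6] <- 0L
  len <- pmax(len, orf)
  n_exons <- 1L + stats::rpois(n, p$exon_lambda)
  gc <- pmin(pmax(stats::rnorm(n, p$gc_mean, p$gc_sd), 0.15), 0.85)
  score <- stats::rbeta(n, p$score_shape1, p$score_shape2)
  data.frame(length = len, orf_len = orf, n_exons = n_exons,
             gc_target = gc, score = score)
}

#' Generate one species' synthetic transcriptome
#'
#' Emits a single-chromosome genome FASTA, an assembled-transcripts GTF, a
#' reference GFF3 (with a \code{novel_fraction} of transcripts withheld) and a
#' ranked lncRNA prediction score TSV, all of which parse with the package's
#' readers. Each transcript's spliced sequence carries a planted ORF of the
#' drawn length and is tuned to its drawn GC target; exon counts and spliced
#' lengths follow the per-class distributions.
#'
#' @param cfg A \code{"fixture_config"}.
#' @param species Species label (used for file names and the chromosome name).
#' @param dir Output directory (created if needed).
#' @param seed Optional RNG seed.
#' @param class_overrides Optional list with elements \code{lncRNA}/\code{other}
#'   of parameter overrides (used by \code{\link{generate_study}} to impose
#'   per-species trait drift).
#' @return Invisibly, a list with the four file \code{paths} and a
#'   \code{truth} data frame of planted classes and traits.
#' @export
generate_transcriptome <- function(cfg, species, dir, seed = NULL,
                                   class_overrides = list()) {
  cfg <- validate_fixture_config(unclass(cfg))
  for (cl in names(class_overrides))
    cfg[[cl]] <- utils::modifyList(cfg[[cl]], class_overrides[[cl]])
  cfg <- validate_fixture_config(unclass(cfg))
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- cfg$n_transcripts
  n_lnc <- max(1L, round(n * cfg$lnc_fraction))
  is_lnc <- sample(c(rep(TRUE, n_lnc), rep(FALSE, n - n_lnc)))
  traits <- draw_class_traits(cfg$other, n)
  lnc_traits <- draw_class_traits(cfg$lncRNA, n_lnc)
  traits[is_lnc, ] <- lnc_traits
  chrom <- paste0(species, "_chr1")

  genome_parts <- character(0)
  cursor <- 0L
  gtf <- character(0)
  gff <- character(0)
  truth <- vector("list", n)
  in_ref <- stats::runif(n) >= cfg$novel_fraction
  for (i in seq_len(n)) {
    tx <- sprintf("%s_t%04d", species, i)
    len <- traits$length[i]; orf <- traits$orf_len[i]
    k <- min(traits$n_exons[i], len)
    strand <- sample(c("+", "-"), 1)
    sense <- build_transcript_seq(len, orf, traits$gc_target[i])
    genomic <- if (strand == "-") revcomp_chr(sense) else sense
    exon_len <- if (k == 1) len else
      as.integer(stats::rmultinom(1, len - k, rep(1, k))) + 1L
    intron_len <- if (k > 1)
      as.integer(round(stats::runif(k - 1, cfg$intron_range[1],
                                    cfg$intron_range[2]))) else integer(0)
    spacer <- as.integer(round(stats::runif(1, cfg$spacer_range[1],
                                            cfg$spacer_range[2])))
    genome_parts <- c(genome_parts, random_dna(spacer, cfg$background_gc))
    cursor <- cursor + spacer
    starts <- ends <- integer(k)
    off <- 0L
    for (e in seq_len(k)) {
      piece <- substring(genomic, off + 1L, off + exon_len[e])
      off <- off + exon_len[e]
      starts[e] <- cursor + 1L
      ends[e] <- cursor + exon_len[e]
      genome_parts <- c(genome_parts, piece)
      cursor <- cursor + exon_len[e]
      if (e < k) {
        genome_parts <- c(genome_parts,
                          random_dna(intron_len[e], cfg$background_gc))
        cursor <- cursor + intron_len[e]
      }
    }
    gtf <- c(gtf, sprintf(
      "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\ttranscript_id \"%s\"; gene_id \"%s\";",
      chrom, starts, ends, strand, tx, paste0(tx, "_g")))
    if (in_ref[i]) {
      gff <- c(gff,
               sprintf("%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom, starts[1], ends[k], strand, tx),
               sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       chrom, starts, ends, strand, tx))
    }
    truth[[i]] <- data.frame(
      species = species, transcript_id = tx,
      class = if (is_lnc[i]) "lncRNA" else "other",
      score = traits$score[i], in_reference = in_ref[i], strand = strand,
      length = len, n_exons = k, gc_target = traits$gc_target[i],
      orf_len = orf)
  }
  genome <- Biostrings::DNAStringSet(paste(genome_parts, collapse = ""))
  names(genome) <- chrom
  paths <- list(genome = file.path(dir, paste0(species, "_genome.fa")),
                assembled = file.path(dir, paste0(species, "_assembled.gtf")),
                reference = file.path(dir, paste0(species, "_reference.gff3")),
                scores = file.path(dir, paste0(species, "_scores.tsv")))
  Biostrings::writeXStringSet(genome, paths$genome, width = 80)
  writeLines(gtf, paths$assembled)
  writeLines(c("##gff-version 3", gff), paths$reference)
  truth <- do.call(rbind, truth)
  utils::write.table(truth[order(-truth$score),
                           c("transcript_id", "score")],
                     paths$scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth = truth))
}

#' Generate a complete multi-species synthetic study
#'
#' Builds a pure-birth tree, lets the class-level trait parameters drift
#' across species under Brownian motion on that tree (so the species means
#' carry genuine phylogenetic signal), generates one transcriptome per tip,
#' and writes the tree, the per-species files and a \code{fixture.yaml}.
#'
#' @param cfg A \code{"fixture_config"}.
#' @param n_species Number of tree tips / species (default 10).
#' @param dir Output directory.
#' @param seed Master seed; per-species streams are derived from it.
#' @param bm_sd Standard deviations of the Brownian drift applied at depth 1
#'   to the class parameters: \code{gc} (additive on gc_mean),
#'   \code{log_len} (additive on len_meanlog), \code{log_exon} and
#'   \code{log_orf} (multiplicative on exon_lambda / orf_mean). Set entries to
#'   0 for identical species.
#' @return A list: \code{tree}, \code{species} (named list of per-species file
#'   paths), \code{truth}, \code{tree_path}, \code{config_path}.
#' @export
generate_study <- function(cfg, n_species = 10, dir, seed = 1,
                           bm_sd = c(gc = 0.06, log_len = 0.3,
                                     log_exon = 0.3, log_orf = 0.3)) {
  cfg <- validate_fixture_config(unclass(cfg))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- generate_tree(n_species, birth_rate = 1, seed = seed)
  tips <- tip_order(tree)
  set.seed(seed + 7L)
  drift <- list()
  for (cl in c("lncRNA", "other")) {
    drift[[cl]] <- list(
      gc = simulate_trait(tree, "BM", z0 = 0, sigma2 = bm_sd[["gc"]]^2),
      log_len = simulate_trait(tree, "BM", z0 = 0, sigma2 = bm_sd[["log_len"]]^2),
      log_exon = simulate_trait(tree, "BM", z0 = 0, sigma2 = bm_sd[["log_exon"]]^2),
      log_orf = simulate_trait(tree, "BM", z0 = 0, sigma2 = bm_sd[["log_orf"]]^2))
  }
  species <- list(); truths <- list()
  for (i in seq_along(tips)) {
    sp <- tips[i]
    ov <- lapply(drift, function(d) list())
    for (cl in c("lncRNA", "other")) {
      base <- cfg[[cl]]
      len_meanlog <- base$len_meanlog + drift[[cl]]$log_len[sp]
      ov[[cl]] <- list(
        gc_mean = min(max(base$gc_mean + drift[[cl]]$gc[sp], 0.2), 0.7),
        len_meanlog = len_meanlog,
        exon_lambda = base$exon_lambda * exp(drift[[cl]]$log_exon[sp]),
        # drifted ORF stays inside the drifted typical transcript length
        orf_mean = min(base$orf_mean * exp(drift[[cl]]$log_orf[sp]),
                       0.8 * exp(len_meanlog)))
    }
    res <- generate_transcriptome(cfg, sp, dir, seed = seed + 100L + i,
                                  class_overrides = ov)
    species[[sp]] <- res$paths
    truths[[sp]] <- res$truth
  }
  tree_path <- file.path(dir, "tree.nwk")
  write_phylogeny(tree, tree_path)
  config_path <- file.path(dir, "fixture.yaml")
  write_fixture_config(cfg, config_path)
  list(tree = tree, species = species, truth = do.call(rbind, truths),
       tree_path = tree_path, config_path = config_path)
}
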