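# Orchestration of the full comparative analysis: per-species counts and
# novelty, species x class trait means, the three signal statistics per trait
# and class, local correlograms, and BM/OU model comparison for traits with
# K > 1.

#' Percentage of predicted lncRNAs among assembled transcripts
#'
#' The normalization used to compare species with different transcriptome
#' sizes; reported to 1 decimal.
#'
#' @param n_lnc Number of predicted lncRNAs.
#' @param n_total Total assembled transcripts (> 0).
#' @return Percentage rounded to 1 decimal.
#' @export
percent_lncrna <- function(n_lnc, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_lnc > n_total)) stop("n_lnc exceeds n_total")
  round(100 * n_lnc / n_total, 1)
}

#' Study-level summary of per-species lncRNA percentages
#'
#' @param pcts Vector of per-species percentages.
#' @return List with \code{mean}, \code{sem} (standard error of the mean) and
#'   \code{n}.
#' @export
percent_summary <- function(pcts) {
  n <- length(pcts)
  list(mean = mean(pcts), sem = stats::sd(pcts) / sqrt(n), n = n)
}

#' Study configuration for \code{run_pipeline}
#'
#' @param species Named list (names = species labels matching tree tips); each
#'   element a list with paths \code{genome}, \code{assembled},
#'   \code{reference}, \code{scores}.
#' @param tree A \code{"phylo"} or path to a newick file (rooted, ultrametric).
#' @param score_threshold lncRNA call cutoff on the prediction score
#'   (default 0.5).
#' @param exclude Species to leave out of the signal analysis (still counted
#'   in the per-species tables).
#' @param n_perm Permutations for the Moran/K tests (default 999).
#' @param n_boot,n_points,ci Correlogram bootstrap parameters
#'   (defaults 1000 / 100 / 0.95).
#' @param fit_all Fit BM/OU for every trait x class rather than only those
#'   with K > 1 (default FALSE).
#' @param boundary_correction Use the boundary-mixture null for the BM/OU
#'   likelihood-ratio test (default TRUE); FALSE gives plain chi-square(1).
#' @param out_dir Output directory for the TSV report bundle (NULL: no files).
#' @param seed Master seed; every stochastic stage derives its stream from it.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(species, tree, score_threshold = 0.5,
                         exclude = character(0), n_perm = 999, n_boot = 1000,
                         n_points = 100, ci = 0.95, fit_all = FALSE,
                         boundary_correction = TRUE, out_dir = NULL,
                         seed = 1) {
  if (is.null(names(species)) || any(names(species) == ""))
    stop("`species` must be a named list")
  if (score_threshold < 0 || score_threshold > 1)
    stop("score_threshold must lie in [0, 1]")
  structure(list(species = species, tree = tree,
                 score_threshold = score_threshold, exclude = exclude,
                 n_perm = n_perm, n_boot = n_boot, n_points = n_points,
                 ci = ci, fit_all = fit_all,
                 boundary_correction = boundary_correction,
                 out_dir = out_dir, seed = seed),
            class = "study_config")
}

sub_seed <- function(seed, k) as.integer((seed + k * 10007) %% 2147483647L)

read_scores <- function(path) {
  sc <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("transcript_id", "score") %in% names(sc)))
    stop("score table needs columns transcript_id, score: ", path)
  stats::setNames(sc$score, sc$transcript_id)
}

PIPELINE_TRAITS <- c(orf = "mean_orf", gc = "mean_gc", exons = "mean_exons",
                     length = "mean_length")

#' Run the full comparative analysis
#'
#' Reads every species' genome, assembled transcripts, reference annotation
#' and prediction scores; flags lncRNAs at the score threshold; computes
#' per-species counts/percentages, novelty reports, the species x class mean
#' trait matrix; estimates Moran's I, Pagel's lambda and Blomberg's K for the
#' four traits in the lncRNA, other and difference series; computes the local
#' correlogram per trait and class; and compares BM vs OU fits for the
#' trait/class combinations with K > 1 (all combinations when
#' \code{fit_all = TRUE}). With \code{out_dir} set, the tables are also
#' written as TSV files.
#'
#' @param cfg A \code{"study_config"}.
#' @return A list with elements \code{counts}, \code{novelty},
#'   \code{trait_means}, \code{signal}, \code{correlograms} (named list of
#'   \code{"correlogram"} data frames), \code{model_fits}, \code{summary} and
#'   \code{tree}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree else
    read_phylogeny(file = cfg$tree)
  tree <- normalize_depth(tree)

  counts <- novelty <- list()
  all_records <- list()
  flags_all <- logical(0)
  for (sp in names(cfg$species)) {
    paths <- cfg$species[[sp]]
    genome <- Biostrings::readDNAStringSet(paths$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    assembled <- read_annotation(paths$assembled)
    reference <- read_annotation(paths$reference)
    scores <- read_scores(paths$scores)
    missing_scores <- setdiff(names(assembled), names(scores))
    if (length(missing_scores))
      stop(sp, ": assembled transcripts without a prediction score: ",
           paste(utils::head(missing_scores, 5), collapse = ", "))
    flags <- scores[names(assembled)] >= cfg$score_threshold
    flags_all <- c(flags_all, flags)
    tr <- transcriptome_traits(assembled, genome)
    tr$species <- sp
    all_records[[sp]] <- tr
    cls <- classify_vs_reference(assembled, reference)
    nv <- novelty_report(cls, flags)
    counts[[sp]] <- data.frame(species = sp,
                               n_transcripts = length(assembled),
                               n_lncrna = sum(flags),
                               pct_lncrna = percent_lncrna(sum(flags),
                                                           length(assembled)))
    novelty[[sp]] <- cbind(data.frame(species = sp), nv)
  }
  counts <- do.call(rbind, counts); rownames(counts) <- NULL
  novelty <- do.call(rbind, novelty); rownames(novelty) <- NULL
  records <- do.call(rbind, all_records); rownames(records) <- NULL
  trait_means <- aggregate_species_means(records, flags_all)

  signal_species <- sort(setdiff(names(cfg$species), cfg$exclude))
  tips <- tree$tip.label
  extra_tips <- setdiff(setdiff(tips, cfg$exclude), signal_species)
  missing_tips <- setdiff(signal_species, tips)
  if (length(extra_tips) || length(missing_tips))
    stop("tree tips and species data disagree; tips without data: {",
         paste(extra_tips, collapse = ", "), "}, data without tips: {",
         paste(missing_tips, collapse = ", "), "}")
  drop <- setdiff(tips, signal_species)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)

  D <- patristic_distances(tree)
  W <- proximity_matrix(D)
  C <- bm_covariance(tree)

  signal <- list(); correlograms <- list(); fits <- list()
  k <- 0L
  for (cl in c("lncRNA", "other", "difference")) {
    sub <- trait_means[trait_means$class == cl, ]
    for (tn in names(PIPELINE_TRAITS)) {
      k <- k + 1L
      x <- stats::setNames(sub[[PIPELINE_TRAITS[tn]]], sub$species)
      mi <- moran_i(x, W, n_perm = cfg$n_perm, seed = sub_seed(cfg$seed, k))
      la <- pagel_lambda(x, C)
      bk <- blomberg_k(x, C, n_perm = cfg$n_perm,
                       seed = sub_seed(cfg$seed, k + 100L))
      signal[[length(signal) + 1L]] <- data.frame(
        trait = tn, class = cl,
        moran_I = mi$value, moran_p = mi$p_value,
        lambda = la$value, lambda_p = la$p_value,
        K = bk$value, K_p = bk$p_value)
      cg <- local_correlogram(x, D, n_points = cfg$n_points,
                              n_boot = cfg$n_boot, ci = cfg$ci,
                              seed = sub_seed(cfg$seed, k + 200L))
      correlograms[[paste(tn, cl, sep = "_")]] <- cg
      if (isTRUE(cfg$fit_all) || bk$value > 1) {
        bm <- fit_bm(x, C)
        ou <- fit_ou(x, tree)
        cmp <- compare_bm_ou(bm, ou,
                             boundary_correction = cfg$boundary_correction)
        fits[[length(fits) + 1L]] <- data.frame(
          trait = tn, class = cl, K = bk$value,
          lnL_BM = bm$lnL, lnL_OU = ou$lnL, alpha = ou$alpha,
          lr_stat = cmp$lr_stat, p_value = cmp$p_value,
          preferred = cmp$preferred)
      }
    }
  }
  signal <- do.call(rbind, signal)
  signal$moran_p_bh <- stats::p.adjust(signal$moran_p, "BH")
  signal$lambda_p_bh <- stats::p.adjust(signal$lambda_p, "BH")
  signal$K_p_bh <- stats::p.adjust(signal$K_p, "BH")
  fits <- if (length(fits)) do.call(rbind, fits) else NULL

  summary <- percent_summary(counts$pct_lncrna)
  out <- list(counts = counts, novelty = novelty, trait_means = trait_means,
              signal = signal, correlograms = correlograms,
              model_fits = fits, summary = summary, tree = tree, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  counts <- res$counts
  counts$pct_lncrna <- round(counts$pct_lncrna, 1)
  wt(counts, "lncrna_counts.tsv")
  nv <- res$novelty
  nv$pct_novel <- round(nv$pct_novel, 1)
  nv$pct_intergenic <- round(nv$pct_intergenic, 1)
  wt(nv, "novelty.tsv")
  wt(round_df(res$trait_means, 4), "species_trait_means.tsv")
  sig <- round_df(res$signal, 3)
  wt(sig[sig$class != "difference", ], "signal_table.tsv")
  wt(sig[sig$class == "difference", ], "signal_difference.tsv")
  for (nm in names(res$correlograms)) {
    cg <- as.data.frame(res$correlograms[[nm]])
    cg <- round_df(cg, 4)
    wt(cg, paste0("correlogram_", nm, ".tsv"))
  }
  if (!is.null(res$model_fits))
    wt(round_df(res$model_fits, 4), "model_comparison.tsv")
  cfg <- res$config
  yaml::write_yaml(list(score_threshold = cfg$score_threshold,
                        exclude = cfg$exclude, n_perm = cfg$n_perm,
                        n_boot = cfg$n_boot, n_points = cfg$n_points,
                        ci = cfg$ci, fit_all = cfg$fit_all,
                        boundary_correction = cfg$boundary_correction,
                        seed = cfg$seed),
                   file.path(dir, "run_parameters.yaml"))
  invisible(dir)
}
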