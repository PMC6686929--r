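#' @importFrom ape read.tree write.tree node.depth.edgelength vcv.phylo
#' @importFrom stats cophenetic setNames var optimize pchisq sd rnorm
#' @importFrom stats quantile
#' @importFrom utils write.table read.table
NULL

# Canonical tip order for every matrix in the package: lexicographic by label,
# so repeated runs and differently-rotated newicks give identical matrices.
tip_order <- function(tree) sort(tree$tip.label, method = "radix")

#' Parse a rooted newick tree with branch lengths
#'
#' Reads a newick string (or file) into an \code{ape} \code{"phylo"} object and
#' validates the invariants every downstream matrix relies on: unique tip
#' labels, branch lengths present and non-negative, and a single root.
#'
#' @param text A newick string (terminated by \code{;}). Exactly one of
#'   \code{text} and \code{file} must be given.
#' @param file Path to a newick file.
#' @return A validated \code{"phylo"} object.
#' @examples
#' tr <- read_phylogeny("((A:0.25,B:0.25):0.75,(C:0.5,D:0.5):0.5);")
#' @export
read_phylogeny <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("malformed newick: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')') in ", substr(text, 1, 60))
  if (!grepl(";\\s*$", text))
    stop("malformed newick: missing terminal ';' in ", substr(text, 1, 60))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree) || inherits(tree, "multiPhylo"))
    stop("newick parse error: input did not yield a single tree")
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length))
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s): min = ", min(tree$edge.length))
  # single root = exactly one node that is never a child (basal polytomies,
  # e.g. star trees, are still rooted in this sense)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stop("tree is not rooted: found ", length(roots),
                               " root nodes")
  tree
}

#' Serialize a phylogeny to newick
#'
#' @param tree A \code{"phylo"} object.
#' @param file Optional path; if \code{NULL} the newick string is returned.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_phylogeny <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' ordered lexicographically by tip label.
#'
#' @param tree A rooted \code{"phylo"} with branch lengths.
#' @return A symmetric n x n matrix with zero diagonal and tip-label dimnames.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_phylogeny(tree)
  ord <- tip_order(tree)
  D <- stats::cophenetic(tree)[ord, ord]
  D
}

#' Brownian-motion covariance matrix
#'
#' \code{C[i, j]} is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds root-to-tip depths. Under Brownian motion with rate
#' \eqn{\sigma^2} the tip traits are multivariate normal with covariance
#' \eqn{\sigma^2 C}.
#'
#' @param tree A rooted \code{"phylo"} with branch lengths.
#' @return A symmetric positive-definite matrix in lexicographic tip order.
#' @export
bm_covariance <- function(tree) {
  tree <- validate_phylogeny(tree)
  ord <- tip_order(tree)
  ape::vcv.phylo(tree)[ord, ord]
}

root_to_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  stats::setNames(d, tree$tip.label)
}

#' Rescale an ultrametric tree to unit depth (relative branch ages)
#'
#' Branch lengths estimated in substitution units are converted to relative
#' ages by dividing every branch length by the root-to-tip depth, so the tree
#' spans phylogenetic distance 0-1. The input must be ultrametric.
#'
#' @param tree A rooted ultrametric \code{"phylo"}.
#' @param tol Relative tolerance on the root-to-tip depth spread
#'   (default \code{1e-6}); newick round-off stays well inside it.
#' @return The depth-1 tree (idempotent for an already unit-depth tree).
#' @export
normalize_depth <- function(tree, tol = 1e-6) {
  tree <- validate_phylogeny(tree)
  depths <- root_to_tip_depths(tree)
  depth <- max(depths)
  if (depth <= 0) stop("tree has zero depth")
  spread <- max(depths) - min(depths)
  if (spread > tol * depth)
    stop("tree is not ultrametric: root-to-tip depth spread ", signif(spread, 4),
         " exceeds tolerance ", signif(tol * depth, 4),
         " (depths range ", signif(min(depths), 6), "-", signif(max(depths), 6), ")")
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Phylogenetic proximity (weight) matrix for Moran's I
#'
#' Builds row-normalized weights from a patristic distance matrix. With
#' \code{method = "inverse_distance"}, \eqn{w_{ij} \propto 1/d_{ij}} with zero
#' diagonal and each row rescaled to sum 1 — the usual distance-decay weighting
#' for autocorrelation indices.
#'
#' @param D A patristic distance matrix (symmetric, zero diagonal, positive
#'   off-diagonal entries).
#' @param method Weighting scheme; only \code{"inverse_distance"} is provided,
#'   the argument exists so alternatives can be plugged in.
#' @return A matrix with zero diagonal and rows summing to 1.
#' @export
proximity_matrix <- function(D, method = c("inverse_distance")) {
  method <- match.arg(method)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 2) stop("need at least 2 tips")
  off <- D[upper.tri(D) | lower.tri(D)]
  if (any(off <= 0))
    stop("zero or negative off-diagonal distance (identical tips): ",
         "1/d weighting undefined")
  W <- 1 / D
  diag(W) <- 0
  W <- W / rowSums(W)
  W
}

#' Write a labelled matrix as TSV
#'
#' Tip labels form the header row and first column, so the matrix round-trips
#' through \code{read_matrix_tsv}.
#'
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
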