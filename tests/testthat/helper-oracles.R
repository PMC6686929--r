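# Independent brute-force oracles used to check the package's estimators.

# Moran's I by explicit double loop over tip pairs.
moran_oracle <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
    S0 <- S0 + W[i, j]
  }
  unname((n / S0) * num / sum((x - xb)^2))
}

# Longest ORF by exhaustive enumeration of every (ATG, downstream in-frame
# stop) pair, independent of the single-pass scanner in the package.
orf_oracle <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (st in seq_len(max(0L, n - 5L))) {
    if (substr(s, st, st + 2) != "ATG") next
    j <- st + 3L
    while (j + 2L <= n) {
      if (substr(s, j, j + 2) %in% stops) {
        best <- max(best, j + 2L - st + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# Patristic distance by walking each tip's ancestor chain to the root and
# summing branch lengths down from the first shared ancestor.
patristic_oracle <- function(tree, a, b) {
  chain <- function(tip) {
    node <- which(tree$tip.label == tip)
    anc <- integer(0)
    cum <- numeric(0)
    len <- 0
    while (TRUE) {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      len <- len + tree$edge.length[e]
      node <- tree$edge[e, 1]
      anc <- c(anc, node)
      cum <- c(cum, len)
    }
    list(anc = anc, cum = cum)
  }
  ca <- chain(a)
  cb <- chain(b)
  mrca <- intersect(ca$anc, cb$anc)[1]
  ca$cum[match(mrca, ca$anc)] + cb$cum[match(mrca, cb$anc)]
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

random_dna_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# Four-tip hand-checkable ultrametric tree used across tests.
tree4 <- function() read_phylogeny("((A:0.25,B:0.25):0.75,(C:0.5,D:0.5):0.5);")

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  tr
}
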