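# Phylogenetic signal estimators on tip traits: global Moran's I with a
# permutation test, Blomberg's K, profile-ML Pagel's lambda, and the
# 100-point local Moran correlogram with tip-bootstrap confidence intervals.

align_trait <- function(x, labels) {
  if (is.null(names(x))) {
    if (length(x) != length(labels))
      stop("trait vector has no names and its length (", length(x),
           ") does not match the number of tips (", length(labels), ")")
    names(x) <- labels
  }
  miss <- setdiff(labels, names(x))
  if (length(miss))
    stop("trait values missing for tips: ", paste(miss, collapse = ", "))
  x <- x[labels]
  if (!all(is.finite(x))) stop("non-finite trait values")
  x
}

new_signal_estimate <- function(statistic, value, null_expectation, p_value,
                                n_reps = NA_integer_, seed = NA_integer_,
                                extra = list()) {
  structure(c(list(statistic = statistic, value = value,
                   null_expectation = null_expectation, p_value = p_value,
                   n_reps = n_reps, seed = seed), extra),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat("Phylogenetic signal estimate (", x$statistic, ")\n", sep = "")
  cat("  value:            ", format(x$value, digits = 4), "\n")
  if (is.finite(x$null_expectation))
    cat("  null expectation: ", format(x$null_expectation, digits = 4), "\n")
  if (!is.na(x$p_value))
    cat("  p-value:          ", format.pval(x$p_value, digits = 3),
        if (!is.na(x$n_reps)) paste0(" (", x$n_reps, " reps)"), "\n", sep = "")
  invisible(x)
}

moran_stat <- function(xc, W, ssq) {
  n <- length(xc)
  S0 <- sum(W)
  (n / S0) * sum(W * tcrossprod(xc)) / ssq
}

#' Global Moran's I for a tip trait
#'
#' Autocorrelation of a trait over the phylogeny:
#' \deqn{I = (n/S_0) \sum_{i \ne j} w_{ij}(x_i-\bar x)(x_j-\bar x) /
#'       \sum_i (x_i-\bar x)^2.}
#' The null expectation is \eqn{-1/(n-1)}; values significantly above it
#' indicate that proximate tips carry similar trait values. Significance comes
#' from random tip-label permutations (two-sided, \code{(b+1)/(B+1)} rule).
#'
#' @param x Named trait vector (one value per tip of the weight matrix).
#' @param W Row-normalized proximity matrix from \code{\link{proximity_matrix}}.
#' @param n_perm Number of permutations (default 999); 0 skips the test.
#' @param seed Optional RNG seed for the permutation test.
#' @return A \code{"signal_estimate"} with value, null expectation
#'   \eqn{-1/(n-1)} and permutation p-value.
#' @export
moran_i <- function(x, W, n_perm = 999, seed = NULL) {
  labels <- rownames(W)
  x <- align_trait(x, labels)
  n <- length(x)
  if (n < 2) stop("need at least 2 tips")
  xc <- x - mean(x)
  ssq <- sum(xc^2)
  if (ssq == 0) stop("zero variance: trait is constant across tips")
  obs <- moran_stat(xc, W, ssq)
  e0 <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    dev <- abs(obs - e0)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      xp <- xc[sample.int(n)]
      if (abs(moran_stat(xp, W, ssq) - e0) >= dev - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  new_signal_estimate("moran_I", obs, e0, p, n_perm,
                      if (is.null(seed)) NA_integer_ else seed)
}

k_ratio <- function(x, Cinv, ones) {
  n <- length(x)
  a_hat <- sum(Cinv %*% x) / sum(ones %*% Cinv %*% ones)
  r <- x - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(crossprod(r, Cinv %*% r)) / (n - 1)
  mse0 / mse
}

#' Blomberg's K for a tip trait
#'
#' Ratio of the observed to the Brownian-expected partitioning of trait
#' variance on the tree. With the phylogenetic GLS mean
#' \eqn{\hat a = (1'C^{-1}1)^{-1} 1'C^{-1}x},
#' \deqn{K = \frac{MSE_0/MSE}{[\mathrm{tr}(C) - n/(1'C^{-1}1)]/(n-1)}}
#' where \eqn{MSE_0} is the ordinary and \eqn{MSE} the phylogenetically
#' corrected mean square. K = 1 matches Brownian motion; K > 1 means stronger,
#' K < 1 weaker resemblance among relatives. The p-value permutes tip labels
#' and compares the observed variance ratio to the permuted ones (one-sided).
#'
#' @param x Named trait vector.
#' @param C Brownian covariance matrix from \code{\link{bm_covariance}}.
#' @param n_perm Number of permutations (default 999); 0 skips the test.
#' @param seed Optional RNG seed.
#' @return A \code{"signal_estimate"}; \code{null_expectation} is 1 (the BM
#'   reference value).
#' @export
blomberg_k <- function(x, C, n_perm = 999, seed = NULL) {
  labels <- rownames(C)
  x <- align_trait(x, labels)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  if (stats::var(x) == 0) stop("zero variance: trait is constant across tips")
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("BM covariance is singular: ", conditionMessage(e)))
  ones <- rep(1, n)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  obs_ratio <- k_ratio(x, Cinv, ones)
  K <- obs_ratio / expected
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (k_ratio(x[sample.int(n)], Cinv, ones) >= obs_ratio - 1e-12)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  new_signal_estimate("blomberg_K", K, 1, p, n_perm,
                      if (is.null(seed)) NA_integer_ else seed)
}

# Profiled multivariate-normal log-likelihood of x on covariance sigma2 * V,
# with the root state and sigma2 at their analytic optima.
profile_lnl <- function(x, V) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Vinv_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  z0 <- sum(Vinv_x) / sum(Vinv_1)
  r <- x - z0
  q <- drop(crossprod(r, backsolve(ch, forwardsolve(t(ch), r))))
  if (q <= 0) return(-Inf)
  sigma2 <- q / n
  lnl <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  attr(lnl, "z0") <- z0
  attr(lnl, "sigma2") <- sigma2
  lnl
}

lambda_transform <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

#' Maximum-likelihood Pagel's lambda
#'
#' Finds the multiplier \eqn{\lambda} on the off-diagonal of the Brownian
#' covariance that maximizes the multivariate-normal likelihood of the trait,
#' with the root state and rate profiled analytically. \eqn{\lambda = 1} keeps
#' the tree as is (Brownian-like signal); \eqn{\lambda = 0} erases shared
#' history (a star tree, no signal). The search interval is
#' \eqn{[0, \lambda_{max}]} where the upper bound keeps the transformed matrix
#' positive definite, capped at 1.2 so mild overshoot past 1 is measurable.
#' The p-value is a likelihood-ratio test of \eqn{\hat\lambda} against
#' \eqn{\lambda = 0}; the null sits on the interval boundary, so the statistic
#' is referred to the \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} mixture.
#'
#' @param x Named trait vector.
#' @param C Brownian covariance from an ultrametric tree (equal diagonal).
#' @param lambda_max Optional upper search bound; defaults to the
#'   positive-definiteness safeguard capped at 1.2.
#' @param tol Absolute tolerance of the scalar optimizer (default 1e-8).
#' @return A \code{"signal_estimate"} carrying \code{lnL} (at the optimum),
#'   \code{lnL0} (at \eqn{\lambda = 0}), \code{z0} and \code{sigma2}.
#' @export
pagel_lambda <- function(x, C, lambda_max = NULL, tol = 1e-8) {
  labels <- rownames(C)
  x <- align_trait(x, labels)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  if (stats::var(x) == 0) stop("zero variance: trait is constant across tips")
  dC <- diag(C)
  if ((max(dC) - min(dC)) > 1e-6 * max(dC))
    stop("C does not come from an ultrametric tree (unequal diagonal); ",
         "the lambda transform requires equal tip depths")
  if (is.null(lambda_max)) {
    off <- C[upper.tri(C)]
    io <- which(upper.tri(C), arr.ind = TRUE)
    pd_bound <- suppressWarnings(
      min((dC[io[, 1]] * dC[io[, 2]]) / off[off > 0]^2, na.rm = TRUE))
    lambda_max <- min(1.2, pd_bound)
  }
  obj <- function(l) {
    v <- as.numeric(profile_lnl(x, lambda_transform(C, l)))
    if (is.finite(v)) v else -1e300  # keep optimize() off the non-PD region
  }
  opt <- stats::optimize(obj, c(0, lambda_max), maximum = TRUE, tol = tol)
  # optimize() never lands exactly on a boundary; check both explicitly
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, obj(0)), c(lambda_max, obj(lambda_max)))
  best <- cand[which.max(cand[, 2]), ]
  if (!is.finite(best[2]) || best[2] <= -1e299)
    stop("lambda optimization failed: log-likelihood not finite on [0, ",
         signif(lambda_max, 4), "]")
  lam <- best[1]
  lnl <- profile_lnl(x, lambda_transform(C, lam))
  lnl0 <- obj(0)
  lr <- max(0, 2 * (as.numeric(lnl) - lnl0))
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  new_signal_estimate("pagel_lambda", lam, 0, p,
                      extra = list(lnL = as.numeric(lnl), lnL0 = lnl0,
                                   z0 = attr(lnl, "z0"),
                                   sigma2 = attr(lnl, "sigma2"),
                                   lambda_max = lambda_max))
}

# Moran's I with a binary distance-window weight matrix; `excl` marks pairs
# that must not be weighted (self-pairs, incl. bootstrap duplicates).
window_moran <- function(xc, ssq, D, h, bw, excl) {
  n <- length(xc)
  A <- abs(D - h) <= bw
  A[excl] <- FALSE
  if (sum(A) < 2) return(NA_real_)
  rs <- rowSums(A)
  W <- A / pmax(rs, 1)
  (n / sum(W)) * sum(W * tcrossprod(xc)) / ssq
}

#' Local Moran's I correlogram with bootstrap confidence intervals
#'
#' Profiles autocorrelation across phylogenetic distance: at each of
#' \code{n_points} grid distances a binary sliding window selects the tip
#' pairs whose patristic distance falls within \code{bandwidth} of the grid
#' point, the window weights are row-normalized, and Moran's I is computed.
#' Percentile confidence intervals come from resampling tips with replacement
#' (\code{n_boot} case-bootstrap replicates; duplicate-tip pairs are excluded
#' from the windows). A grid point is flagged significant when its CI excludes
#' the null threshold \eqn{-1/(n-1)}. The phylogenetic patch is the smallest
#' grid distance at which the flag drops from significant-positive to not
#' significant.
#'
#' @param x Named trait vector.
#' @param D Patristic distance matrix.
#' @param n_points Grid size (default 100).
#' @param n_boot Bootstrap replicates (default 1000); 0 skips CIs.
#' @param ci Confidence level (default 0.95).
#' @param bandwidth Window half-width; default twice the grid spacing.
#' @param seed Optional RNG seed.
#' @return A data frame of class \code{"correlogram"} with columns \code{h},
#'   \code{I}, \code{lo}, \code{hi}, \code{significant} and attributes
#'   \code{threshold} and \code{patch} (NA when no positive-to-null crossing
#'   occurs).
#' @export
local_correlogram <- function(x, D, n_points = 100, n_boot = 1000, ci = 0.95,
                              bandwidth = NULL, seed = NULL) {
  labels <- rownames(D)
  x <- align_trait(x, labels)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips")
  dmax <- max(D)
  if (dmax <= 0) stop("max patristic distance must be positive")
  if (stats::var(x) == 0) stop("zero variance: trait is constant across tips")
  spacing <- dmax / n_points
  if (is.null(bandwidth)) bandwidth <- 2 * spacing
  h <- spacing * seq_len(n_points)
  thr <- -1 / (n - 1)

  diag_excl <- diag(n) == 1
  xc <- x - mean(x)
  ssq <- sum(xc^2)
  I_obs <- vapply(h, function(hk)
    window_moran(xc, ssq, D, hk, bandwidth, diag_excl), numeric(1))

  lo <- hi <- rep(NA_real_, n_points)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, n_points)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        xb <- x[idx]
        if (length(unique(idx)) >= 2 && stats::var(xb) > 0) break
      }
      Db <- D[idx, idx]
      excl <- outer(idx, idx, `==`)
      xbc <- xb - mean(xb)
      ssqb <- sum(xbc^2)
      boot[b, ] <- vapply(h, function(hk)
        window_moran(xbc, ssqb, Db, hk, bandwidth, excl), numeric(1))
    }
    alpha <- (1 - ci) / 2
    for (k in seq_len(n_points)) {
      bk <- boot[, k]
      bk <- bk[is.finite(bk)]
      if (length(bk) >= 10) {
        q <- stats::quantile(bk, c(alpha, 1 - alpha), names = FALSE, type = 7)
        lo[k] <- q[1]; hi[k] <- q[2]
      }
    }
  }
  significant <- ifelse(is.na(lo) | is.na(hi), NA, lo > thr | hi < thr)

  patch <- NA_real_
  for (k in 2:n_points) {
    prev_pos <- isTRUE(significant[k - 1]) && is.finite(I_obs[k - 1]) &&
      I_obs[k - 1] > thr
    if (prev_pos && !isTRUE(significant[k])) { patch <- h[k]; break }
  }

  out <- data.frame(h = h, I = I_obs, lo = lo, hi = hi,
                    significant = significant)
  attr(out, "threshold") <- thr
  attr(out, "patch") <- patch
  attr(out, "bandwidth") <- bandwidth
  attr(out, "n_boot") <- n_boot
  attr(out, "ci") <- ci
  class(out) <- c("correlogram", "data.frame")
  out
}
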