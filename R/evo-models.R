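# Maximum-likelihood Brownian-motion and Ornstein-Uhlenbeck fits on tip
# traits, the likelihood-ratio comparison between them, and seeded trait
# simulators used as the test harness for every estimator.

new_model_fit <- function(model, z0, sigma2, lnL, alpha = NA_real_,
                          at_bound = FALSE) {
  structure(list(model = model, z0 = z0, sigma2 = sigma2, alpha = alpha,
                 lnL = lnL, n_params = if (model == "OU") 3L else 2L,
                 at_bound = at_bound),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(x$model, "fit: lnL =", format(x$lnL, digits = 6),
      " z0 =", format(x$z0, digits = 4),
      " sigma2 =", format(x$sigma2, digits = 4))
  if (x$model == "OU") cat("  alpha =", format(x$alpha, digits = 4))
  if (isTRUE(x$at_bound)) cat("  [alpha at search bound]")
  cat("\n")
  invisible(x)
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Closed-form ML under \eqn{x \sim N(z_0 1, \sigma^2 C)}:
#' \eqn{\hat z_0 = (1'C^{-1}1)^{-1}1'C^{-1}x},
#' \eqn{\hat\sigma^2 = (x-\hat z_0 1)'C^{-1}(x-\hat z_0 1)/n}, and
#' \eqn{\ln L = -\tfrac12[n\ln(2\pi\hat\sigma^2) + \ln|C| + n]}.
#'
#' @param x Named trait vector.
#' @param C Brownian covariance from \code{\link{bm_covariance}}.
#' @return A \code{"model_fit"} (model "BM", 2 parameters).
#' @export
fit_bm <- function(x, C) {
  labels <- rownames(C)
  x <- align_trait(x, labels)
  if (length(x) < 3) stop("need at least 3 tips")
  if (stats::var(x) == 0) stop("degenerate trait: zero variance")
  lnl <- profile_lnl(x, C)
  if (!is.finite(lnl)) stop("BM fit failed: C is singular or not positive definite")
  new_model_fit("BM", attr(lnl, "z0"), attr(lnl, "sigma2"), as.numeric(lnl))
}

# OU correlation structure (sigma2 profiled out): for an ultrametric tree,
# R_ij(alpha) = (1/2a) exp(-a d_ij) (1 - exp(-2a s_ij)).
ou_structure <- function(alpha, D, S) {
  (1 / (2 * alpha)) * exp(-alpha * D) * (1 - exp(-2 * alpha * S))
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit
#'
#' Fits the single-optimum OU process with the root state fixed at the optimum
#' (\eqn{\theta = z_0}). The tip covariance is
#' \deqn{V_{ij}(\alpha) = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
#'       (1 - e^{-2\alpha s_{ij}})}
#' with \eqn{d_{ij}} the patristic distance and \eqn{s_{ij}} the shared
#' root-to-MRCA path. \eqn{z_0} and \eqn{\sigma^2} are profiled analytically
#' and \eqn{\alpha} is found by scalar search over \code{alpha_bounds}
#' (default \eqn{[10^{-8}, 50/T]} for tree depth T — beyond that the
#' covariance is numerically singular). As \eqn{\alpha \to 0} the model
#' collapses to Brownian motion.
#'
#' @param x Named trait vector.
#' @param tree A rooted ultrametric \code{"phylo"}.
#' @param alpha_bounds Length-2 search interval for \eqn{\alpha}.
#' @return A \code{"model_fit"} (model "OU", 3 parameters); \code{at_bound}
#'   flags an estimate pinned at the upper search bound.
#' @export
fit_ou <- function(x, tree, alpha_bounds = NULL) {
  tree <- validate_phylogeny(tree)
  depths <- root_to_tip_depths(tree)
  T_depth <- max(depths)
  if ((max(depths) - min(depths)) > 1e-6 * T_depth)
    stop("OU fit requires an ultrametric tree")
  S <- bm_covariance(tree)
  D <- patristic_distances(tree)
  x <- align_trait(x, rownames(S))
  if (length(x) < 3) stop("need at least 3 tips")
  if (stats::var(x) == 0) stop("degenerate trait: zero variance")
  if (is.null(alpha_bounds)) alpha_bounds <- c(1e-8, 50 / T_depth)
  obj <- function(a) {
    v <- as.numeric(profile_lnl(x, ou_structure(a, D, S)))
    if (is.finite(v)) v else -1e300
  }
  opt <- stats::optimize(obj, alpha_bounds, maximum = TRUE, tol = 1e-10)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(alpha_bounds[1], obj(alpha_bounds[1])),
                c(alpha_bounds[2], obj(alpha_bounds[2])))
  best <- cand[which.max(cand[, 2]), ]
  if (!is.finite(best[2]) || best[2] <= -1e299)
    stop("OU optimization failed on [",
                                signif(alpha_bounds[1], 3), ", ",
                                signif(alpha_bounds[2], 3), "]")
  alpha_hat <- best[1]
  at_bound <- (alpha_bounds[2] - alpha_hat) < 1e-6 * alpha_bounds[2]
  if (at_bound)
    warning("OU alpha estimate at upper search bound (", signif(alpha_hat, 4),
            "); covariance nearly singular, estimate unreliable")
  lnl <- profile_lnl(x, ou_structure(alpha_hat, D, S))
  new_model_fit("OU", attr(lnl, "z0"), attr(lnl, "sigma2"), as.numeric(lnl),
                alpha = alpha_hat, at_bound = at_bound)
}

#' Likelihood-ratio comparison of BM and OU fits
#'
#' \eqn{LR = 2(\ln L_{OU} - \ln L_{BM})} with 1 degree of freedom (the OU
#' \eqn{\alpha}). BM is nested in OU at \eqn{\alpha = 0}, a boundary of the
#' parameter space, so by default the statistic is referred to the
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} mixture;
#' \code{boundary_correction = FALSE} gives the plain \eqn{\chi^2_1} test.
#' BM is preferred unless the test is significant at 0.05 (the fewer-parameters
#' rule).
#'
#' @param bm,ou \code{"model_fit"} objects for the same data.
#' @param boundary_correction Use the boundary mixture null (default TRUE).
#' @param alpha_level Significance level for model preference (default 0.05).
#' @return A list of class \code{"model_comparison"} with \code{lr_stat},
#'   \code{df}, \code{p_value} and \code{preferred}.
#' @export
compare_bm_ou <- function(bm, ou, boundary_correction = TRUE,
                          alpha_level = 0.05) {
  stopifnot(inherits(bm, "model_fit"), inherits(ou, "model_fit"))
  if (bm$model != "BM" || ou$model != "OU")
    stop("arguments must be a BM fit and an OU fit, in that order")
  if (ou$lnL < bm$lnL - 1e-4)
    stop("OU log-likelihood (", format(ou$lnL), ") below BM (",
         format(bm$lnL), "): OU optimizer failure, models are nested")
  lr <- max(0, 2 * (ou$lnL - bm$lnL))
  p <- if (boundary_correction) {
    if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(lr, df = 1, lower.tail = FALSE)
  }
  structure(list(lr_stat = lr, df = 1L, p_value = p,
                 preferred = if (p < alpha_level) "OU" else "BM",
                 boundary_correction = boundary_correction),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("BM vs OU: LR =", format(x$lr_stat, digits = 4),
      " df =", x$df, " p =", format.pval(x$p_value, digits = 3),
      " preferred:", x$preferred, "\n")
  invisible(x)
}

#' Simulate a continuous trait along a phylogeny
#'
#' Pre-order recursion from the root: under Brownian motion a child state is
#' \eqn{parent + N(0, \sigma^2 b)} for branch length b; under OU it is
#' \eqn{\theta + (parent - \theta)e^{-\alpha b} +
#'      N(0, \frac{\sigma^2}{2\alpha}(1 - e^{-2\alpha b}))}.
#'
#' @param tree A rooted \code{"phylo"} with branch lengths.
#' @param model "BM" or "OU".
#' @param z0 Root state (default 0).
#' @param sigma2 Diffusion rate (> 0, default 1).
#' @param alpha OU pull strength (required > 0 for OU).
#' @param theta OU optimum (defaults to \code{z0}).
#' @param seed Optional RNG seed (same seed, same vector).
#' @return Named tip-trait vector in the tree's tip order.
#' @export
simulate_trait <- function(tree, model = c("BM", "OU"), z0 = 0, sigma2 = 1,
                           alpha = 0, theta = z0, seed = NULL) {
  model <- match.arg(model)
  tree <- validate_phylogeny(tree)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (model == "OU" && alpha <= 0) stop("OU requires alpha > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  states <- numeric(n + tree$Nnode)
  states[n + 1L] <- z0
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    b <- tree$edge.length[e]
    states[child] <- if (model == "BM") {
      states[par] + stats::rnorm(1, 0, sqrt(sigma2 * b))
    } else {
      theta + (states[par] - theta) * exp(-alpha * b) +
        stats::rnorm(1, 0, sqrt(sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * b))))
    }
  }
  stats::setNames(states[seq_len(n)], tree$tip.label)
}
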