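#' Gaussian mixture parameters
#'
#' @param weights Mixing proportions (sum to 1).
#' @param means Component means.
#' @param variances Component variances (> 0).
#' @param loglik Final log-likelihood of the fit.
#' @return An object of class `gmm_params`, components sorted by increasing
#'   mean.
#' @export
gmm_params <- function(weights, means, variances, loglik = NA_real_) {
  K <- length(means)
  if (length(weights) != K || length(variances) != K) {
    stop("weights, means and variances must have equal length", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(variances <= 0)) stop("variances must be positive", call. = FALSE)
  ord <- order(means)
  structure(list(weights = as.numeric(weights[ord]),
                 means = as.numeric(means[ord]),
                 variances = as.numeric(variances[ord]),
                 K = K, loglik = loglik),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("<gmm_params K = %d, loglik = %.4f>\n", x$K, x$loglik))
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  invisible(x)
}

# EM core for a 1-D Gaussian mixture from a given initialization. Log-space
# E-step; variances floored at 1e-8, weights at 1e-6 (a collapsing component
# is recorded in the "collapsed" attribute rather than allowed to go
# singular). The log-likelihood trace is non-decreasing.
gmm_em_core <- function(x, weights, means, vars, tol = 1e-6,
                        max_iter = 500L, sort_by_mean = TRUE) {
  K <- length(means)
  n <- length(x)
  vars <- pmax(vars, 1e-8)
  weights <- pmax(weights, 1e-6); weights <- weights / sum(weights)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  collapsed <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k) {
      log(weights[k]) + stats::dnorm(x, means[k], sqrt(vars[k]), log = TRUE)
    }, numeric(n))
    if (K == 1L) logd <- matrix(logd, ncol = 1L)
    lse <- logsumexp(logd)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk / n < 1e-6)) collapsed <- TRUE
    nk <- pmax(nk, 1e-10)
    weights <- pmax(nk / n, 1e-6); weights <- weights / sum(weights)
    means <- colSums(resp * x) / nk
    vars <- vapply(seq_len(K), function(k) {
      sum(resp[, k] * (x - means[k])^2) / nk[k]
    }, numeric(1))
    if (any(vars < 1e-8)) collapsed <- TRUE
    vars <- pmax(vars, 1e-8)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (sort_by_mean) {
    ord <- order(means)
    weights <- weights[ord]; means <- means[ord]; vars <- vars[ord]
  }
  list(weights = weights, means = means, vars = vars,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = length(ll_trace), collapsed = collapsed)
}

#' Fit a Gaussian mixture to image intensities by EM
#'
#' Models the pooled pixel intensities as a `K`-component Gaussian mixture
#' `p(x) = sum_k alpha_k N(x | mu_k, Sigma_k)` and fits it by expectation
#' maximization, initialized from seeded K-means on the intensities.
#' `K = 3` (default) lets the mixture absorb bright tissue (vessels, pleura,
#' highlight tissue) in a third component so the nodule/background posteriors
#' stay clean around the nodule.
#'
#' @param img An [intensity_image()] (or numeric vector/matrix).
#' @param K Number of components (default 3).
#' @param seed Seed for the K-means initialization.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @return A [gmm_params()] (components sorted by mean) with attributes
#'   `"loglik_trace"`, `"iterations"` and `"collapsed"`.
#' @export
fit_gmm_em <- function(img, K = 3L, seed = 1L, tol = 1e-6, max_iter = 500L) {
  x <- if (is.numeric(img) && !is.matrix(img)) as.numeric(img)
       else as.vector(as_pixel_matrix(img))
  if (length(unique(x)) < K) {
    stop("fewer than K = ", K, " distinct intensities", call. = FALSE)
  }
  km <- seeded_kmeans(x, K, seed = seed)
  pop_var <- function(v) mean((v - mean(v))^2)
  w0 <- tabulate(km$cluster, K) / length(x)
  m0 <- vapply(seq_len(K), function(k) mean(x[km$cluster == k]), numeric(1))
  v0 <- vapply(seq_len(K), function(k) {
    v <- pop_var(x[km$cluster == k]); max(v, 1e-8)
  }, numeric(1))
  fit <- gmm_em_core(x, w0, m0, v0, tol = tol, max_iter = max_iter)
  out <- gmm_params(fit$weights, fit$means, fit$vars, fit$loglik)
  attr(out, "loglik_trace") <- fit$loglik_trace
  attr(out, "iterations") <- fit$iterations
  attr(out, "collapsed") <- fit$collapsed
  out
}

#' Per-pixel posterior probabilities under a fitted mixture
#'
#' Bayesian responsibilities
#' `p(k | x, theta) = alpha_k p_k(x) / sum_j alpha_j p_j(x)`, computed in
#' log-space.
#'
#' @param img An [intensity_image()].
#' @param theta A [gmm_params()].
#' @return A `posterior_map`: an `M x N x K` array; each pixel's posteriors
#'   sum to 1.
#' @export
posterior_map <- function(img, theta) {
  px <- as_pixel_matrix(img)
  x <- as.vector(px)
  K <- theta$K
  logd <- vapply(seq_len(K), function(k) {
    log(theta$weights[k]) +
      stats::dnorm(x, theta$means[k], sqrt(theta$variances[k]), log = TRUE)
  }, numeric(length(x)))
  if (K == 1L) logd <- matrix(logd, ncol = 1L)
  post <- exp(logd - logsumexp(logd))
  out <- array(post, dim = c(nrow(px), ncol(px), K))
  class(out) <- "posterior_map"
  attr(out, "theta") <- theta
  out
}

#' Bayesian probability-difference stopping map
#'
#' The boundary stopping function
#' `S = |p(nodule | x) - p(background | x)|`. S is close to 1 where one of
#' the two selected components clearly dominates and falls to 0 on the
#' class-ambiguity locus -- the (possibly blurred) nodule boundary -- so the
#' weighted contour-length term halts evolution there even when the intensity
#' gradient is weak.
#'
#' @param post A [posterior_map()].
#' @param nodule_k Index of the nodule component (default 2, the middle-mean
#'   component of a K = 3 fit).
#' @param background_k Index of the background component (default 1, the
#'   lowest-mean component).
#' @return A `stopping_map`: a matrix with values in [0, 1].
#' @export
stopping_map <- function(post, nodule_k = 2L, background_k = 1L) {
  stopifnot(inherits(post, "posterior_map"))
  K <- dim(post)[3L]
  nodule_k <- as.integer(nodule_k); background_k <- as.integer(background_k)
  if (nodule_k == background_k || nodule_k < 1L || background_k < 1L ||
      nodule_k > K || background_k > K) {
    stop("nodule_k and background_k must be distinct component indices <= K",
         call. = FALSE)
  }
  S <- abs(post[, , nodule_k] - post[, , background_k])
  structure(S, class = "stopping_map",
            nodule_k = nodule_k, background_k = background_k)
}

# Match mixture components to the two MRF classes: the nodule component is
# the one whose mean is closest to the class-2 (nodule) mean, the background
# component the one closest to the class-1 mean (resolved to a distinct
# component if both match the same one).
select_components <- function(theta, stats) {
  nod <- which.min(abs(theta$means - stats$means[2L]))
  bg <- which.min(abs(theta$means - stats$means[1L]))
  if (bg == nod) {
    others <- setdiff(seq_len(theta$K), nod)
    bg <- others[which.min(abs(theta$means[others] - stats$means[1L]))]
  }
  list(nodule_k = nod, background_k = bg)
}
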