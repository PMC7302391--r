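#' Smoothed Heaviside function
#'
#' `H(phi) = (1/2) (1 + (2/pi) atan(phi / epsilon))`, the regularised step
#' used to write the region membership of the level-set interior.
#'
#' @param phi Numeric (scalar, vector or matrix).
#' @param epsilon Smoothing width in pixel units (> 0).
#' @return Values in (0, 1), monotone increasing in `phi`.
#' @export
heaviside <- function(phi, epsilon = 1) {
  stopifnot(epsilon > 0)
  0.5 * (1 + (2 / pi) * atan(phi / epsilon))
}

#' Smoothed Dirac delta
#'
#' `delta(phi) = (epsilon / pi) / (epsilon^2 + phi^2)`, the derivative of
#' [heaviside()]; it localises contour forces in a band around the zero
#' level set.
#'
#' @inheritParams heaviside
#' @return Positive values, even in `phi`, peaked at 0 where
#'   `delta(0) = 1 / (pi * epsilon)`.
#' @export
dirac_delta <- function(phi, epsilon = 1) {
  stopifnot(epsilon > 0)
  (epsilon / pi) / (epsilon^2 + phi^2)
}

#' Active contour configuration
#'
#' @param lambda1,lambda2 Region-term weights (inside/outside); default 1.
#' @param mu Boundary (weighted length) term weight; default 1.
#' @param nu Distance-regularisation weight keeping `|grad phi| ~ 1`;
#'   default 1.
#' @param epsilon Heaviside/Dirac smoothing width in pixels; default 1.
#' @param dt Explicit Euler time step; default 0.1 (stable for the default
#'   weights, `dt * nu < 0.25`).
#' @param max_iter Iteration cap; default 500.
#' @param conv_tol Convergence tolerance: relative change of the integrated
#'   energy per iteration; evolution stops when below this for 10
#'   consecutive iterations. An energy-based criterion lets slow flows run
#'   to their own optimum instead of stopping at the (shared)
#'   initialization. Default 1e-4.
#' @param band Half-width (in pixels, on the value of `phi`) of the update
#'   band around the zero level set; `phi` is frozen outside it. Near the
#'   contour `|grad phi| ~ 1` and the distance-regularisation flow is
#'   well-posed; far from it (signed-distance ridges, image corners) the
#'   naive regulariser flow flattens the field, so updates are confined to
#'   where they are meaningful. Default 6; `Inf` disables banding.
#' @return An object of class `acm_config`.
#' @export
acm_config <- function(lambda1 = 1, lambda2 = 1, mu = 1, nu = 1,
                       epsilon = 1, dt = 0.1, max_iter = 500L,
                       conv_tol = 1e-4, band = 6) {
  if (any(c(lambda1, lambda2, mu, nu) < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (epsilon <= 0 || dt <= 0) stop("epsilon and dt must be > 0",
                                    call. = FALSE)
  if (band <= 0) stop("band must be > 0", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu,
                 epsilon = epsilon, dt = dt,
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 band = band),
            class = "acm_config")
}

#' Signed distance function of a mask
#'
#' Euclidean distance transform, positive inside the mask and negative
#' outside: at an interior pixel the distance to the nearest background
#' pixel, at an exterior pixel minus the distance to the nearest foreground
#' pixel.
#'
#' @param mask A [binary_mask()] (or 0/1 matrix) that is neither empty nor
#'   full.
#' @return A numeric matrix `phi` with `phi > 0` exactly on the mask.
#' @export
signed_distance <- function(mask) {
  m <- as_pixel_matrix(mask, "mask")
  if (all(m == 1) || all(m == 0)) {
    stop("mask must have both interior and exterior", call. = FALSE)
  }
  din <- EBImage::distmap(m)
  dout <- EBImage::distmap(1 - m)
  unclass(din - dout)
}

#' Initial level-set function
#'
#' Builds the initial contour from the pre-segmentation: the nodule-class
#' mask (`mode = "kmeans_mask"`, default) or the maximum-posterior mask of
#' the nodule mixture component (`mode = "bayes_mask"`); keeps the largest
#' connected component; returns its signed distance function. Starting from
#' a contour already near the nodule boundary is what lets the (non-convex)
#' evolution reach a good minimum reliably.
#'
#' @param labels2 Two-class [label_field()] (used by `"kmeans_mask"`).
#' @param post A [posterior_map()] (used by `"bayes_mask"`).
#' @param nodule_k Nodule component index for `"bayes_mask"`.
#' @param mode `"kmeans_mask"` or `"bayes_mask"`.
#' @return A numeric matrix `phi` (positive inside); the initial mask is
#'   attached as attribute `"mask"`.
#' @export
init_phi <- function(labels2 = NULL, post = NULL, nodule_k = 2L,
                     mode = c("kmeans_mask", "bayes_mask")) {
  mode <- match.arg(mode)
  m <- if (mode == "kmeans_mask") {
    if (is.null(labels2)) stop("labels2 required for kmeans_mask",
                               call. = FALSE)
    (as_pixel_matrix(labels2, "labels") == 2L) + 0
  } else {
    if (is.null(post)) stop("post required for bayes_mask", call. = FALSE)
    am <- apply(post, c(1L, 2L), which.max)
    (am == nodule_k) + 0
  }
  if (sum(m) == 0) {
    stop("initial nodule mask is empty; adjust the ROI or the class/",
         "component selection", call. = FALSE)
  }
  if (all(m == 1)) {
    stop("initial nodule mask covers the whole image (no exterior); ",
         "adjust the ROI", call. = FALSE)
  }
  cc <- EBImage::bwlabel(m)
  sizes <- tabulate(cc[cc > 0])
  m <- (cc == which.max(sizes)) + 0
  phi <- signed_distance(m)
  attr(phi, "mask") <- binary_mask(m)
  phi
}

# Central differences in the interior, one-sided at the image borders (a
# replicated-border central difference would halve the slope there and make
# even an exact signed distance function look irregular).
grad_central <- function(m) {
  M <- nrow(m); N <- ncol(m)
  up <- m[c(1L, seq_len(M - 1L)), , drop = FALSE]
  down <- m[c(seq_len(M - 1L) + 1L, M), , drop = FALSE]
  left <- m[, c(1L, seq_len(N - 1L)), drop = FALSE]
  right <- m[, c(seq_len(N - 1L) + 1L, N), drop = FALSE]
  dr <- (down - up) / 2
  dc <- (right - left) / 2
  dr[1L, ] <- dr[1L, ] * 2
  dr[M, ] <- dr[M, ] * 2
  dc[, 1L] <- dc[, 1L] * 2
  dc[, N] <- dc[, N] * 2
  list(dr = dr, dc = dc)
}

laplacian <- function(m) {
  M <- nrow(m); N <- ncol(m)
  up <- m[c(1L, seq_len(M - 1L)), , drop = FALSE]
  down <- m[c(seq_len(M - 1L) + 1L, M), , drop = FALSE]
  left <- m[, c(1L, seq_len(N - 1L)), drop = FALSE]
  right <- m[, c(seq_len(N - 1L) + 1L, N), drop = FALSE]
  up + down + left + right - 4 * m
}

#' Region means of the energy map
#'
#' Heaviside-weighted means of the region feature inside (`f1`) and outside
#' (`f2`) the current contour; these are the stationarity conditions of the
#' region term in the level-set energy.
#'
#' @param u An [energy_map()] (or matrix).
#' @param phi Level-set matrix.
#' @param epsilon Heaviside smoothing width.
#' @return List with elements `f1`, `f2`.
#' @export
region_means <- function(u, phi, epsilon = 1) {
  uu <- if (inherits(u, "energy_map")) u$energy else as_pixel_matrix(u)
  H <- heaviside(phi, epsilon)
  s1 <- sum(H); s2 <- sum(1 - H)
  if (s1 < 1e-8 || s2 < 1e-8) {
    stop("contour has collapsed: one region has vanishing area",
         call. = FALSE)
  }
  list(f1 = sum(uu * H) / s1, f2 = sum(uu * (1 - H)) / s2)
}

# One iteration's shared computation: the integrated energy of `phi` (with
# its four terms) and the explicit Euler update. Heaviside, Dirac, the
# gradient and the region means are computed once for both.
level_set_iter <- function(phi, uu, SS, cfg) {
  f <- region_means(uu, phi, cfg$epsilon)
  H <- heaviside(phi, cfg$epsilon)
  d <- dirac_delta(phi, cfg$epsilon)
  g <- grad_central(phi)
  gn <- sqrt(g$dr^2 + g$dc^2)
  terms <- c(region_in = cfg$lambda1 * sum((uu - f$f1)^2 * H),
             region_out = cfg$lambda2 * sum((uu - f$f2)^2 * (1 - H)),
             boundary = cfg$mu * sum(SS * d * gn),
             regular = cfg$nu * sum(0.5 * (gn - 1)^2))
  gn_f <- pmax(gn, 1e-10)
  nr <- g$dr / gn_f
  nc <- g$dc / gn_f
  div_S <- grad_central(SS * nr)$dr + grad_central(SS * nc)$dc
  div_1 <- grad_central(nr)$dr + grad_central(nc)$dc
  force <- d * (cfg$lambda2 * (uu - f$f2)^2 -
                  cfg$lambda1 * (uu - f$f1)^2) +
    cfg$mu * d * div_S +
    cfg$nu * (laplacian(phi) - div_1)
  phi_new <- phi + cfg$dt * force * (abs(phi) <= cfg$band)
  if (any(!is.finite(phi_new))) {
    stop("level-set update produced non-finite values; reduce dt",
         call. = FALSE)
  }
  list(energy = sum(terms), terms = terms, phi_new = phi_new)
}

as_feature_matrix <- function(u, like = NULL) {
  if (inherits(u, "energy_map")) return(u$energy)
  if (is.matrix(u)) return(unclass(u))
  matrix(u, nrow(like), ncol(like))
}

#' One explicit gradient-descent step of the contour evolution
#'
#' Updates `phi` by one explicit Euler step of the descent flow
#' `dphi/dt = delta(phi) (lambda2 (u - f2)^2 - lambda1 (u - f1)^2)
#'  + mu delta(phi) div(S grad(phi)/|grad(phi)|)
#'  + nu (lap(phi) - div(grad(phi)/|grad(phi)|))`
#' with `f1`, `f2` recomputed from the current `phi`. Central differences,
#' reflecting image borders, `|grad phi|` floored at 1e-10.
#'
#' @param phi Level-set matrix.
#' @param u An [energy_map()] (or matrix), the region feature.
#' @param S A `stopping_map` (or matrix), the boundary stopping function.
#' @param cfg An [acm_config()].
#' @return The updated `phi` matrix.
#' @export
evolve_step <- function(phi, u, S, cfg = acm_config()) {
  level_set_iter(phi, uu = as_feature_matrix(u, phi),
                 SS = as_feature_matrix(S, phi), cfg = cfg)$phi_new
}

#' Total integrated energy of the contour
#'
#' The discrete (unit pixel quadrature) value of the integrated active
#' contour energy:
#' `lambda1 int (u - f1)^2 H + lambda2 int (u - f2)^2 (1 - H)
#'  + mu int S delta(phi) |grad phi| + nu int (1/2)(|grad phi| - 1)^2`.
#'
#' @inheritParams evolve_step
#' @return The scalar energy, with the four terms in attribute `"terms"`.
#' @export
total_energy <- function(phi, u, S, cfg = acm_config()) {
  it <- level_set_iter(phi, uu = as_feature_matrix(u, phi),
                       SS = as_feature_matrix(S, phi), cfg = cfg)
  structure(it$energy, terms = it$terms)
}

#' Evolve the contour to convergence
#'
#' Iterates [evolve_step()] until the relative change of the integrated
#' energy stays below `cfg$conv_tol` for 10 consecutive iterations, or
#' `cfg$max_iter` is reached. The final mask is `phi > 0`.
#'
#' @param phi0 Initial level-set matrix (see [init_phi()]).
#' @inheritParams evolve_step
#' @return List with elements `phi`, `mask` (a [binary_mask()]), `trace`
#'   (per-iteration total energy), `iterations`, `converged`.
#' @export
evolve_contour <- function(phi0, u, S, cfg = acm_config()) {
  uu <- as_feature_matrix(u, phi0)
  SS <- as_feature_matrix(S, phi0)
  phi <- phi0
  step <- level_set_iter(phi, uu, SS, cfg)
  e_prev <- step$energy            # energy at phi0
  trace <- numeric(cfg$max_iter)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iter) {
    it <- it + 1L
    phi <- step$phi_new
    step <- level_set_iter(phi, uu, SS, cfg)
    trace[it] <- step$energy       # energy after the it-th update
    rel <- abs(trace[it] - e_prev) / (abs(e_prev) + 1e-12)
    e_prev <- trace[it]
    stable <- if (rel < cfg$conv_tol) stable + 1L else 0L
    if (stable >= 10L) {
      converged <- TRUE
      break
    }
  }
  list(phi = phi, mask = binary_mask((phi > 0) + 0),
       trace = trace[seq_len(it)], iterations = it, converged = converged)
}
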