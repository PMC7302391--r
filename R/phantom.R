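#' Synthetic GGO phantom specification
#'
#' Describes a seeded synthetic ground-glass-opacity nodule image. The
#' scenarios reproduce the classic challenge cases for small GGO nodules:
#' low contrast (`isolated`), intensity inhomogeneity (`inhomogeneous`),
#' blurred boundary (`blurred`), vascular adhesion (`vessel`), pleural
#' adhesion (`pleura`), adjacent highlight tissue (`highlight`) and internal
#' dark spots from bubbles or necrosis (`dark_spots`).
#'
#' @param size Image size `(M, N)`, default `c(64, 64)`.
#' @param scenario One of `"isolated"`, `"inhomogeneous"`, `"blurred"`,
#'   `"vessel"`, `"pleura"`, `"highlight"`, `"dark_spots"`.
#' @param nodule_center `(row, col)` of the nodule centre (1-based);
#'   default: image centre (for `"pleura"`: shifted towards the left border
#'   so the pleural band touches the nodule).
#' @param nodule_radius Minimal nodule radius in pixels (>= 2); irregular
#'   lobes extend outward from this radius.
#' @param contrast Nodule-minus-background mean intensity in normalized
#'   units; default 0.2 (the low-contrast regime).
#' @param blur_sigma Gaussian blur of the nodule boundary in pixels (used by
#'   `"blurred"`); default 2.
#' @param gradient_strength Peak-to-peak amplitude of the linear intensity
#'   ramp (used by `"inhomogeneous"`); default 0.3, which carries the
#'   bright-end background up to nodule-like intensities so that global
#'   intensity statistics alone cannot separate the classes.
#' @param noise_sd Additive Gaussian noise standard deviation; default 0.05.
#' @param irregularity Relative amplitude of the outward radial shape
#'   perturbation (0 = perfect disk); default 0.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64L, 64L), scenario = "isolated",
                         nodule_center = NULL, nodule_radius = 6,
                         contrast = 0.2, blur_sigma = 2,
                         gradient_strength = 0.3, noise_sd = 0.05,
                         irregularity = 0, seed = 1L) {
  scenario <- match.arg(scenario, phantom_scenarios())
  size <- as.integer(size)
  if (nodule_radius < 2) stop("nodule_radius must be >= 2 px", call. = FALSE)
  if (contrast <= 0 || contrast > 1) {
    stop("contrast must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(nodule_center)) {
    nodule_center <- if (scenario == "pleura") {
      c(round(size[1L] / 2), round(5 + nodule_radius))
    } else {
      c(round(size[1L] / 2), round(size[2L] / 2))
    }
  }
  rmax <- nodule_radius * (1 + irregularity)
  if (nodule_center[1L] - rmax < 2 || nodule_center[1L] + rmax > size[1L] - 1 ||
      nodule_center[2L] - rmax < 2 || nodule_center[2L] + rmax > size[2L] - 1) {
    stop("nodule (radius ", nodule_radius, ") does not fit inside the image",
         call. = FALSE)
  }
  structure(list(size = size, scenario = scenario,
                 nodule_center = as.numeric(nodule_center),
                 nodule_radius = nodule_radius, contrast = contrast,
                 blur_sigma = blur_sigma,
                 gradient_strength = gradient_strength, noise_sd = noise_sd,
                 irregularity = irregularity, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
phantom_scenarios <- function() {
  c("isolated", "inhomogeneous", "blurred", "vessel", "pleura", "highlight",
    "dark_spots")
}

BACKGROUND_LEVEL <- 0.25
BRIGHT_LEVEL <- 0.85
DARK_LEVEL <- 0.15

# Rasterize a 2-px-wide curve leaving the nodule rim radially outward with a
# sinusoidal wiggle, stopping at the image border.
draw_vessel <- function(img, spec, indicator) {
  M <- spec$size[1L]; N <- spec$size[2L]
  ci <- spec$nodule_center[1L]; cj <- spec$nodule_center[2L]
  ang <- stats::runif(1, 0, 2 * pi)
  wig_amp <- stats::runif(1, 0.1, 0.3)
  wig_freq <- stats::runif(1, 0.1, 0.3)
  t <- seq(0, max(M, N), by = 0.25)
  a <- ang + wig_amp * sin(wig_freq * t)
  ri <- ci + (spec$nodule_radius - 1 + t) * sin(a)
  rj <- cj + (spec$nodule_radius - 1 + t) * cos(a)
  keep <- ri >= 1 & ri <= M & rj >= 1 & rj <= N
  for (p in which(keep)) {
    for (di in 0:1) {
      for (dj in 0:1) {
        i <- round(ri[p]) + di; j <- round(rj[p]) + dj
        if (i >= 1 && i <= M && j >= 1 && j <= N && indicator[i, j] == 0) {
          img[i, j] <- BRIGHT_LEVEL
        }
      }
    }
  }
  img
}

#' Generate a synthetic GGO phantom
#'
#' Builds the image and its ground-truth mask. The background sits at mean
#' 0.25 and the nodule at `0.25 + contrast`; scenario modifiers add an
#' intensity ramp, boundary blur, a bright vessel touching the rim, a bright
#' pleural band, an adjacent bright blob, or dark internal spots. Gaussian
#' noise is added last and the image is clipped to [0, 1]. The truth mask is
#' the unblurred nodule indicator (dark spots included: they are part of the
#' nodule, as a radiologist would outline it).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `image` (an [intensity_image()]), `mask` (a
#'   [binary_mask()]) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$size[1L]; N <- spec$size[2L]
  with_seed(spec$seed, {
    ci <- spec$nodule_center[1L]; cj <- spec$nodule_center[2L]
    ii <- matrix(seq_len(M), M, N)
    jj <- matrix(seq_len(N), M, N, byrow = TRUE)
    rr <- sqrt((ii - ci)^2 + (jj - cj)^2)
    th <- atan2(ii - ci, jj - cj)
    # outward-only radial perturbation: nodule_radius is the minimal radius
    radius_theta <- matrix(spec$nodule_radius, M, N)
    if (spec$irregularity > 0) {
      a2 <- stats::runif(1); a3 <- stats::runif(1)
      p2 <- stats::runif(1, 0, 2 * pi); p3 <- stats::runif(1, 0, 2 * pi)
      w <- a2 * cos(2 * th + p2) + a3 * cos(3 * th + p3)
      w <- (w / max(a2 + a3, 1e-12) + 1) / 2        # in [0, 1]
      radius_theta <- spec$nodule_radius * (1 + spec$irregularity * w)
    }
    indicator <- (rr <= radius_theta) + 0
    truth <- indicator

    if (spec$scenario == "blurred") {
      soft <- EBImage::gblur(indicator, sigma = spec$blur_sigma)
      img <- BACKGROUND_LEVEL + spec$contrast * soft
    } else {
      img <- BACKGROUND_LEVEL + spec$contrast * indicator
    }

    if (spec$scenario == "inhomogeneous") {
      ramp <- spec$gradient_strength * ((jj - 1) / (N - 1) - 0.5)
      img <- img + ramp
    }
    if (spec$scenario == "vessel") {
      img <- draw_vessel(img, spec, indicator)
    }
    if (spec$scenario == "pleura") {
      band_w <- max(1L, as.integer(round(cj - spec$nodule_radius)))
      img[, seq_len(band_w)][indicator[, seq_len(band_w)] == 0] <-
        BRIGHT_LEVEL
    }
    if (spec$scenario == "highlight") {
      gap <- 3; rh <- 3
      ang <- stats::runif(1, 0, 2 * pi)
      hc <- c(ci + (spec$nodule_radius + gap + rh) * sin(ang),
              cj + (spec$nodule_radius + gap + rh) * cos(ang))
      hc <- pmin(pmax(hc, rh + 1), c(M, N) - rh)
      hd <- sqrt((ii - hc[1L])^2 + (jj - hc[2L])^2)
      img[hd <= rh & indicator == 0] <- BRIGHT_LEVEL
    }
    if (spec$scenario == "dark_spots") {
      n_spots <- sample(1:3, 1)
      for (s in seq_len(n_spots)) {
        sr <- stats::runif(1, 1, 2)
        da <- stats::runif(1, 0, 2 * pi)
        dd <- stats::runif(1, 0, max(spec$nodule_radius - sr - 1, 0))
        sc <- c(ci + dd * sin(da), cj + dd * cos(da))
        sd2 <- sqrt((ii - sc[1L])^2 + (jj - sc[2L])^2)
        img[sd2 <= sr & indicator == 1] <- DARK_LEVEL
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(M * N, 0, spec$noise_sd)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = intensity_image(img), mask = binary_mask(truth),
         spec = spec)
  })
}

#' Deterministic phantom suite
#'
#' Generates `n_per_scenario` phantoms for each scenario with jittered
#' minimal radius (uniform 3--8 px, the small-nodule regime), contrast
#' (uniform 0.15--0.25) and shape irregularity (uniform 0--0.1), all derived
#' from `base_seed`.
#'
#' @param n_per_scenario Cases per scenario (>= 1).
#' @param base_seed Integer master seed (keep below ~2e6).
#' @return List of `length(phantom_scenarios()) * n_per_scenario` elements,
#'   each a [make_phantom()] result.
#' @export
make_suite <- function(n_per_scenario = 20L, base_seed = 1L) {
  stopifnot(n_per_scenario >= 1L)
  out <- list()
  for (si in seq_along(phantom_scenarios())) {
    scen <- phantom_scenarios()[si]
    for (i in seq_len(n_per_scenario)) {
      case_seed <- as.integer(base_seed) * 1000L + si * 100L + i
      jit <- with_seed(case_seed, {
        list(radius = stats::runif(1, 3, 8),
             contrast = stats::runif(1, 0.15, 0.25),
             irregularity = stats::runif(1, 0, 0.1))
      })
      spec <- phantom_spec(scenario = scen, nodule_radius = jit$radius,
                           contrast = jit$contrast,
                           irregularity = jit$irregularity,
                           seed = case_seed + 499979L)
      out[[length(out) + 1L]] <- make_phantom(spec)
    }
  }
  out
}
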