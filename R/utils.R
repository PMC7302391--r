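# Internal numerical helpers shared across modules.

# Evaluate code with a temporarily seeded RNG, restoring the caller's
# random-number state afterwards so generators are pure functions of their
# seed argument.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

logsumexp <- function(m) {
  # row-wise log(sum(exp(m))) for a matrix of log terms
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# k-means++ seeding for 1-D data; returns K starting centers.
kmeanspp_centers <- function(x, K) {
  n <- length(x)
  centers <- numeric(K)
  centers[1L] <- x[sample.int(n, 1L)]
  if (K > 1L) {
    d2 <- (x - centers[1L])^2
    for (k in 2L:K) {
      p <- d2 / sum(d2)
      centers[k] <- x[sample.int(n, 1L, prob = p)]
      d2 <- pmin(d2, (x - centers[k])^2)
    }
  }
  centers
}

# Seeded 1-D K-means: k-means++ starts, Lloyd iterations, best of n_restarts
# by total within-cluster sum of squares. Returns integer assignments 1..K
# renumbered so cluster means increase with the label.
seeded_kmeans <- function(x, K, seed, n_restarts = 5L) {
  stopifnot(K >= 1L, n_restarts >= 1L)
  if (length(unique(x)) < K) {
    stop("fewer than K = ", K, " distinct values; K-means is degenerate",
         call. = FALSE)
  }
  if (K == 1L) {
    return(list(cluster = rep(1L, length(x)), centers = mean(x),
                tot.withinss = sum((x - mean(x))^2)))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cen <- kmeanspp_centers(x, K)
      # perturb duplicate starts (possible when sampling discrete data)
      while (anyDuplicated(cen)) {
        cen[duplicated(cen)] <- cen[duplicated(cen)] +
          stats::runif(sum(duplicated(cen)), -1e-8, 1e-8)
      }
      fit <- suppressWarnings(
        stats::kmeans(x, centers = matrix(sort(cen), ncol = 1L),
                      iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    ord <- order(best$centers[, 1L])
    relabel <- integer(K)
    relabel[ord] <- seq_len(K)
    list(cluster = relabel[best$cluster],
         centers = unname(sort(best$centers[, 1L])),
         tot.withinss = best$tot.withinss)
  })
}

# Shifted copy of a matrix: entry [i, j] becomes m[i + dr, j + dc] where the
# source exists, NA outside (used for truncated-neighbourhood sums).
shift_mat <- function(m, dr, dc) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(NA_real_, M, N)
  ri <- max(1L, 1L - dr):min(M, M - dr)
  ci <- max(1L, 1L - dc):min(N, N - dc)
  if (length(ri) > 0L && length(ci) > 0L) {
    out[ri, ci] <- m[ri + dr, ci + dc]
  }
  out
}

neighbourhood_offsets <- function(neighbourhood) {
  if (neighbourhood == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
         c(0L, -1L),               c(0L, 1L),
         c(1L, -1L),  c(1L, 0L),  c(1L, 1L))
  }
}

# For each pixel, number of in-bounds neighbours whose label differs from
# `ref`: either a scalar label hypothesis or a matrix (the pixel's own label).
count_discordant <- function(labels, ref, neighbourhood = 8L) {
  acc <- matrix(0, nrow(labels), ncol(labels))
  for (off in neighbourhood_offsets(neighbourhood)) {
    s <- shift_mat(labels, off[1L], off[2L])
    d <- (s != ref)
    d[is.na(d)] <- FALSE
    acc <- acc + d
  }
  acc
}

as_pixel_matrix <- function(x, what = "image") {
  if (inherits(x, "intensity_image")) return(x$pixels)
  if (inherits(x, "label_field")) return(x$labels)
  if (inherits(x, "binary_mask")) return(unclass(x))
  if (is.matrix(x)) return(x)
  stop("cannot interpret input as a ", what, " matrix", call. = FALSE)
}
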