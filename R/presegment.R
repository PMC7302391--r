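#' Label field
#'
#' Per-pixel class labels in `1..L`.
#'
#' @param labels Integer matrix of labels.
#' @param L Number of classes.
#' @return An object of class `label_field`.
#' @export
label_field <- function(labels, L) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  L <- as.integer(L)
  if (any(labels < 1L | labels > L)) {
    stop("labels must lie in 1..", L, call. = FALSE)
  }
  structure(list(labels = matrix(as.integer(labels), nrow(labels)), L = L),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("<label_field %d x %d, L = %d, counts: %s>\n",
              nrow(x$labels), ncol(x$labels), x$L,
              paste(tabulate(x$labels, x$L), collapse = "/")))
  invisible(x)
}

#' K-means pre-segmentation
#'
#' Scalar-intensity K-means clustering of the image into `K` classes, the
#' first step of the MRF energy computation. The initial labelling confines
#' the subsequent (one-shot) MRF refinement to the neighbourhood of a good
#' solution instead of a full combinatorial optimisation. Labels are
#' renumbered so cluster mean intensity increases with the label (1 =
#' darkest). k-means++ starts, Lloyd iterations, best of `n_restarts` by
#' within-cluster sum of squares; deterministic given `seed`.
#'
#' @param img An [intensity_image()] (or matrix).
#' @param K Number of clusters (default 3: lung parenchyma, nodule, bright
#'   tissue such as vessels/pleura).
#' @param seed Integer RNG seed.
#' @param n_restarts Number of seeded restarts.
#' @return A [label_field()] with `L = K`; cluster mean intensities are
#'   attached as attribute `"means"`.
#' @export
kmeans_presegment <- function(img, K = 3L, seed = 1L, n_restarts = 5L) {
  px <- as_pixel_matrix(img)
  fit <- seeded_kmeans(as.vector(px), K, seed = seed, n_restarts = n_restarts)
  lf <- label_field(matrix(fit$cluster, nrow(px)), K)
  attr(lf, "means") <- fit$centers
  lf
}

# 4-neighbour perimeter of a 0/1 matrix; image border counts as exposed.
mask_perimeter <- function(m) {
  per <- 0
  for (off in neighbourhood_offsets(4L)) {
    s <- shift_mat(m, off[1L], off[2L])
    s[is.na(s)] <- 0
    per <- per + sum(m == 1 & s == 0)
  }
  per
}

# Iterated 3x3 majority vote on a 0/1 matrix (outside the image counts as
# 0). Robust denoising of a cluster mask: solid blobs survive even when
# noise drops a fraction of their pixels into another cluster, while
# scattered pixels are removed.
majority_smooth <- function(m, passes = 2L) {
  for (p in seq_len(passes)) {
    acc <- m
    for (off in neighbourhood_offsets(8L)) {
      s <- shift_mat(m, off[1L], off[2L])
      s[is.na(s)] <- 0
      acc <- acc + s
    }
    m <- (acc >= 5) + 0
  }
  m
}

# Surrounding ring of a region: dilation band excluding the region and its
# immediate 1-px neighbourhood.
region_ring <- function(m) {
  outer <- EBImage::dilate(m, EBImage::makeBrush(9L, "disc"))
  inner <- EBImage::dilate(m, EBImage::makeBrush(3L, "box"))
  outer == 1 & inner == 0
}

# Local contrast of a candidate region: mean of the blurred image over the
# region minus the median over a surrounding ring. Blurring first removes
# the selection bias of intensity-thresholded noise clumps (whose raw pixel
# values are high by construction); the median makes the reference robust
# to bright tissue on one side of the nodule.
region_local_contrast <- function(m, blurred) {
  ring <- region_ring(m)
  if (!any(ring)) return(0)
  mean(blurred[m == 1]) - stats::median(blurred[ring])
}

# Refine the chosen nodule region by local intensity: majority smoothing can
# accrete a halo of upper-background pixels onto the nodule when K-means has
# merged both into one cluster. Re-threshold a lightly blurred image halfway
# between the region-core mean and the surrounding-ring median (bounded
# above to exclude bright tissue), keep the connected component overlapping
# the core, and fill interior holes (dark spots belong to the nodule).
# Thresholding the *blurred* image at the midpoint keeps the 50%-crossing
# location of a blurred boundary, so this is consistent with a pre-blur
# ground truth.
refine_nodule_region <- function(m, px, rblur = EBImage::gblur(px, sigma = 1)) {
  core <- EBImage::erode(m, EBImage::makeBrush(3L, "box"))
  if (sum(core) < 4) core <- m
  ring <- region_ring(m)
  if (!any(ring)) return(m)
  # upper quartile as the plateau estimate: when the candidate has already
  # accreted halo pixels (blurred boundaries), its plain core mean is
  # diluted below the plateau and the midpoint threshold over-grows
  mc <- stats::quantile(rblur[core == 1], 0.75, names = FALSE)
  rm <- stats::median(rblur[ring])
  if (mc <= rm) return(m)
  lo <- (mc + rm) / 2
  hi <- mc + (mc - rm)
  # the raw-value bound removes bright tissue whose *blurred* edge falls in
  # the window; the opening then cuts the thin intermediate ribbons that
  # blurring leaves along bright-tissue borders
  cand <- (rblur >= lo & rblur <= hi & px <= hi) + 0
  cand <- EBImage::opening(cand, EBImage::makeBrush(3L, "box"))
  cc <- EBImage::bwlabel(cand)
  ov <- cc[core == 1]
  ov <- ov[ov > 0]
  if (length(ov) == 0) return(m)
  comp <- as.integer(names(which.max(table(ov))))
  refined <- EBImage::fillHull((cc == comp) + 0)
  a0 <- sum(m); a1 <- sum(refined)
  if (a1 < 0.3 * a0 || a1 > 3 * a0) return(m)  # refinement went wild
  refined
}

#' Reduce a K-cluster labelling to the two MRF classes
#'
#' Maps the 3-cluster pre-segmentation onto the 2-class field used by the
#' MRF (class 2 = nodule, class 1 = background, i.e. parenchyma merged with
#' any bright or dark tissue). Which cluster carries the nodule depends on
#' the scene: with bright tissue present (vessels, pleura, highlight) the
#' nodule sits in the middle-mean cluster -- possibly merged with the upper
#' background mode, since K-means must spend a cluster on the bright tissue
#' -- while on isolated low-contrast scenes the background mode splits in
#' two and the nodule is the brightest cluster. The reduction therefore
#' scores candidate *regions*, not whole clusters: each cluster mask is
#' morphologically opened (3 x 3 box) to suppress scattered noise pixels,
#' its connected components of plausible nodule size (12 px to 20% of the
#' image) become candidates, and each candidate is scored by compactness
#' (`4*pi*area/perimeter^2`), a soft size factor, and an intensity-order
#' prior (middle-mean cluster preferred, then brightest, then darkest).
#' The winning region, with interior holes filled (dark spots from bubbles
#' or necrosis belong to the nodule), becomes class 2. If no candidate
#' exists, the middle-mean cluster is used wholesale.
#'
#' @param labels3 A [label_field()] from [kmeans_presegment()].
#' @param img The matching [intensity_image()] (used for cluster means).
#' @return A [label_field()] with `L = 2`; the selection is recorded in
#'   attribute `"policy"`.
#' @export
reduce_to_two_classes <- function(labels3, img) {
  stopifnot(inherits(labels3, "label_field"))
  px <- as_pixel_matrix(img)
  lab <- labels3$labels
  present <- sort(unique(as.vector(lab)))
  if (length(present) == 1L) {
    out <- label_field(matrix(1L, nrow(lab), ncol(lab)), 2L)
    attr(out, "policy") <- list(nodule_cluster = NA_integer_,
                                rule = "single cluster: all background")
    return(out)
  }
  means <- vapply(present, function(k) mean(px[lab == k]), numeric(1))
  ord <- order(means)  # present clusters from darkest to brightest
  # intensity-order prior: middle preferred, then brightest, then darkest.
  # A distinctly bright cluster (normalized mean > 0.75) is solid tissue --
  # vessels, pleura, highlight -- and is never a GGO nodule candidate.
  prior <- numeric(length(present))
  top_bright <- means[ord[length(ord)]] > 0.75
  if (length(present) == 3L) {
    prior[ord] <- c(0.3, 1, if (top_bright) 0 else 0.5)
  } else {
    prior[ord] <- c(0.7, if (top_bright) 0 else 1)
  }
  min_area <- 12
  max_area <- 0.2 * length(lab)
  blurred <- EBImage::gblur(px, sigma = 1.5)
  rblur <- EBImage::gblur(px, sigma = 1)
  best <- list(score = 0, mask = NULL, cluster = NA_integer_)
  for (i in seq_along(present)) {
    cleaned <- majority_smooth((lab == present[i]) + 0)
    cc <- EBImage::bwlabel(cleaned)
    sizes <- tabulate(cc[cc > 0])
    for (comp in which(sizes >= min_area & sizes <= max_area)) {
      # refine each candidate by local intensity before scoring, so a
      # nodule that smoothing left with accreted tendrils still presents
      # as the compact blob it is
      m <- refine_nodule_region((cc == comp) + 0, px, rblur)
      a <- sum(m)
      if (a < min_area || a > max_area) next
      compact <- min(4 * pi * a / max(mask_perimeter(m), 1)^2, 1)
      lc <- region_local_contrast(m, blurred)
      score <- prior[i] * compact * min(1, a / 40) *
        min(1, max(lc, 0) / 0.1)
      if (score > best$score) {
        best <- list(score = score, mask = m, cluster = present[i])
      }
    }
  }
  if (best$score > 0) {
    nodule_mask <- EBImage::fillHull(best$mask)
    rule <- "max nodule-likeness region score"
  } else {
    # fall back to the intensity-order prior alone
    nod <- if (length(present) == 3L) present[ord[2L]] else
      present[ord[length(ord)]][1L]
    nodule_mask <- (lab == nod) + 0
    best$cluster <- nod
    rule <- "fallback: intensity-order prior"
  }
  out <- label_field(nodule_mask + 1L, 2L)
  attr(out, "policy") <- list(nodule_cluster = best$cluster, rule = rule,
                              cluster_means = means, score = best$score)
  out
}
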