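#' Pixelwise confusion counts
#'
#' Counts of true/false positives/negatives of a predicted mask against a
#' reference (gold-standard) mask.
#'
#' @param pred,truth [binary_mask()] objects (or 0/1 matrices) of equal
#'   shape.
#' @return An object of class `confusion_counts` with elements `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  p <- as_pixel_matrix(pred, "mask")
  t <- as_pixel_matrix(truth, "mask")
  if (!identical(dim(p), dim(t))) {
    stop("pred and truth must have the same shape", call. = FALSE)
  }
  structure(list(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
                 FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion TP=%d FP=%d FN=%d TN=%d>\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Intersection over union
#'
#' `IOU = |A ∩ B| / |A ∪ B| = TP / (TP + FP + FN)`; the standard overlap
#' score between an automatic segmentation and the gold standard. Larger is
#' better; 1 means perfect agreement.
#'
#' @inheritParams confusion
#' @return A number in [0, 1].
#' @export
iou <- function(pred, truth) {
  cc <- confusion(pred, truth)
  denom <- cc$TP + cc$FP + cc$FN
  if (denom == 0) {
    stop("IOU is undefined: both masks are empty", call. = FALSE)
  }
  cc$TP / denom
}

#' Combine two raters' masks into a gold standard
#'
#' @inheritParams confusion
#' @param maskA,maskB The two raters' masks.
#' @param rule `"union"` (default), `"intersection"`, or `"vote"` (majority,
#'   ties included; identical to union for two raters).
#' @return A [binary_mask()]; the rule is recorded in attribute `"rule"`.
#' @export
merge_gold <- function(maskA, maskB, rule = c("union", "intersection",
                                              "vote")) {
  rule <- match.arg(rule)
  a <- as_pixel_matrix(maskA, "mask")
  b <- as_pixel_matrix(maskB, "mask")
  if (!identical(dim(a), dim(b))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  m <- switch(rule,
              union = (a + b > 0) + 0,
              intersection = (a + b == 2) + 0,
              vote = (a + b >= 1) + 0)
  out <- binary_mask(m)
  attr(out, "rule") <- rule
  out
}
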