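#' Threshold-based tissue segmentation
#'
#' Multi-level Otsu thresholding of a grayscale microCT volume into
#' `n_classes` intensity classes, honoring the semi-automatic contract of
#' threshold segmentation in virtual dental histology: the automatically
#' chosen thresholds are reported and can be overridden with manually
#' picked values. Classes are assigned to tissues in order of increasing
#' intensity (background < dentine < enamel for teeth; background < bone
#' for postcranial elements).
#'
#' @param gray a [gray_volume].
#' @param n_classes number of intensity classes (2 or 3).
#' @param thresholds optional numeric vector of `n_classes - 1` manual
#'   thresholds (a voxel with value v gets class `sum(v > thresholds)`).
#' @param semantics label semantics to stamp on the result; defaults to
#'   [tooth_semantics()] for 3 classes and [bone_semantics()] for 2.
#' @param n_bins histogram resolution for the Otsu search.
#' @return a [label_volume] with attribute `thresholds` (the thresholds
#'   actually used).
#' @export
segment_tissues <- function(gray, n_classes = 3, thresholds = NULL,
                            semantics = NULL, n_bins = 256) {
  stopifnot(inherits(gray, "gray_volume"))
  if (!n_classes %in% 2:3) .pc_stop("`n_classes` must be 2 or 3")
  if (is.null(semantics))
    semantics <- if (n_classes == 3) tooth_semantics() else bone_semantics()
  if (length(semantics) != n_classes)
    .pc_stop("semantics must declare exactly %d labels", n_classes)
  v <- as.vector(gray$data)
  if (is.null(thresholds)) {
    if (stats::sd(v) == 0)
      .pc_stop("degenerate histogram: intensity sd = 0, no threshold separates %d classes",
               n_classes)
    if (length(unique(v)) < n_classes)
      .pc_stop("degenerate histogram: only %d distinct intensities for %d classes",
               length(unique(v)), n_classes)
    thresholds <- .multi_otsu(v, n_classes, n_bins)
  } else if (length(thresholds) != n_classes - 1L) {
    .pc_stop("need %d manual thresholds for %d classes", n_classes - 1L,
             n_classes)
  }
  thresholds <- sort(thresholds)
  cls <- array(0L, dim(gray$data))
  for (t in thresholds) cls <- cls + (gray$data > t)
  lab <- array(unname(sort(semantics))[cls + 1L], dim(gray$data))
  out <- label_volume(lab, gray$voxel_mm, semantics)
  attr(out, "thresholds") <- thresholds
  out
}

# exhaustive multi-level Otsu on an n_bins histogram:
# maximize between-class variance = sum_k w_k (mu_k - mu)^2
.multi_otsu <- function(v, n_classes, n_bins) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mid <- (br[-1] + br[-length(br)]) / 2
  P <- cumsum(p)                      # class mass up to bin i
  S <- cumsum(p * mid)                # first moment up to bin i
  cw <- function(i, j) {              # weight / mean of bins (i+1)..j
    w <- P[j] - if (i > 0) P[i] else 0
    m <- S[j] - if (i > 0) S[i] else 0
    c(w, if (w > 0) m / w else 0)
  }
  best <- -Inf; best_t <- NULL
  if (n_classes == 2L) {
    for (i in 1:(n_bins - 1L)) {
      a <- cw(0L, i); b <- cw(i, n_bins)
      if (a[1] == 0 || b[1] == 0) next
      fit <- a[1] * b[1] * (a[2] - b[2])^2
      if (fit > best) { best <- fit; best_t <- br[i + 1L] }
    }
  } else {
    mu <- S[n_bins]
    for (i in 1:(n_bins - 2L)) {
      a <- cw(0L, i)
      if (a[1] == 0) next
      for (j in (i + 1L):(n_bins - 1L)) {
        b <- cw(i, j); c3 <- cw(j, n_bins)
        if (b[1] == 0 || c3[1] == 0) next
        fit <- a[1] * (a[2] - mu)^2 + b[1] * (b[2] - mu)^2 +
          c3[1] * (c3[2] - mu)^2
        if (fit > best) { best <- fit; best_t <- c(br[i + 1L], br[j + 1L]) }
      }
    }
  }
  if (is.null(best_t))
    .pc_stop("degenerate histogram: Otsu search found no admissible thresholds")
  best_t
}
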