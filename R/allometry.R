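#' Allometry testing on shape scores
#'
#' Regresses shape scores (typically bgPC scores) on log centroid size,
#' axis by axis, reporting slope, R-squared and the F-test p-value. A
#' significant slope indicates allometry: size-related shape variation.
#'
#' @param scores matrix (n x axes) or vector of shape scores.
#' @param csize centroid sizes (length n), as carried by a `shape_set`.
#' @param log_size regress on log(csize) (default) or raw csize.
#' @return data frame of class `allometry_result` with columns `axis`,
#'   `slope`, `r_squared`, `p_value`, and attribute `predictor`.
#' @export
test_allometry <- function(scores, csize, log_size = TRUE) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 4L) .pc_stop("allometry test needs n >= 4")
  if (length(csize) != nrow(scores))
    .pc_stop("`csize` length does not match the score rows")
  if (stats::var(csize) == 0)
    .pc_stop("zero variance in centroid size")
  x <- if (log_size) log(csize) else csize
  out <- do.call(rbind, lapply(seq_len(ncol(scores)), function(j) {
    fit <- stats::lm(scores[, j] ~ x)
    sm <- summary(fit)
    pv <- if (sm$r.squared >= 1 - 1e-12) 0 else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    data.frame(axis = j, slope = unname(coef(fit)[2]),
               r_squared = sm$r.squared, p_value = unname(pv))
  }))
  attr(out, "predictor") <- if (log_size) "log centroid size" else
    "centroid size"
  class(out) <- c("allometry_result", "data.frame")
  out
}
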