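#' Synthetic standard skeleton
#'
#' A synthetic osteometric standard emulating a complete adult female wolf
#' skeleton: one value per von den Driesch measurement code across the main
#' postcranial elements, in mm. The values are invented but sized for a
#' wolf of roughly 67 cm shoulder height; they exist so that generated
#' populations have a fixed, known reference.
#'
#' @return a [measurement_table] for the single standard individual.
#' @export
canid_standard <- function() {
  df <- data.frame(
    specimen_id = "STD",
    population = "standard",
    skeletal_element = c(
      "humerus", "humerus", "humerus", "humerus",
      "radius", "radius", "radius",
      "ulna", "femur", "femur", "femur",
      "tibia", "tibia", "tibia",
      "metacarpal_1", "metacarpal_3", "metacarpal_3",
      "metatarsal_3", "metatarsal_3", "phalanx_1", "phalanx_1"),
    code = c("GL", "Bp", "Bd", "SD",
             "GL", "Bp", "Bd",
             "GL", "GL", "Bp", "Bd",
             "GL", "Bp", "Bd",
             "GL", "GL", "Bd",
             "GL", "Bd", "GL", "Bp"),
    value = c(197.0, 43.5, 37.0, 14.5,
              196.0, 26.5, 34.0,
              232.0, 214.0, 46.0, 38.5,
              218.0, 41.5, 28.0,
              23.5, 86.0, 10.5,
              92.0, 11.0, 31.0, 9.5),
    flags = "",
    stringsAsFactors = FALSE)
  # one measurement code per (element, code) pair; make specimen keys unique
  df$specimen_id <- "STD"
  df$code <- paste(df$skeletal_element, df$code, sep = ".")
  measurement_table(df)
}

#' Generate a synthetic osteometric measurement table
#'
#' Each population scales every standard measurement by its `size_factor`
#' and multiplies by mean-one lognormal noise with coefficient of variation
#' `noise_cv`, so that the expected log10 ratio against the standard is
#' (up to a small lognormal bias term that vanishes with `noise_cv`)
#' `log10(size_factor)` for every measurement.
#'
#' @param populations data frame with columns `label`, `size_factor`, `n`
#'   (individuals per population).
#' @param standard a [measurement_table]; defaults to [canid_standard()].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return a [measurement_table] with attribute `truth` (the generating
#'   parameters).
#' @export
gen_measurement_table <- function(populations, standard = canid_standard(),
                                  noise_cv = 0.05, seed = 1) {
  stopifnot(is.data.frame(populations),
            all(c("label", "size_factor", "n") %in% names(populations)))
  if (any(populations$n < 1))
    .pc_stop("every population must have n >= 1 (got n = %d for '%s')",
             min(populations$n),
             populations$label[which.min(populations$n)])
  if (any(populations$size_factor <= 0))
    .pc_stop("size factors must be > 0")
  .check_range(noise_cv, "noise_cv", 0)
  standard <- measurement_table(as.data.frame(standard))
  set.seed(seed)
  s2 <- log(1 + noise_cv^2)
  rows <- list()
  for (i in seq_len(nrow(populations))) {
    for (j in seq_len(populations$n[i])) {
      noise <- if (noise_cv > 0)
        stats::rlnorm(nrow(standard), -s2 / 2, sqrt(s2)) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sprintf("%s_%02d", populations$label[i], j),
        population = populations$label[i],
        skeletal_element = standard$skeletal_element,
        code = standard$code,
        value = standard$value * populations$size_factor[i] * noise,
        flags = "", stringsAsFactors = FALSE)
    }
  }
  out <- measurement_table(do.call(rbind, rows))
  attr(out, "truth") <- list(populations = populations, noise_cv = noise_cv,
                             seed = seed)
  out
}
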