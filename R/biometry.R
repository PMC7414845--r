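#' Log-shape-ratio biometry against a standard skeleton
#'
#' Classic log-ratio (Simpson) diagrams compare homologous osteometric
#' measurements of archaeological specimens with a single designated
#' standard individual: for every measurement,
#' \deqn{d = \log_{10}(\mathrm{value}/\mathrm{standard})}
#' so that negative values mark specimens smaller than the standard and
#' positive ones larger. Measurement codes follow the von den Driesch
#' osteometric convention (GL, Bp, Bd, SD, ...), values in mm.
#'
#' @name biometry
NULL

#' Validate and construct a measurement table
#'
#' @param df data frame with columns `specimen_id`, `population`,
#'   `skeletal_element`, `code` (von den Driesch measurement code),
#'   `value` (mm), and optionally `flags` (comma-separated subset of
#'   `reworked`, `burnt`, `unmeasurable`, `juvenile`).
#' @return the validated data frame with class `measurement_table`.
#' @export
measurement_table <- function(df) {
  need <- c("specimen_id", "population", "skeletal_element", "code", "value")
  if (!all(need %in% names(df)))
    .pc_stop("measurement table needs columns: %s", paste(need, collapse = ", "))
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  if (any(!is.finite(df$value)) || any(df$value <= 0))
    .pc_stop("all measurement values must be finite and > 0")
  key <- paste(df$specimen_id, df$code)
  if (anyDuplicated(key))
    .pc_stop("duplicate (specimen_id, code) pairs: %s",
             paste(unique(key[duplicated(key)]), collapse = "; "))
  known <- c("reworked", "burnt", "unmeasurable", "juvenile")
  fl <- unique(unlist(strsplit(df$flags[nzchar(df$flags)], ",\\s*")))
  if (length(setdiff(fl, known)))
    .pc_stop("unknown flags: %s", paste(setdiff(fl, known), collapse = ", "))
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Remove specimens excluded from biometric comparison
#'
#' Rows flagged `reworked` (insecure stratigraphic context), `burnt`
#' (possible heat shrinkage) or `unmeasurable` are removed, and every
#' removal is itemized with its reason. An empty result is allowed (with a
#' warning).
#'
#' @param table a [measurement_table].
#' @param exclude flags that trigger removal.
#' @return the filtered table, with attribute `exclusion_report`: a data
#'   frame (`specimen_id`, `code`, `reason`) listing each removed row.
#' @export
apply_exclusions <- function(table,
                             exclude = c("reworked", "burnt", "unmeasurable")) {
  table <- measurement_table(as.data.frame(table))
  fl <- strsplit(table$flags, ",\\s*")
  hit <- vapply(fl, function(f) any(f %in% exclude), logical(1))
  report <- data.frame(
    specimen_id = table$specimen_id[hit], code = table$code[hit],
    reason = vapply(fl[hit], function(f)
      paste(intersect(f, exclude), collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  out <- table[!hit, , drop = FALSE]
  if (nrow(out) == 0L)
    .pc_warn("all rows excluded; returning an empty measurement table")
  attr(out, "exclusion_report") <- report
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Log shape ratios against a standard individual
#'
#' @param table a [measurement_table] of specimens to compare.
#' @param standard a [measurement_table] (or data frame with `code`,
#'   `value`) holding one value per measurement code for the standard
#'   individual.
#' @return data frame of class `log_ratio_profile`: the input rows plus
#'   `standard_value` and `d = log10(value/standard_value)`.
#' @export
log_shape_ratio <- function(table, standard) {
  table <- measurement_table(as.data.frame(table))
  std <- as.data.frame(standard)
  if (anyDuplicated(std$code))
    .pc_stop("the standard has duplicated measurement codes")
  miss <- setdiff(unique(table$code), std$code)
  if (length(miss))
    .pc_stop("measurement codes absent from the standard: %s",
             paste(miss, collapse = ", "))
  sv <- std$value[match(table$code, std$code)]
  out <- as.data.frame(table)
  out$standard_value <- sv
  out$d <- log10(out$value / sv)
  attr(out, "standard_id") <-
    if (!is.null(std$specimen_id)) std$specimen_id[1] else "standard"
  class(out) <- c("log_ratio_profile", "data.frame")
  out
}

#' Per-population summaries of log shape ratios
#'
#' Produces the plot data of a log-ratio diagram: per population and
#' measurement code, the number of specimens and the mean, sd, min and max
#' of d. The sd of a single specimen is reported as `NA`. Both the
#' population-level summary and specimen-level points are of interest for
#' plotting; the specimen-level rows are the input profile itself.
#'
#' @param profile a `log_ratio_profile` from [log_shape_ratio].
#' @param population_order optional ordering of populations in the output.
#' @return data frame with columns `population`, `code`, `n`, `mean_d`,
#'   `sd_d`, `min_d`, `max_d`.
#' @export
summarize_population <- function(profile, population_order = NULL) {
  stopifnot(inherits(profile, "log_ratio_profile"))
  if (nrow(profile) == 0L) .pc_stop("empty log-ratio profile")
  sp <- split(profile, list(profile$population, profile$code), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    population = g$population[1], code = g$code[1], n = nrow(g),
    mean_d = mean(g$d), sd_d = if (nrow(g) > 1L) stats::sd(g$d) else NA_real_,
    min_d = min(g$d), max_d = max(g$d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (!is.null(population_order)) {
    drop <- setdiff(unique(out$population), population_order)
    if (length(drop))
      .pc_warn("populations not in `population_order` omitted: %s",
               paste(drop, collapse = ", "))
    out <- out[out$population %in% population_order, , drop = FALSE]
    out <- out[order(match(out$population, population_order), out$code), ,
               drop = FALSE]
  } else {
    out <- out[order(out$population, out$code), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
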