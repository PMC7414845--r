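#' Run the full analysis pipeline
#'
#' Orchestrates the five analysis stages - biometry, tissue (microCT),
#' outline shape, aDNA damage, radiocarbon calibration - over either
#' user-supplied input files or, by default, bundled synthetic data
#' generated on the fly with known ground truth. Every random stage draws
#' its own child seed deterministically from the master seed, so a given
#' configuration always produces a byte-identical JSON report.
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Recognized keys: `stages` (subset of biometry, tissue, outline,
#'   damage, calibrate; default all), `seed` (master seed), `out_dir`
#'   (where `report.json` and the human-readable summary go; NULL = do not
#'   write), `wear_frac`, `bvtv_threshold`, `hpd_mass`, `sliding_mode`,
#'   and `inputs`: optional named paths (`biometry_table`, `standard`,
#'   `reads_tsv`, `reference_fasta`, `curve_14c`). Unknown keys are
#'   rejected.
#' @return the report, invisibly (a named list, one section per stage,
#'   plus `config_hash` and `seed`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) .pc_stop("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("stages", "seed", "out_dir", "wear_frac", "bvtv_threshold",
             "hpd_mass", "sliding_mode", "inputs")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    .pc_stop("unknown config keys: %s", paste(unknown, collapse = ", "))
  defaults <- list(stages = c("biometry", "tissue", "outline", "damage",
                              "calibrate"),
                   seed = 1L, out_dir = NULL, wear_frac = 0.5,
                   bvtv_threshold = 0.65, hpd_mass = 0.954,
                   sliding_mode = "bending_energy", inputs = list())
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) .pc_stop("unknown stages: %s", paste(bad, collapse = ", "))
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) .pc_stop("input path does not exist: %s", p)
  report <- list(seed = as.integer(cfg$seed),
                 config_hash = .config_hash(cfg))
  runners <- list(biometry = .stage_biometry, tissue = .stage_tissue,
                  outline = .stage_outline, damage = .stage_damage,
                  calibrate = .stage_calibrate)
  ok <- TRUE
  for (st in cfg$stages) {
    res <- tryCatch(runners[[st]](cfg),
                    error = function(e) list(status = "error",
                                             message = conditionMessage(e)))
    if (identical(res$status, "error")) ok <- FALSE
    report[[st]] <- res
  }
  report$ok <- ok
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(.report_summary(report),
               file.path(cfg$out_dir, "summary.txt"))
  }
  invisible(report)
}

.config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]  # paths don't change results
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

.stage_biometry <- function(cfg) {
  std <- if (!is.null(cfg$inputs$standard))
    measurement_table(utils::read.csv(cfg$inputs$standard)) else
      canid_standard()
  tab <- if (!is.null(cfg$inputs$biometry_table))
    measurement_table(utils::read.csv(cfg$inputs$biometry_table)) else
      gen_measurement_table(data.frame(label = c("dog", "wolf"),
                                       size_factor = c(0.8, 1.0),
                                       n = c(6, 6)),
                            standard = std, noise_cv = 0.04,
                            seed = .child_seed(cfg$seed, "biometry"))
  filt <- apply_exclusions(tab)
  prof <- log_shape_ratio(filt, std)
  summ <- summarize_population(prof)
  means <- tapply(prof$d, prof$population, mean)
  list(status = "ok", n_rows = nrow(filt),
       n_excluded = nrow(attr(filt, "exclusion_report")),
       population_mean_log_ratio = as.list(round(means, 5)),
       summary = summ)
}

.stage_tissue <- function(cfg) {
  seed <- .child_seed(cfg$seed, "tissue")
  ph <- gen_tooth_phantom(tooth_phantom_config(seed = seed))
  seg <- segment_tissues(ph$gray, n_classes = 3)
  sl <- extract_crown_slice(seg, ph$truth$cervix_plane)
  dp <- dentine_percent(sl)
  wr <- detect_wear(seg, ph$truth$cervix_plane, section2 = sl$section2,
                    frac = cfg$wear_frac)
  ep <- gen_epiphysis_phantom(epiphysis_phantom_config(porosity = 0.2,
                                                       seed = seed + 1L))
  bv <- bv_tv(ep, attr(ep, "truth")$separation_plane,
              threshold = cfg$bvtv_threshold)
  list(status = "ok",
       dentine_percent = dp$percent,
       dentine_percent_truth = ph$truth$slice_dentine_percent,
       worn = wr$worn,
       bvtv = bv$ratio, maturity_call = bv$maturity_call)
}

.stage_outline <- function(cfg) {
  seed <- .child_seed(cfg$seed, "outline")
  oc <- outline_pop_config(n_per_group = c(8, 8), n_fourier = 6,
                           group_offset = outline_contrast(6, 0.004),
                           within_sd = 0.004, seed = seed)
  pop <- gen_outline_population(oc)
  sc <- semilandmark_config(counts = c(30, 20), mode = cfg$sliding_mode)
  confs <- lapply(pop$outlines, resample_outline, cfg = sc)
  shapes <- slide_semilandmarks(confs, sc)
  model <- bgpca(shapes)
  allo <- test_allometry(model$scores[, 1, drop = FALSE], shapes$csize)
  list(status = "ok", n = shapes$n,
       bgpc1_group_means = as.list(round(model$group_means[, 1], 5)),
       allometry_p = allo$p_value[1], allometry_r2 = allo$r_squared[1])
}

.stage_damage <- function(cfg) {
  seed <- .child_seed(cfg$seed, "damage")
  rs <- if (!is.null(cfg$inputs$reads_tsv)) {
    if (is.null(cfg$inputs$reference_fasta))
      .pc_stop("reads_tsv input requires reference_fasta")
    read_reads_tsv(cfg$inputs$reads_tsv, cfg$inputs$reference_fasta)
  } else {
    gen_ancient_reads(read_sim_config(n_reads = 3000, ref_length = 8000,
                                      seed = seed))
  }
  fl <- fragment_length_stats(rs)
  pr <- damage_profile(rs)
  cv <- coverage_summary(rs)
  list(status = "ok", n_reads = fl$n, mean_length = fl$mean,
       ct5_position1 = pr$ct5_rate[1], ga3_position1 = pr$ga3_rate[1],
       fraction_covered = cv$fraction_covered, mean_depth = cv$mean_depth)
}

.stage_calibrate <- function(cfg) {
  seed <- .child_seed(cfg$seed, "calibrate")
  curve <- if (!is.null(cfg$inputs$curve_14c))
    read_intcal(cfg$inputs$curve_14c) else
      gen_calibration_curve(curve_sim_config(seed = seed))
  comb <- combine_measurements(list(c14_measurement(12150, 70, "A"),
                                    c14_measurement(12200, 65, "B")))
  cal <- calibrate_c14(comb, curve, mass = cfg$hpd_mass)
  list(status = "ok", combined_age = comb$age, combined_sigma = comb$sigma,
       mode_cal_bp = cal$mode,
       hpd = lapply(seq_len(nrow(cal$hpd)), function(i)
         list(older = cal$hpd$older[i], younger = cal$hpd$younger[i],
              mass = cal$hpd$mass[i])))
}

.report_summary <- function(report) {
  ln <- c(sprintf("paleocanid pipeline report (seed %d, config %s)",
                  report$seed, report$config_hash),
          sprintf("overall status: %s", if (report$ok) "ok" else "FAILED"))
  for (st in setdiff(names(report), c("seed", "config_hash", "ok"))) {
    sec <- report[[st]]
    ln <- c(ln, sprintf("- %s: %s", st, sec$status))
    if (identical(sec$status, "error"))
      ln <- c(ln, sprintf("    %s", sec$message))
  }
  ln
}
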