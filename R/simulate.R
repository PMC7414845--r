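#' Emit a complete synthetic fixture set
#'
#' Writes every input the analysis stages consume, generated with known
#' ground truth: crown outlines (TPS and CSV), osteometric tables (CSV),
#' an aligned ancient-read set (TSV + SAM + reference FASTA), a synthetic
#' calibration curve (IntCal-format text), and tooth/epiphysis phantom
#' volumes (NRRD + TIFF stacks), each with a JSON ground-truth sidecar.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param preset `"study-scale"` (21 + 23 outlines, 50,000 reads) or
#'   `"demo"` (scaled down for quick runs).
#' @return the output directory, invisibly.
#' @export
simulate_fixtures <- function(out_dir, seed = 1,
                              preset = c("study-scale", "demo")) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  big <- preset == "study-scale"
  j <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                           auto_unbox = TRUE, digits = NA)
  # outlines
  ocfg <- outline_pop_config(
    n_per_group = if (big) c(21, 23) else c(4, 4),
    group_offset = outline_contrast(8, 0.004), within_sd = 0.004,
    seed = .child_seed(seed, "outline"))
  pop <- gen_outline_population(ocfg)
  write_tps(pop$outlines, file.path(out_dir, "outlines.tps"))
  pts <- do.call(rbind, lapply(pop$outlines, function(o)
    data.frame(specimen_id = o$specimen_id, group = o$group,
               x = o$points[, 1], y = o$points[, 2])))
  utils::write.csv(pts, file.path(out_dir, "outlines.csv"),
                   row.names = FALSE)
  j(list(contrast = pop$truth$contrast, csize = pop$truth$csize,
         groups = pop$groups), "outlines.truth.json")
  # measurements
  tab <- gen_measurement_table(
    data.frame(label = c("dog", "wolf"), size_factor = c(0.8, 1.0),
               n = if (big) c(8, 8) else c(3, 3)),
    seed = .child_seed(seed, "measure"))
  utils::write.csv(tab, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(canid_standard(), file.path(out_dir, "standard.csv"),
                   row.names = FALSE)
  # reads
  rcfg <- read_sim_config(n_reads = if (big) 50000 else 2000,
                          seed = .child_seed(seed, "reads"))
  rs <- gen_ancient_reads(rcfg)
  write_reads_tsv(rs, file.path(out_dir, "reads.tsv"))
  write_fasta(rs$reference, file.path(out_dir, "reference.fasta"))
  write_sam(rs, file.path(out_dir, "reads.sam"))
  j(unclass(rcfg), "reads.truth.json")
  # calibration curve, IntCal-format text
  cc <- gen_calibration_curve(curve_sim_config(
    seed = .child_seed(seed, "curve")))
  writeLines(c("# synthetic calibration curve (paleocanid)",
               "# CAL BP, 14C age, Error",
               sprintf("%g,%g,%g", cc$cal_bp, cc$c14_age, cc$error)),
             file.path(out_dir, "synthetic_curve.14c"))
  # phantoms
  ph <- gen_tooth_phantom(tooth_phantom_config(
    seed = .child_seed(seed, "tooth")))
  write_volume_nrrd(ph$labels, file.path(out_dir, "tooth_labels.nrrd"))
  write_volume_tiff(ph$gray, file.path(out_dir, "tooth_gray.tif"))
  j(ph$truth[c("z_cervix_mm", "h1_mm", "h2_mm",
               "slice_dentine_percent")], "tooth.truth.json")
  ep <- gen_epiphysis_phantom(epiphysis_phantom_config(
    porosity = 0.4, seed = .child_seed(seed, "epi")))
  write_volume_nrrd(ep, file.path(out_dir, "epiphysis_labels.nrrd"))
  j(attr(ep, "truth")[c("void_fraction", "trabecular_voxels")],
    "epiphysis.truth.json")
  invisible(out_dir)
}
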