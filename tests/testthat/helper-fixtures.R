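# shared fixtures, built lazily once per test run
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_tooth <- function() fx("tooth", function()
  gen_tooth_phantom(tooth_phantom_config(seed = 1)))

fx_tooth_seg <- function() fx("tooth_seg", function()
  segment_tissues(fx_tooth()$gray, n_classes = 3))

fx_tooth_slice <- function() fx("tooth_slice", function()
  extract_crown_slice(fx_tooth_seg(), fx_tooth()$truth$cervix_plane))

fx_outline_pop <- function() fx("outline_pop", function() {
  cfg <- outline_pop_config(group_offset = outline_contrast(8, 0.004),
                            seed = 7)
  list(cfg = cfg, pop = gen_outline_population(cfg))
})

fx_shapes <- function() fx("shapes", function() {
  sc <- semilandmark_config()
  confs <- lapply(fx_outline_pop()$pop$outlines, resample_outline, cfg = sc)
  slide_semilandmarks(confs, sc)
})

fx_model <- function() fx("model", function() bgpca(fx_shapes()))

# small helper: resampled configuration of a generated outline list
resample_all <- function(outlines, cfg = semilandmark_config()) {
  lapply(outlines, resample_outline, cfg = cfg)
}
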