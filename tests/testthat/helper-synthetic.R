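# Shared fixtures: reduced-scale configurations so unit tests run in seconds.
# The mechanics under test (segmentation, morphometry, QC arithmetic,
# normalization) do not depend on field size; full-scale defaults are
# exercised in test-acceptance.R.

small_config <- function(assay_kind = "evpt") {
  cfg <- default_config(assay_kind)
  cfg$calibration$field_xy <- 800
  cfg$calibration$n_sections <- 20
  cfg$generator$count_range <- c(10L, 25L)
  cfg$generator$single_cell_mean <- 40
  cfg
}

small_scene <- function(seed = 1, effect = effect_model(), n_tumoroids = NULL,
                        cfg = small_config(), ...) {
  p <- scene_defaults(cfg)
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  if (!is.null(n_tumoroids)) p$count_fixed <- n_tumoroids
  sample_scene(p, effect, seed = seed)
}

small_well <- function(seed = 1, effect = effect_model(), cfg = small_config(), ...) {
  sc <- small_scene(seed = seed, effect = effect, cfg = cfg, ...)
  render_well(sc, imaging_defaults(cfg), seed = seed + 1000)
}

# A sphere painted into an empty label grid: ground-truth geometry for
# morphometry tests, independent of the segmentation pipeline.
sphere_labels <- function(diameter_um, vox = 5, zst = 25, pad_um = 40) {
  r <- diameter_um / 2
  ext <- diameter_um + 2 * pad_um
  ny <- nx <- ceiling(ext / vox)
  nz <- ceiling(ext / zst)
  cy <- cx <- ext / 2
  cz <- zst * nz / 2
  yy <- (seq_len(ny) - 0.5) * vox
  xx <- (seq_len(nx) - 0.5) * vox
  zz <- (seq_len(nz) - 0.5) * zst
  d2 <- outer(outer((yy - cy)^2, (xx - cx)^2, `+`), (zz - cz)^2, `+`)
  lab <- array(0L, c(ny, nx, nz))
  lab[d2 <= r^2] <- 1L
  organoidhci:::label_volume(lab, 1L, vox, zst)
}

# Constructed per-well measurement rows for QC tests (no imaging involved).
fake_measurements <- function(well_ids, object_count, total_volume_mm3,
                              qc_flag = "pass") {
  data.frame(well_id = well_ids,
             object_count = object_count,
             total_volume_mm3 = total_volume_mm3,
             mean_object_volume_um3 = 1e5,
             median_object_volume_um3 = 1e5,
             single_cell_count = 100L,
             tracker_cell_count = NA_integer_,
             infiltrated_count = NA_integer_,
             infiltration_fraction = NA_real_,
             qc_flag = qc_flag, qc_reason = "",
             stringsAsFactors = FALSE)
}

# Minimal layout around given wells: one sample, one condition + control.
fake_layout <- function(n_ctrl = 8, n_treat = 8, assay_kind = "evpt",
                        ctrl_rows = NULL) {
  design_layout(c("control", "treat"),
                n_replicates = max(n_ctrl, n_treat),
                assay_kind = assay_kind)
}
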