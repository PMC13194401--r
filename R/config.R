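#' Default pipeline configuration
#'
#' Returns the full nested configuration used across the pipeline: imaging
#' calibration, synthetic-generator parameters, segmentation and
#' classification thresholds, QC gates and normalization options. Every
#' field can be overridden via [read_config()] (YAML file) or by modifying
#' the returned list.
#'
#' Units are micrometres (µm) for lengths, µm³ for object volumes and mm³ for
#' per-well cumulative volumes (1 mm³ = 1e9 µm³).
#'
#' @param assay_kind `"evpt"` (ex vivo patient tissue; nuclei + actin
#'   channels) or `"reconstituted"` (organoid-PBMC co-culture; adds a
#'   cell-tracker channel for pre-labeled immune cells).
#' @return A nested list of class `ohci_config`.
#' @export
default_config <- function(assay_kind = c("evpt", "reconstituted")) {
  assay_kind <- match.arg(assay_kind)
  cfg <- list(
    assay_kind = assay_kind,
    calibration = list(
      voxel_size_xy = 5,    # µm per pixel at 4x with binning
      z_step        = 25,   # µm per optical section
      field_xy      = 2000, # µm, imaged square region of the well
      n_sections    = 24
    ),
    generator = list(
      count_range        = c(50L, 300L), # tumoroids seeded per well
      diameter_range     = c(50, 200),   # µm, seeded cluster diameters
      diameter_meanlog   = log(90),
      diameter_sdlog     = 0.4,
      min_gap            = 25,   # µm surface-to-surface clearance between tumoroids
      nucleus_spacing    = 20,   # µm between nuclei inside a tumoroid body
      nucleus_sigma      = 4,    # µm, rendered nuclear blob s.d.
      single_cell_mean   = 300,  # expected free single cells per well
      single_cell_diameter = 12, # µm, actin shell outer diameter
      tracker            = (assay_kind == "reconstituted"),
      labeled_fraction_in_field = 0.1, # effectors added atop the gel that end up in the imaged volume
      background         = 100,  # camera offset, ADU
      read_noise_sd      = 10,   # ADU
      actin_intensity    = 2000, # ADU above background inside tumoroids
      shell_intensity    = 1200, # ADU, single-cell actin shells
      nucleus_peak       = 3000, # ADU, nuclear blob peak
      tracker_peak       = 3000, # ADU, tracker blob peak
      max_place_tries    = 2000L
    ),
    segmentation = list(
      smooth_sigma          = 5,    # µm, per-axis Gaussian (scaled by spacing)
      threshold             = "otsu", # or a fixed numeric intensity
      closing_radius_px     = 2L,   # per-slice morphological closing
      min_object_diameter   = 15,   # µm, components below this are debris
      fill_holes            = TRUE,
      blob_floor_sd         = 8,    # blob threshold floor, in background sd
      nucleus_min_separation = 10,  # µm, local-maximum window
      tracker_min_separation = 10
    ),
    classification = list(
      single_cell_max_diameter = 30, # µm; below this an object is not multicellular
      min_nuclei               = 2L  # nuclei required inside a multicellular object
    ),
    qc = list(
      min_control_objects    = 50L,   # control-window gate
      min_control_volume_mm3 = 0.01,
      foreground_lo          = 1e-4,  # image-quality gates
      foreground_hi          = 0.5,
      min_intensity_ratio    = 2,
      min_coverage           = 0.8,
      exclusion_warn         = 0.04,
      control_fail_fraction  = 0.5,   # sample verdict: fail if > this fraction of controls fail
      edge_p                 = 0.01,
      edge_ratio_band        = c(0.8, 1.25)
    ),
    normalization = list(
      control_summary = "mean",  # denominator for percent-of-control; or "median"
      responder_floor = 10       # % reduction below which a sample is a non-responder
    )
  )
  class(cfg) <- "ohci_config"
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML file of overrides and merges it (recursively) onto
#' [default_config()]. Only keys present in the file are changed.
#'
#' @param path YAML file.
#' @param assay_kind passed to [default_config()]; a top-level `assay_kind`
#'   key in the file takes precedence.
#' @return An `ohci_config` list.
#' @export
read_config <- function(path, assay_kind = "evpt") {
  if (!file.exists(path)) stop_format(sprintf("config file not found: %s", path))
  over <- yaml::read_yaml(path)
  if (!is.null(over$assay_kind)) assay_kind <- over$assay_kind
  cfg <- merge_config(default_config(assay_kind), over)
  validate_config(cfg)
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  cal <- cfg$calibration
  assert_scalar_pos(cal$voxel_size_xy, "calibration$voxel_size_xy")
  assert_scalar_pos(cal$z_step, "calibration$z_step")
  assert_scalar_pos(cal$field_xy, "calibration$field_xy")
  assert_scalar_pos(cal$n_sections, "calibration$n_sections")
  if (diff(cfg$generator$count_range) < 0 || cfg$generator$count_range[1] < 1)
    stop_validation("generator$count_range must be positive and non-decreasing")
  if (diff(cfg$generator$diameter_range) <= 0 || cfg$generator$diameter_range[1] <= 0)
    stop_validation("generator$diameter_range must be positive and increasing")
  assert_scalar_pos(cfg$classification$single_cell_max_diameter,
                    "classification$single_cell_max_diameter")
  assert_fraction(cfg$qc$foreground_lo, "qc$foreground_lo")
  assert_fraction(cfg$qc$foreground_hi, "qc$foreground_hi")
  invisible(cfg)
}

#' Write the effective configuration to a YAML file
#' @param cfg an `ohci_config` list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Stable, platform-independent seed derivation: master seed + string key ->
# integer in [1, 2^31). Polynomial rolling hash over UTF-8 bytes.
derive_seed <- function(master_seed, key) {
  s <- as.double(master_seed) %% 2147480009
  for (b in utf8ToInt(as.character(key))) s <- (s * 131 + b) %% 2147480009
  as.integer(s + 1)
}
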