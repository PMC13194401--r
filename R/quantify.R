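# Per-object morphometry and per-well aggregate readouts.

#' Measure segmented multicellular objects
#'
#' Per object: per-slice cross-sectional areas (µm², voxel-counted),
#' volume as the cumulative area through the stack times the z-step
#' (`volume = sum(per_slice_area) * z_step`), the equivalent spherical
#' diameter `(6 V / pi)^(1/3)`, the contained-nucleus count and the centroid
#' in µm.
#'
#' @param labels an `ohci_labels` (typically `classify_objects()$multicellular`).
#' @param nuclei optional nucleus point set; contained nuclei are counted by
#'   centroid-in-mask.
#' @param per_slice keep the per-slice area matrix as an attribute
#'   `"per_slice_areas"` (objects x sections, µm²).
#' @return A data.frame with one row per object: `object_id`,
#'   `volume_um3`, `equivalent_diameter_um`, `nucleus_count`,
#'   `infiltrated_cell_count` (0 until [count_infiltration()]),
#'   `x_um`, `y_um`, `z_um`. Empty labeling gives an empty data.frame.
#' @export
measure_objects <- function(labels, nuclei = NULL, per_slice = FALSE) {
  lab <- labels$labels
  n <- labels$n
  vox <- labels$voxel_size_xy; zst <- labels$z_step
  empty <- data.frame(object_id = integer(0), volume_um3 = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      nucleus_count = integer(0),
                      infiltrated_cell_count = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  if (n == 0L) return(empty)
  d <- dim(lab)
  fg <- which(lab > 0L)
  lv <- lab[fg]
  # decompose linear indices into (y, x, z)
  zi <- (fg - 1L) %/% (d[1] * d[2]) + 1L
  rem <- (fg - 1L) %% (d[1] * d[2])
  xi <- rem %/% d[1] + 1L
  yi <- rem %% d[1] + 1L
  areas <- matrix(tabulate((zi - 1L) * n + lv, n * d[3]), nrow = n) * vox^2
  volume <- rowSums(areas) * zst
  cy <- rowsum(as.double(yi), lv)[, 1] / tabulate(lv, n)
  cx <- rowsum(as.double(xi), lv)[, 1] / tabulate(lv, n)
  cz <- rowsum(as.double(zi), lv)[, 1] / tabulate(lv, n)
  nuc_count <- integer(n)
  if (!is.null(nuclei) && nrow(nuclei)) {
    nl <- lab[cbind(nuclei$y, nuclei$x, nuclei$z)]
    nuc_count <- tabulate(nl[nl > 0L], n)
  }
  out <- data.frame(object_id = seq_len(n),
                    volume_um3 = volume,
                    equivalent_diameter_um = (6 * volume / pi)^(1 / 3),
                    nucleus_count = nuc_count,
                    infiltrated_cell_count = 0L,
                    x_um = (cx - 0.5) * vox,
                    y_um = (cy - 0.5) * vox,
                    z_um = (cz - 0.5) * zst)
  if (per_slice) attr(out, "per_slice_areas") <- areas
  out
}

#' Count infiltrated labeled cells per object
#'
#' A tracker-cell centroid is infiltrated iff its voxel belongs to a
#' multicellular object's mask (centroid-in-mask; partial overlap of the
#' cell body does not count).
#'
#' @param labels an `ohci_labels` of multicellular objects.
#' @param tracker a point set from [detect_tracker_cells()].
#' @return List: `per_object` (integer vector over labels), `total` and
#'   `n_tracker`.
#' @export
count_infiltration <- function(labels, tracker) {
  n <- labels$n
  if (nrow(tracker) == 0L)
    return(list(per_object = integer(n), total = 0L, n_tracker = 0L))
  tl <- labels$labels[cbind(tracker$y, tracker$x, tracker$z)]
  per <- tabulate(tl[tl > 0L], n)
  list(per_object = per, total = sum(per), n_tracker = nrow(tracker))
}

#' Run the full single-well measurement chain
#'
#' Composes [detect_nuclei()], [segment_actin_objects()],
#' [classify_objects()], [measure_objects()], [count_infiltration()] and the
#' image-quality gate into one per-well record. A failing stage marks the
#' well `analysis_failed` instead of aborting the plate.
#'
#' @param stack an [image_stack()].
#' @param layout_row optional single-row layout entry; copies well metadata.
#' @param config an [default_config()] list.
#' @return List of class `ohci_well`: `measurement` (one-row data.frame with
#'   `well_id`, `object_count`, `total_volume_mm3`, `mean_object_volume_um3`,
#'   `median_object_volume_um3`, `single_cell_count`, `tracker_cell_count`,
#'   `infiltrated_count`, `infiltration_fraction`, `qc_flag`), `objects`
#'   (per-object table) and `image_qc`.
#' @export
measure_well <- function(stack, layout_row = NULL, config = default_config()) {
  wid <- if (!is.null(layout_row)) layout_row$well_id else stack$well_id
  res <- tryCatch({
    nuclei <- detect_nuclei(stack, config)
    raw <- segment_actin_objects(stack, config)
    cls <- classify_objects(raw, nuclei, config)
    objs <- measure_objects(cls$multicellular, nuclei)
    has_tracker <- !is.null(get_channel(stack, "tracker"))
    tracker <- if (has_tracker) detect_tracker_cells(stack, config, quiet = TRUE)
               else point_set(matrix(integer(0), 0, 3), "tracker_cell",
                              stack$voxel_size_xy, stack$z_step)
    inf <- count_infiltration(cls$multicellular, tracker)
    if (nrow(objs)) objs$infiltrated_cell_count <- inf$per_object
    iq <- image_well_qc(stack, cls$multicellular, config)
    m <- data.frame(
      well_id = wid,
      object_count = nrow(objs),
      total_volume_mm3 = sum(objs$volume_um3) / 1e9,
      mean_object_volume_um3 = if (nrow(objs)) mean(objs$volume_um3) else 0,
      median_object_volume_um3 = if (nrow(objs)) median(objs$volume_um3) else 0,
      single_cell_count = nrow(cls$single_cells),
      tracker_cell_count = if (has_tracker) inf$n_tracker else NA_integer_,
      infiltrated_count = if (has_tracker) inf$total else NA_integer_,
      infiltration_fraction = if (has_tracker && inf$n_tracker > 0)
        inf$total / inf$n_tracker else NA_real_,
      qc_flag = if (iq$pass) "pass" else "fail_image_quality",
      qc_reason = if (iq$pass) "" else iq$reason,
      stringsAsFactors = FALSE)
    list(measurement = m, objects = objs, image_qc = iq)
  }, error = function(e) {
    m <- data.frame(well_id = wid, object_count = NA_integer_,
                    total_volume_mm3 = NA_real_, mean_object_volume_um3 = NA_real_,
                    median_object_volume_um3 = NA_real_,
                    single_cell_count = NA_integer_,
                    tracker_cell_count = NA_integer_,
                    infiltrated_count = NA_integer_,
                    infiltration_fraction = NA_real_,
                    qc_flag = "analysis_failed",
                    qc_reason = conditionMessage(e), stringsAsFactors = FALSE)
    list(measurement = m, objects = NULL, image_qc = NULL)
  })
  class(res) <- "ohci_well"
  res
}

#' @export
print.ohci_well <- function(x, ...) {
  m <- x$measurement
  cat(sprintf("<ohci_well> %s: %s objects, %.4g mm3 total, %s single cells [%s]\n",
              m$well_id, m$object_count, m$total_volume_mm3,
              m$single_cell_count, m$qc_flag))
  invisible(x)
}
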