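# Plate layouts: which well holds which sample/condition/dose/replicate group.

plate_rows <- function(plate_format) {
  switch(as.character(plate_format),
         "384" = 16L, "96" = 8L,
         stop_validation("supported plate formats: 96, 384"))
}

plate_cols <- function(plate_format) {
  switch(as.character(plate_format), "384" = 24L, "96" = 12L)
}

well_row_col <- function(well_id) {
  m <- regmatches(well_id, regexec("^([A-P])([0-9]{1,2})$", well_id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop_validation(sprintf("malformed well id(s): %s",
                            paste(well_id[bad], collapse = ", ")))
  data.frame(row = match(vapply(m, `[`, "", 2L), LETTERS),
             col = as.integer(vapply(m, `[`, "", 3L)))
}

well_name <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

is_edge_well <- function(well_id, plate_format = 384) {
  rc <- well_row_col(well_id)
  nr <- plate_rows(plate_format); nc <- plate_cols(plate_format)
  if (any(rc$row > nr | rc$col > nc))
    stop_validation("well id outside plate geometry")
  rc$row == 1L | rc$row == nr | rc$col == 1L | rc$col == nc
}

#' Construct and validate a plate layout
#'
#' @param wells data.frame with columns `well_id`, `sample_id`, `condition`,
#'   `dose` (numeric, `NA` for none), `dose_units` (character, may be `NA`),
#'   `replicate_group`, `is_control` (logical).
#' @param plate_format number of wells on the physical plate (default 384).
#' @param assay_kind `"evpt"` or `"reconstituted"`; sets the expected
#'   technical replicate count (8 vs 4) used in consistency warnings.
#' @return A data.frame of class `ohci_layout` with an added `is_edge` column
#'   (outermost ring of the plate: rows A/P, columns 1/24 for 384-well).
#' @export
plate_layout <- function(wells, plate_format = 384, assay_kind = c("evpt", "reconstituted")) {
  assay_kind <- match.arg(assay_kind)
  req <- c("well_id", "sample_id", "condition", "replicate_group", "is_control")
  miss <- setdiff(req, names(wells))
  if (length(miss))
    stop_format(sprintf("layout missing required column(s): %s", paste(miss, collapse = ", ")))
  if (is.null(wells$dose)) wells$dose <- NA_real_
  if (is.null(wells$dose_units)) wells$dose_units <- NA_character_
  wells$is_control <- as.logical(wells$is_control)
  if (anyDuplicated(wells$well_id))
    stop_validation(sprintf("duplicate well id(s): %s",
      paste(unique(wells$well_id[duplicated(wells$well_id)]), collapse = ", ")))
  # every non-control replicate group must map to exactly one condition x dose
  ncw <- wells[!wells$is_control, , drop = FALSE]
  if (nrow(ncw)) {
    key <- paste(ncw$condition, ncw$dose)
    spans <- tapply(key, ncw$replicate_group, function(k) length(unique(k)))
    if (any(spans > 1L))
      stop_validation(sprintf("replicate group(s) span multiple condition/dose: %s",
                              paste(names(spans)[spans > 1L], collapse = ", ")))
  }
  by_sample <- tapply(wells$is_control, wells$sample_id, any)
  if (!all(by_sample))
    stop_validation(sprintf("sample(s) without control wells: %s",
                            paste(names(by_sample)[!by_sample], collapse = ", ")))
  expected_n <- if (assay_kind == "evpt") 8L else 4L
  nrep <- table(ncw$replicate_group)
  if (length(nrep) && any(nrep != expected_n))
    warning(sprintf("%d replicate group(s) deviate from the expected n=%d %s replicates",
                    sum(nrep != expected_n), expected_n, assay_kind))
  wells$is_edge <- is_edge_well(wells$well_id, plate_format)
  structure(wells, plate_format = plate_format, assay_kind = assay_kind,
            class = c("ohci_layout", "data.frame"))
}

#' Read a plate layout from CSV
#'
#' Expected header: `well_id,sample_id,condition,dose,dose_units,
#' replicate_group,is_control` (dose columns optional). Edge flags are
#' computed from plate geometry, not read.
#'
#' @param path CSV file.
#' @inheritParams plate_layout
#' @return An `ohci_layout` data.frame.
#' @export
read_layout <- function(path, plate_format = 384, assay_kind = c("evpt", "reconstituted")) {
  if (!file.exists(path)) stop_format(sprintf("layout file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  plate_layout(df, plate_format = plate_format, assay_kind = match.arg(assay_kind))
}

#' Lay out a one-sample screen on a plate
#'
#' Convenience constructor used by the simulator, demos and tests: assigns
#' each condition `n_replicates` consecutive wells (row-major), optionally
#' skipping the outermost ring of the plate.
#'
#' @param conditions character vector of condition names; the first entry is
#'   taken as the control condition unless `control` names another one.
#' @param n_replicates technical replicates per condition (paper practice:
#'   4 for reconstituted co-cultures, 8 for ex vivo patient tissue).
#' @param control name of the control condition.
#' @param sample_id sample identifier for all wells.
#' @param doses optional numeric vector parallel to `conditions`.
#' @param dose_units optional character vector parallel to `conditions`.
#' @param plate_format,assay_kind see [plate_layout()].
#' @param use_edges place wells on the plate edge ring as well.
#' @return An `ohci_layout` data.frame.
#' @export
design_layout <- function(conditions, n_replicates = 8, control = conditions[1],
                          sample_id = "S1", doses = NULL, dose_units = NULL,
                          plate_format = 384,
                          assay_kind = c("evpt", "reconstituted"),
                          use_edges = FALSE) {
  assay_kind <- match.arg(assay_kind)
  nr <- plate_rows(plate_format); nc <- plate_cols(plate_format)
  rows <- if (use_edges) seq_len(nr) else 2:(nr - 1L)
  cols <- if (use_edges) seq_len(nc) else 2:(nc - 1L)
  slots <- as.vector(t(outer(rows, cols, well_name)))
  need <- length(conditions) * n_replicates
  if (need > length(slots))
    stop_validation(sprintf("layout needs %d wells but only %d are available", need, length(slots)))
  wells <- data.frame(
    well_id = slots[seq_len(need)],
    sample_id = sample_id,
    condition = rep(conditions, each = n_replicates),
    dose = if (is.null(doses)) NA_real_ else rep(doses, each = n_replicates),
    dose_units = if (is.null(dose_units)) NA_character_ else rep(dose_units, each = n_replicates),
    replicate_group = rep(paste0("g_", make.unique(conditions)), each = n_replicates),
    is_control = rep(conditions == control, each = n_replicates),
    stringsAsFactors = FALSE)
  plate_layout(wells, plate_format = plate_format, assay_kind = assay_kind)
}

#' Write a measurement or readout table to CSV
#'
#' Column order is preserved as-is and the file re-reads losslessly
#' (numeric round-trip within 1e-9). An empty table writes a header-only
#' file with a warning.
#'
#' @param rows a data.frame (per-well measurements, per-object morphometry,
#'   or normalized readouts).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(rows, path) {
  if (!is.data.frame(rows)) stop_validation("`rows` must be a data.frame")
  if (nrow(rows) == 0L) warning("writing an empty measurement table (header only)")
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- tryCatch({ write.csv(rows, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_format(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE)
}
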