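# End-to-end orchestration: simulate-and-measure whole plates in a streaming
# fashion (stacks are discarded well by well), analyze directories written by
# `simulate_plate`, and turn per-well measurements into normalized readouts,
# categories and statistics.

#' Simulate and measure a plate without keeping stacks
#'
#' Renders each well from ground truth, measures it, and discards the voxel
#' data: the memory footprint stays at a single well regardless of plate
#' size. Identical seeds give identical results to [simulate_plate()]
#' followed by [measure_well()].
#'
#' @inheritParams simulate_plate
#' @param progress print a short note every `progress` wells (0 = silent).
#' @return List: `measurements` (per-well data.frame), `truth_summary`
#'   (per-well data.frame: true tumoroid count, total true volume mm³, max
#'   diameter, infiltration), `layout`.
#' @export
screen_synthetic_plate <- function(layout, effects, master_seed = 1L,
                                   config = default_config(), progress = 0) {
  conds <- unique(layout$condition)
  ctrl_conds <- unique(layout$condition[layout$is_control])
  miss <- setdiff(setdiff(conds, names(effects)), ctrl_conds)
  if (length(miss))
    stop_validation(sprintf("no effect model for condition(s): %s",
                            paste(miss, collapse = ", ")))
  for (cc in setdiff(ctrl_conds, names(effects))) effects[[cc]] <- null_effect()
  params <- scene_defaults(config)
  imaging <- imaging_defaults(config)
  group_count <- group_seed_counts(layout, params, master_seed)
  meas <- vector("list", nrow(layout))
  tru <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    wid <- layout$well_id[i]
    wseed <- derive_seed(master_seed, wid)
    p <- params
    p$count_fixed <- well_count(group_count[[layout$sample_id[i]]], wseed, params)
    scene <- sample_scene(p, effects[[layout$condition[i]]], seed = wseed)
    stk <- render_well(scene, imaging, seed = derive_seed(master_seed, paste0(wid, ":img")))
    stk$well_id <- wid
    w <- measure_well(stk, layout[i, , drop = FALSE], config)
    meas[[i]] <- w$measurement
    tru[[i]] <- data.frame(
      well_id = wid,
      true_object_count = nrow(scene$tumoroids),
      true_total_volume_mm3 = sum(scene$tumoroids$true_volume_um3) / 1e9,
      true_max_diameter_um = if (nrow(scene$tumoroids))
        max(scene$tumoroids$equivalent_diameter_um) else NA_real_,
      true_single_cells = nrow(scene$single_cells),
      true_labeled_cells = nrow(scene$labeled_cells),
      true_infiltrated = sum(scene$labeled_cells$infiltrated),
      stringsAsFactors = FALSE)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  well %d/%d (%s)", i, nrow(layout), wid))
  }
  list(measurements = do.call(rbind, meas),
       truth_summary = do.call(rbind, tru),
       layout = layout)
}

#' Analyze a directory of per-well stacks
#'
#' Reads `<well>_<role>.tif` stacks written by [simulate_plate()] (or any
#' acquisition export following that naming), measures every well in the
#' layout, and returns the per-well measurement table.
#'
#' @param indir directory with per-well TIFFs.
#' @param layout an `ohci_layout`.
#' @param config an [default_config()] list.
#' @return Per-well measurement data.frame.
#' @export
measure_plate_dir <- function(indir, layout, config = default_config()) {
  if (!dir.exists(indir)) stop_format(sprintf("input directory not found: %s", indir))
  cal <- config$calibration
  meas <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    wid <- layout$well_id[i]
    paths <- c(nuclei = file.path(indir, sprintf("%s_nuclei.tif", wid)),
               actin = file.path(indir, sprintf("%s_actin.tif", wid)),
               tracker = file.path(indir, sprintf("%s_tracker.tif", wid)))
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0L)
      stop_format(sprintf("no stacks found for well %s in %s", wid, indir))
    stk <- read_stack(paths, cal$voxel_size_xy, cal$z_step, well_id = wid)
    meas[[i]] <- measure_well(stk, layout[i, , drop = FALSE], config)$measurement
  }
  do.call(rbind, meas)
}

#' Normalize, aggregate and categorize a measured plate
#'
#' Runs the plate QC report, drops excluded wells, computes per-well
#' percent-of-control for each readout (per sample, against that sample's
#' passing control wells), aggregates technical replicates
#' (median for volume and object count, mean for single-cell count and
#' infiltration), derives the percent volume reduction and its response
#' category, and - when requested - the one-way ANOVA + post-hoc
#' comparisons on the total-volume poc.
#'
#' @param measurements per-well measurement data.frame.
#' @param layout an `ohci_layout`.
#' @param config an [default_config()] list.
#' @param readouts which readouts to normalize.
#' @param stats run [compare_groups()] on total-volume poc per sample.
#' @param reference `NULL` for Tukey all-pairs, or a condition name for
#'   Dunnett.
#' @param poc_reference optional condition to normalize against instead of
#'   the control wells (e.g. a naive-effector condition for infiltration);
#'   `NULL` uses each sample's passing control wells.
#' @return List of class `ohci_analysis`: `qc` (the QC report), `poc`
#'   (per-well long data.frame), `summaries` (per sample x condition x dose x
#'   readout with `summary`, `sd`, `n`, `low_n`, `reduction_percent`,
#'   `response_category` for volume), `stats` (per-sample
#'   `ohci_comparison` or `NULL`).
#' @export
analyze_measurements <- function(measurements, layout, config = default_config(),
                                 readouts = c("total_volume", "object_count",
                                              "single_cell_count",
                                              "infiltration_fraction"),
                                 stats = TRUE, reference = NULL,
                                 poc_reference = NULL) {
  qc <- plate_qc_report(measurements, layout, config)
  lay <- as.data.frame(layout)
  m <- merge(lay[, c("well_id", "sample_id", "condition", "dose",
                     "replicate_group", "is_control")],
             measurements, by = "well_id")
  m <- m[m$qc_flag == "pass", , drop = FALSE]
  col_of <- c(total_volume = "total_volume_mm3",
              object_count = "object_count",
              single_cell_count = "single_cell_count",
              infiltration_fraction = "infiltration_fraction",
              median_object_volume = "median_object_volume_um3")
  poc_rows <- list()
  for (sid in unique(m$sample_id)) {
    ms <- m[m$sample_id == sid, , drop = FALSE]
    ctrl <- if (is.null(poc_reference)) ms[ms$is_control, , drop = FALSE]
            else ms[ms$condition == poc_reference, , drop = FALSE]
    for (r in readouts) {
      cl <- col_of[[r]]
      v <- ms[[cl]]
      cv <- ctrl[[cl]]
      if (all(!is.finite(cv))) next  # readout absent (e.g. no tracker channel)
      poc <- percent_of_control(v, cv, config$normalization$control_summary)
      poc_rows[[length(poc_rows) + 1L]] <-
        data.frame(sample_id = sid, well_id = ms$well_id,
                   condition = ms$condition, dose = ms$dose,
                   replicate_group = ms$replicate_group,
                   is_control = ms$is_control,
                   readout = r, value = v, poc = poc,
                   stringsAsFactors = FALSE)
    }
  }
  poc <- do.call(rbind, poc_rows)
  if (is.null(poc))
    stop_validation("no normalizable readouts (are all wells excluded?)")

  key <- paste(poc$sample_id, poc$condition, poc$dose, poc$readout, sep = "\r")
  summaries <- do.call(rbind, lapply(unique(key), function(k) {
    g <- poc[key == k, , drop = FALSE]
    a <- aggregate_replicates(g$poc, g$readout[1])
    data.frame(sample_id = g$sample_id[1], condition = g$condition[1],
               dose = g$dose[1], readout = g$readout[1],
               summary = a$summary, sd = a$sd, n = a$n, low_n = a$low_n,
               stringsAsFactors = FALSE)
  }))
  vol <- summaries$readout == "total_volume"
  summaries$reduction_percent <- NA_real_
  summaries$reduction_percent[vol] <- 100 - summaries$summary[vol]
  summaries$response_category <- NA_character_
  summaries$response_category[vol] <-
    as.character(classify_response(summaries$reduction_percent[vol]))

  st <- NULL
  if (isTRUE(stats)) {
    st <- list()
    pv <- poc[poc$readout == "total_volume", , drop = FALSE]
    for (sid in unique(pv$sample_id)) {
      g <- pv[pv$sample_id == sid, , drop = FALSE]
      cond_lab <- ifelse(is.na(g$dose), g$condition, paste0(g$condition, "@", g$dose))
      df <- data.frame(value = g$poc, group = cond_lab)
      st[[sid]] <- tryCatch(compare_groups(df, reference = reference),
                            error = function(e) NULL)
    }
  }
  structure(list(qc = qc, poc = poc, summaries = summaries, stats = st),
            class = "ohci_analysis")
}

#' @export
print.ohci_analysis <- function(x, ...) {
  cat(sprintf("<ohci_analysis> %d wells normalized, %d condition summaries\n",
              length(unique(x$poc$well_id)), nrow(x$summaries)))
  print(x$qc)
  vol <- x$summaries[x$summaries$readout == "total_volume", , drop = FALSE]
  if (nrow(vol)) {
    cat("  total-volume summaries (poc):\n")
    print(vol[, c("sample_id", "condition", "dose", "summary", "n",
                  "reduction_percent", "response_category")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write the analysis outputs as CSV tables
#'
#' @param analysis an `ohci_analysis`.
#' @param outdir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_analysis <- function(analysis, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    write_measurements(analysis$poc, file.path(outdir, "poc_per_well.csv")),
    write_measurements(analysis$summaries, file.path(outdir, "condition_summaries.csv")),
    write_measurements(analysis$qc$well_flags, file.path(outdir, "qc_well_flags.csv")),
    write_measurements(analysis$qc$group_cv, file.path(outdir, "qc_group_cv.csv")))
  if (!is.null(analysis$stats)) {
    st <- do.call(rbind, lapply(names(analysis$stats), function(sid) {
      s <- analysis$stats[[sid]]
      if (is.null(s)) return(NULL)
      cbind(sample_id = sid, method = s$method, s$comparisons)
    }))
    if (!is.null(st))
      paths <- c(paths, write_measurements(st, file.path(outdir, "comparisons.csv")))
  }
  invisible(paths)
}
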