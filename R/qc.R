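# Well- and plate-level quality gates and precision metrics.

#' Control-window QC gate
#'
#' A control well passes iff it holds at least `min_objects` multicellular
#' objects (default 50) *and* a cumulative volume of at least
#' `min_total_volume` mm³ (default 0.01), both inclusive. The sample verdict
#' fails when more than `control_fail_fraction` (default 0.5) of a sample's
#' control wells fail - without an adequate control window the volumetric
#' reduction used as the response proxy cannot be measured.
#'
#' @param measurements per-well measurement data.frame (from
#'   [measure_well()] rows) restricted to or joined with control wells.
#' @param layout an `ohci_layout`; used to find control wells and samples.
#' @param min_objects,min_total_volume gate thresholds.
#' @param control_fail_fraction sample verdict threshold.
#' @return List: `wells` (data.frame `well_id`, `sample_id`, `object_count`,
#'   `total_volume_mm3`, `pass`), `samples` (data.frame `sample_id`,
#'   `n_control`, `n_fail`, `pass`).
#' @export
control_window_qc <- function(measurements, layout,
                              min_objects = 50, min_total_volume = 0.01,
                              control_fail_fraction = 0.5) {
  ctrl <- layout[layout$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0L)
    stop_validation("layout contains no control wells")
  m <- merge(ctrl[, c("well_id", "sample_id")], measurements, by = "well_id")
  if (nrow(m) == 0L)
    stop_validation("no measurements for any control well")
  m$pass <- !is.na(m$object_count) &
    m$object_count >= min_objects & m$total_volume_mm3 >= min_total_volume
  wells <- m[, c("well_id", "sample_id", "object_count", "total_volume_mm3", "pass")]
  agg_n <- tapply(wells$pass, wells$sample_id, length)
  agg_f <- tapply(!wells$pass, wells$sample_id, sum)
  samples <- data.frame(sample_id = names(agg_n),
                        n_control = as.integer(agg_n),
                        n_fail = as.integer(agg_f),
                        pass = as.integer(agg_f) / as.integer(agg_n) <= control_fail_fraction,
                        stringsAsFactors = FALSE)
  list(wells = wells, samples = samples)
}

#' Image-quality gate for a single well
#'
#' Flags acquisition/segmentation failures that would otherwise contaminate
#' readouts: gel instability, staining perturbation, low label intensity or
#' heavy debris. A well fails if any of:
#' Background is the lower-quartile intensity and noise the MAD, so the
#' estimates stay valid even when bright debris dominates the well; the
#' foreground cut is `background + 5 MAD` (at least `min_intensity_ratio`
#' times the background). A well fails if any of:
#' \itemize{
#'   \item foreground fraction outside
#'     `[foreground_lo, foreground_hi]` (empty well / debris overgrowth);
#'   \item median foreground intensity below `min_intensity_ratio` times the
#'     background level (weak staining);
#'   \item segmentation coverage - the fraction of bright actin voxels inside
#'     the final object masks - below `min_coverage` (the segmentation does
#'     not represent the input image).
#' }
#'
#' @param stack an [image_stack()].
#' @param labels multicellular `ohci_labels` for the coverage check (may be
#'   `NULL` to skip it).
#' @param config an [default_config()] list (gates under `config$qc`).
#' @return List: `pass` (logical), `reason` (string, `""` when passing),
#'   `metrics` (foreground fraction, intensity ratio, coverage).
#' @export
image_well_qc <- function(stack, labels = NULL, config = default_config()) {
  q <- config$qc
  ch <- get_channel(stack, "actin")
  if (is.null(ch)) ch <- stack$channels[[1]]
  sub <- if (length(ch) > 2e5) ch[seq(1L, length(ch), by = ceiling(length(ch) / 2e5))] else ch
  # lower-quartile background + MAD noise stay valid even when bright debris
  # dominates the well (a median would then sit in the saturated mass)
  bgm <- max(unname(quantile(sub, 0.25)), 1)
  noise <- stats::mad(sub)
  cut <- max(bgm + 5 * noise, q$min_intensity_ratio * bgm)
  fg <- ch > cut
  fg_frac <- mean(fg)
  int_ratio <- if (any(fg)) median(ch[fg]) / max(bgm, 1) else 0
  coverage <- NA_real_
  reasons <- character(0)
  if (fg_frac < q$foreground_lo) reasons <- c(reasons, "empty_or_low_signal")
  if (fg_frac > q$foreground_hi) reasons <- c(reasons, "debris_or_overgrowth")
  if (fg_frac >= q$foreground_lo && int_ratio < q$min_intensity_ratio)
    reasons <- c(reasons, "low_label_intensity")
  if (!is.null(labels) && any(fg)) {
    coverage <- sum(labels$labels[fg] > 0L) / sum(fg)
    if (length(reasons) == 0L && coverage < q$min_coverage)
      reasons <- c(reasons, "segmentation_mismatch")
  }
  list(pass = length(reasons) == 0L,
       reason = paste(reasons, collapse = ";"),
       metrics = list(foreground_fraction = fg_frac,
                      intensity_ratio = int_ratio, coverage = coverage))
}

#' Coefficient of variation of a replicate group
#'
#' The ratio of the standard deviation to the mean, with the sample
#' (n-1 denominator) standard deviation. Used as the replicate-precision
#' metric for organoid seeding: well-behaved models show CV below 0.35.
#'
#' @param values numeric vector of positive readouts (>= 2 values).
#' @return The CV (dimensionless).
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L)
    stop_validation("CV requires at least 2 replicate values")
  if (!all(is.finite(values)) || any(values <= 0))
    stop_validation("CV is defined here for positive finite readouts")
  m <- mean(values)
  if (m == 0) stop_validation("CV undefined for zero mean")
  sd(values) / m
}

#' Edge-effect check on control wells
#'
#' Compares total volumes of edge-ring vs interior control wells with a
#' two-sided Wilcoxon rank-sum test. Verdict is `"edge_effect"` when p <
#' `edge_p` (default 0.01) *and* the edge/interior median ratio falls outside
#' `edge_ratio_band` (default 0.8-1.25); with fewer than 3 wells on either
#' side the check is `"not_evaluable"`.
#'
#' @param measurements per-well measurement data.frame.
#' @param layout an `ohci_layout`.
#' @param config an [default_config()] list.
#' @return List: `verdict` (`"no_edge_effect"`, `"edge_effect"`,
#'   `"not_evaluable"`), `p_value`, `median_ratio`, `n_edge`, `n_interior`.
#' @export
edge_effect_check <- function(measurements, layout, config = default_config()) {
  ctrl <- layout[layout$is_control, , drop = FALSE]
  m <- merge(ctrl[, c("well_id", "is_edge")], measurements, by = "well_id")
  m <- m[!is.na(m$total_volume_mm3), , drop = FALSE]
  e <- m$total_volume_mm3[m$is_edge]
  i <- m$total_volume_mm3[!m$is_edge]
  if (length(e) < 3L || length(i) < 3L)
    return(list(verdict = "not_evaluable", p_value = NA_real_,
                median_ratio = NA_real_, n_edge = length(e), n_interior = length(i)))
  p <- suppressWarnings(wilcox.test(e, i)$p.value)
  ratio <- median(e) / median(i)
  band <- config$qc$edge_ratio_band
  verdict <- if (p < config$qc$edge_p && (ratio < band[1] || ratio > band[2]))
    "edge_effect" else "no_edge_effect"
  list(verdict = verdict, p_value = p, median_ratio = ratio,
       n_edge = length(e), n_interior = length(i))
}

#' Plate-level QC report
#'
#' Aggregates per-well flags into the plate exclusion fraction (excluded
#' wells / assayed wells; a warning is raised at or above
#' `config$qc$exclusion_warn`, default 4%), per-replicate-group CVs of total
#' volume, the control-window verdicts and the edge-effect check.
#'
#' @param measurements per-well measurement data.frame covering the plate.
#' @param layout an `ohci_layout`.
#' @param config an [default_config()] list.
#' @return An object of class `ohci_qc_report`: `exclusion_fraction`,
#'   `n_excluded`, `n_assayed`, `well_flags` (data.frame), `group_cv`
#'   (data.frame `replicate_group`, `n`, `cv`), `control_window`,
#'   `edge_effect`.
#' @export
plate_qc_report <- function(measurements, layout, config = default_config()) {
  m <- merge(as.data.frame(layout)[, c("well_id", "sample_id", "replicate_group",
                                       "is_control")],
             measurements, by = "well_id")
  excluded <- m$qc_flag != "pass"
  cw <- control_window_qc(measurements, layout,
                          min_objects = config$qc$min_control_objects,
                          min_total_volume = config$qc$min_control_volume_mm3,
                          control_fail_fraction = config$qc$control_fail_fraction)
  groups <- split(m[!excluded, , drop = FALSE],
                  m$replicate_group[!excluded])
  group_cv <- data.frame(
    replicate_group = names(groups),
    n = vapply(groups, nrow, 1L),
    cv = vapply(groups, function(g)
      if (nrow(g) >= 2L && all(g$total_volume_mm3 > 0)) cv_percent(g$total_volume_mm3)
      else NA_real_, 1.0),
    stringsAsFactors = FALSE)
  edge <- edge_effect_check(m, layout, config)
  frac <- mean(excluded)
  if (frac >= config$qc$exclusion_warn)
    warning(sprintf("%.1f%% of wells excluded (threshold %.0f%%)",
                    100 * frac, 100 * config$qc$exclusion_warn))
  structure(list(exclusion_fraction = frac,
                 n_excluded = sum(excluded), n_assayed = nrow(m),
                 well_flags = m[, c("well_id", "sample_id", "replicate_group",
                                    "is_control", "qc_flag", "qc_reason")],
                 group_cv = group_cv,
                 control_window = cw,
                 edge_effect = edge),
            class = "ohci_qc_report")
}

#' @export
print.ohci_qc_report <- function(x, ...) {
  cat(sprintf("<ohci_qc_report> %d/%d wells excluded (%.2f%%)\n",
              x$n_excluded, x$n_assayed, 100 * x$exclusion_fraction))
  cat(sprintf("  control window: %d/%d sample(s) pass\n",
              sum(x$control_window$samples$pass), nrow(x$control_window$samples)))
  cv <- x$group_cv$cv
  if (any(is.finite(cv)))
    cat(sprintf("  replicate CV (total volume): median %.3f, max %.3f\n",
                median(cv, na.rm = TRUE), max(cv, na.rm = TRUE)))
  cat(sprintf("  edge effect: %s\n", x$edge_effect$verdict))
  invisible(x)
}
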