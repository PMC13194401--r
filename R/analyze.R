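# Percent-of-control normalization, replicate aggregation, response
# categories, and the group-comparison statistics reported for these screens.

#' Percent-of-control normalization
#'
#' `poc = 100 * value / mean(passing control values)`; control wells are
#' normalized too, so their mean poc is exactly 100. The control summary can
#' be switched to the median via `control_summary`.
#'
#' @param values numeric readout per well (excluded wells already dropped).
#' @param control_values readouts of the passing control wells.
#' @param control_summary `"mean"` (default) or `"median"`.
#' @return Numeric vector of poc values, parallel to `values`.
#' @export
percent_of_control <- function(values, control_values, control_summary = "mean") {
  control_values <- control_values[is.finite(control_values)]
  if (length(control_values) == 0L)
    stop(errorCondition("no passing control wells to normalize against",
                        class = c("ohci_normalization_error", "error", "condition")))
  denom <- if (identical(control_summary, "median")) median(control_values)
           else mean(control_values)
  if (!is.finite(denom) || denom == 0)
    stop(errorCondition("degenerate control summary (zero or non-finite)",
                        class = c("ohci_normalization_error", "error", "condition")))
  100 * values / denom
}

# Per-readout replicate summary convention: size/volume and object count are
# summarized by the median (robust to single-well outliers in heterogeneous
# tissue), single-cell count and infiltration by the mean.
readout_summary_fun <- function(readout) {
  if (readout %in% c("total_volume", "object_count", "median_object_volume"))
    median else mean
}

#' Aggregate technical replicates of a normalized readout
#'
#' Median for `total_volume` and `object_count`, mean for
#' `single_cell_count` and `infiltration_fraction`. Also reports the SD and
#' flags groups left with fewer than 2 surviving replicates.
#'
#' @param poc numeric poc values of the surviving replicate wells.
#' @param readout one of `"total_volume"`, `"object_count"`,
#'   `"single_cell_count"`, `"infiltration_fraction"`
#'   (also accepts `"median_object_volume"`, summarized like volume).
#' @return List: `summary`, `sd`, `n`, `low_n`.
#' @export
aggregate_replicates <- function(poc, readout) {
  poc <- poc[is.finite(poc)]
  if (length(poc) == 0L)
    stop_validation("no surviving replicates to aggregate")
  f <- readout_summary_fun(readout)
  list(summary = f(poc),
       sd = if (length(poc) >= 2L) sd(poc) else NA_real_,
       n = length(poc),
       low_n = length(poc) < 2L)
}

#' Categorize a sample response from its volume reduction
#'
#' Stepwise categories on the percent reduction of tumor volume
#' (`100 - poc`): below 10% (including growth) is a non-responder, then
#' half-open bins `[10, 31)`, `[31, 51)`, `[51, 71)` and `[71, Inf)` carrying
#' the conventional labels `"10-30"`, `"31-50"`, `"51-70"`, `">71"`.
#'
#' @param reduction_percent numeric vector (negative = growth).
#' @return Factor with levels `non-responder`, `10-30`, `31-50`, `51-70`,
#'   `>71`.
#' @export
classify_response <- function(reduction_percent) {
  if (!is.numeric(reduction_percent) || any(!is.finite(reduction_percent)))
    stop_validation("reduction_percent must be finite numeric")
  cut(reduction_percent,
      breaks = c(-Inf, 10, 31, 51, 71, Inf), right = FALSE,
      labels = c("non-responder", "10-30", "31-50", "51-70", ">71"))
}

p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 0.005, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Group comparisons: ANOVA with Tukey or Dunnett post-hoc tests
#'
#' Fits a fixed-effects ANOVA on well-level values (one-way on `group`, or
#' two-way `value ~ group + group2`) and reports adjusted p-values for all
#' pairs (Tukey honest significant differences, studentized-range) or
#' many-to-one against a named reference (Dunnett). Significance stars
#' follow the screening convention: `*` p<0.05, `**` p<0.01, `***` p<0.005,
#' `****` p<0.0001.
#'
#' @param data data.frame with columns `value`, `group`, and optionally
#'   `group2` for a two-way design.
#' @param design `"one-way"` or `"two-way"`.
#' @param reference `NULL` for all-pairs Tukey, or the control group name
#'   for Dunnett many-to-one comparisons.
#' @return List of class `ohci_comparison`: `anova` (data.frame with the F
#'   test(s)), `comparisons` (data.frame `comparison`, `estimate`, `p_adj`,
#'   `stars`), `method`.
#' @export
compare_groups <- function(data, design = c("one-way", "two-way"), reference = NULL) {
  design <- match.arg(design)
  if (!all(c("value", "group") %in% names(data)))
    stop_validation("`data` needs columns `value` and `group`")
  data <- data[is.finite(data$value), , drop = FALSE]
  data$group <- factor(data$group)
  sizes <- table(data$group)
  if (any(sizes < 2L)) {
    warning(sprintf("dropping group(s) with fewer than 2 wells: %s",
                    paste(names(sizes)[sizes < 2L], collapse = ", ")))
    data <- data[data$group %in% names(sizes)[sizes >= 2L], , drop = FALSE]
    data$group <- droplevels(data$group)
  }
  if (nlevels(data$group) < 2L)
    stop_validation("need at least 2 groups with >= 2 wells each")
  if (design == "two-way") {
    if (!"group2" %in% names(data))
      stop_validation("two-way design needs a `group2` column")
    data$group2 <- factor(data$group2)
    fit <- aov(value ~ group + group2, data = data)
  } else {
    fit <- aov(value ~ group, data = data)
  }
  an <- summary(fit)[[1]]
  anova_df <- data.frame(term = trimws(rownames(an)),
                         df = an$Df, F = an$`F value`, p = an$`Pr(>F)`)
  if (is.null(reference)) {
    tk <- TukeyHSD(fit, which = "group")$group
    comps <- data.frame(comparison = rownames(tk),
                        estimate = tk[, "diff"],
                        p_adj = tk[, "p adj"],
                        stringsAsFactors = FALSE)
    method <- "Tukey"
  } else {
    if (!reference %in% levels(data$group))
      stop_validation(sprintf("reference group '%s' not present", reference))
    data$group <- stats::relevel(data$group, ref = reference)
    fit <- if (design == "two-way") aov(value ~ group + group2, data = data)
           else aov(value ~ group, data = data)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    comps <- data.frame(comparison = names(sm$test$coefficients),
                        estimate = as.numeric(sm$test$coefficients),
                        p_adj = as.numeric(sm$test$pvalues),
                        stringsAsFactors = FALSE)
    method <- "Dunnett"
  }
  comps$p_adj[is.nan(comps$p_adj)] <- 1
  comps$stars <- p_stars(comps$p_adj)
  rownames(comps) <- NULL
  structure(list(anova = anova_df, comparisons = comps, method = method),
            class = "ohci_comparison")
}

#' @export
print.ohci_comparison <- function(x, ...) {
  f <- x$anova[1, ]
  cat(sprintf("<ohci_comparison> %s ANOVA: F = %.4g, p = %.3g; %s post-hoc:\n",
              if (nrow(x$anova) > 2) "two-way" else "one-way", f$F, f$p, x$method))
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Build a dose-response table
#'
#' Long-format table of replicate summaries across doses per sample,
#' compound and readout, ready for heatmap rendering, with monotone dose
#' trends flagged by the sign of the Spearman correlation between dose and
#' summary (|rho| >= `rho_cut`).
#'
#' @param readouts data.frame with columns `sample_id`, `condition`, `dose`,
#'   `readout`, `summary` (one row per condition x dose x readout, as
#'   produced by replicate aggregation).
#' @param rho_cut Spearman threshold for calling a trend (default 0.8).
#' @return The input with an added `trend` column
#'   (`"decreasing"`, `"increasing"` or `""`), per sample/condition/readout.
#' @export
build_dose_table <- function(readouts, rho_cut = 0.8) {
  req <- c("sample_id", "condition", "dose", "readout", "summary")
  miss <- setdiff(req, names(readouts))
  if (length(miss))
    stop_validation(sprintf("dose table missing column(s): %s", paste(miss, collapse = ", ")))
  key <- interaction(readouts$sample_id, readouts$condition, readouts$readout, drop = TRUE)
  trend <- rep("", nrow(readouts))
  for (k in levels(key)) {
    i <- which(key == k)
    d <- readouts$dose[i]; s <- readouts$summary[i]
    ok <- is.finite(d) & is.finite(s)
    if (sum(ok) < 2L) next
    rho <- suppressWarnings(cor(d[ok], s[ok], method = "spearman"))
    if (is.na(rho)) next
    if (rho <= -rho_cut) trend[i] <- "decreasing"
    else if (rho >= rho_cut) trend[i] <- "increasing"
  }
  readouts$trend <- trend
  readouts
}
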