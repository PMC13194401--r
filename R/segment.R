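# 3D segmentation: nucleus/tracker blob detection and actin-defined object
# segmentation. The pipeline is deliberately classical - anisotropic Gaussian
# smoothing, global Otsu threshold, per-slice morphological closing and hole
# filling, 26-connected 3D components - with every threshold exposed in the
# configuration.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 0.15) return(1)
  h <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-h:h)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable anisotropic Gaussian smoothing; sigma is physical (µm) and is
# divided by the per-axis spacing, so 20-50 µm z-steps get (correctly) almost
# no axial smoothing.
smooth_channel <- function(arr, sigma_um, voxel_size_xy, z_step) {
  d <- dim(arr)
  kxy <- gaussian_kernel_1d(sigma_um / voxel_size_xy)
  kz <- gaussian_kernel_1d(sigma_um / z_step)
  if (is.integer(arr)) storage.mode(arr) <- "double"
  conv_sep_3d(arr, d[1], d[2], d[3], kxy, kxy, kz)
}

# Otsu's threshold from a 512-bin histogram of the supplied intensities
# (uniform bins, so binning is plain arithmetic; intensities are subsampled
# beyond 1e6 values - the histogram shape is what matters).
otsu_threshold <- function(values, n_bins = 512L) {
  values <- values[is.finite(values)]
  if (length(values) > 1e6)
    values <- values[seq(1L, length(values), by = ceiling(length(values) / 1e6))]
  if (length(values) == 0L) return(Inf)
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(hi)
  bin <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  h <- as.double(tabulate(bin, n_bins))
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Robust background statistics: median and a MAD-based noise sd, estimated
# on a deterministic strided subsample (background dominates these stacks,
# so ~2e5 voxels estimate both to well under a grey level).
background_stats <- function(arr, max_n = 2e5) {
  v <- arr
  if (length(v) > max_n) v <- v[seq(1L, length(v), by = ceiling(length(v) / max_n))]
  med <- median(v)
  sdev <- stats::mad(v, center = med)
  if (sdev == 0) sdev <- sd(v)
  list(median = med, sd = sdev)
}

point_set <- function(coords, kind, voxel_size_xy, z_step) {
  df <- as.data.frame(coords)
  names(df) <- c("y", "x", "z")[seq_len(ncol(df))]
  if (nrow(df)) {
    df$x_um <- (df$x - 0.5) * voxel_size_xy
    df$y_um <- (df$y - 0.5) * voxel_size_xy
    df$z_um <- (df$z - 0.5) * z_step
  } else {
    df$x_um <- df$y_um <- df$z_um <- numeric(0)
  }
  structure(df, kind = kind, class = c("ohci_points", "data.frame"))
}

# Shared blob detector for the nuclei and tracker channels: smooth, subtract
# the median background, threshold (Otsu on positive residuals, floored at
# `blob_floor_sd` background sd so blank wells yield nothing), then local
# maxima with a minimum-separation window.
detect_blobs <- function(arr, kind, min_separation, config, voxel_size_xy, z_step) {
  seg <- config$segmentation
  sm <- smooth_channel(arr, seg$smooth_sigma, voxel_size_xy, z_step)
  bg <- background_stats(sm)
  res <- sm - bg$median
  floor_sd <- if (is.null(seg$blob_floor_sd)) 8 else seg$blob_floor_sd
  thr <- if (is.numeric(seg$threshold)) seg$threshold else {
    pos <- res[res > 0]
    max(otsu_threshold(pos), floor_sd * bg$sd)
  }
  d <- dim(arr)
  hxy <- max(1L, as.integer(round(min_separation / voxel_size_xy)))
  hz <- max(0L, as.integer(round(min_separation / z_step)))
  pk <- local_maxima_3d(res, d[1], d[2], d[3], hxy, hxy, hz, thr)
  point_set(pk, kind, voxel_size_xy, z_step)
}

#' Detect nuclei in the nuclei channel
#'
#' One centroid per resolvable nucleus: anisotropic Gaussian smoothing,
#' median-background subtraction, Otsu threshold on the positive residuals
#' (floored at `blob_floor_sd` background standard deviations; overridable via
#' `segmentation$threshold`), and 3D local-maximum seeding with a minimum
#' separation of one nucleus diameter. Two blobs closer than the minimum
#' separation merge into a single detection.
#'
#' @param stack an [image_stack()] with a `nuclei` channel.
#' @param config an [default_config()] list.
#' @return A point set (data.frame, voxel indices `y, x, z` plus physical
#'   `x_um, y_um, z_um`) of kind `"nucleus"`.
#' @export
detect_nuclei <- function(stack, config = default_config()) {
  ch <- get_channel(stack, "nuclei")
  if (is.null(ch)) stop_validation("stack has no nuclei channel")
  detect_blobs(ch, "nucleus", config$segmentation$nucleus_min_separation,
               config, stack$voxel_size_xy, stack$z_step)
}

#' Detect tracker-labeled immune cells
#'
#' Same detector family as [detect_nuclei()] with tracker-specific defaults.
#' A missing tracker channel yields an empty point set with a warning, since
#' label-free assay variants are valid.
#'
#' @inheritParams detect_nuclei
#' @param quiet suppress the missing-channel warning.
#' @return A point set of kind `"tracker_cell"`.
#' @export
detect_tracker_cells <- function(stack, config = default_config(), quiet = FALSE) {
  ch <- get_channel(stack, "tracker")
  if (is.null(ch)) {
    if (!quiet) warning("no tracker channel; returning an empty point set")
    return(point_set(matrix(integer(0), 0, 3), "tracker_cell",
                     stack$voxel_size_xy, stack$z_step))
  }
  detect_blobs(ch, "tracker_cell", config$segmentation$tracker_min_separation,
               config, stack$voxel_size_xy, stack$z_step)
}

label_volume <- function(labels, n, voxel_size_xy, z_step, provenance = list()) {
  structure(list(labels = labels, n = as.integer(n),
                 voxel_size_xy = voxel_size_xy, z_step = z_step,
                 provenance = provenance),
            class = "ohci_labels")
}

#' @export
print.ohci_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<ohci_labels> %d object(s) in %dx%dx%d grid (%s)\n",
              x$n, d[1], d[2], d[3],
              if (length(x$provenance)) x$provenance$channel else "?"))
  invisible(x)
}

#' Segment actin-defined multicellular objects
#'
#' Smoothing, global threshold (Otsu over the whole smoothed channel, floored
#' at background + 5 sd so an all-background image yields an empty labeling),
#' per-slice morphological closing (disc, radius
#' `segmentation$closing_radius_px`), per-slice hole filling, 26-connected 3D
#' components, and removal of components smaller than the volume of a
#' `min_object_diameter` sphere (debris). Touching tumoroids merge into one
#' component; no watershed splitting is attempted.
#'
#' @param stack an [image_stack()] with an `actin` channel.
#' @param config an [default_config()] list.
#' @return An `ohci_labels` object: 3D integer grid with consecutive labels
#'   1..K (0 = background) plus provenance.
#' @export
segment_actin_objects <- function(stack, config = default_config()) {
  ch <- get_channel(stack, "actin")
  if (is.null(ch)) stop_validation("stack has no actin channel")
  seg <- config$segmentation
  vox <- stack$voxel_size_xy; zst <- stack$z_step
  sm <- smooth_channel(ch, seg$smooth_sigma, vox, zst)
  bg <- background_stats(sm)
  thr <- if (is.numeric(seg$threshold)) seg$threshold
         else max(otsu_threshold(sm), bg$median + 5 * bg$sd)
  mask <- sm > thr
  d <- dim(ch)
  if (any(mask)) {
    if (seg$closing_radius_px > 0) {
      brush <- EBImage::makeBrush(2L * seg$closing_radius_px + 1L, "disc")
      mask <- EBImage::closing(mask, brush) > 0
    }
    if (isTRUE(seg$fill_holes)) mask <- EBImage::fillHull(mask) > 0
    dim(mask) <- d
  }
  lab <- cc_label_26(mask, d[1], d[2], d[3])
  n <- max(lab)
  if (n > 0) {
    min_vox <- max(1, round(pi / 6 * seg$min_object_diameter^3 / (vox^2 * zst)))
    sizes <- tabulate(lab[lab > 0L], n)
    keep <- which(sizes >= min_vox)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n <- length(keep)
  }
  label_volume(lab, n, vox, zst,
               provenance = list(channel = "actin", threshold = thr,
                                 parameters = seg))
}

#' Split segmented objects into multicellular clusters and single cells
#'
#' An actin component is multicellular iff its equivalent diameter is at
#' least `classification$single_cell_max_diameter` (default 30 µm) *and* it
#' contains at least `classification$min_nuclei` (default 2) nucleus
#' centroids; the nucleus rule dominates, so a 60 µm component with one
#' nucleus is a single cell. Nuclei of non-multicellular components and
#' nuclei outside any component all count as single cells, so every detected
#' nucleus is assigned exactly once:
#' `single cells + nuclei inside multicellular objects = detected nuclei`.
#' A nucleus on a component's voxel belongs to that component; on a
#' background voxel it is a single cell.
#'
#' @param objects an `ohci_labels` from [segment_actin_objects()].
#' @param nuclei a point set from [detect_nuclei()].
#' @param config an [default_config()] list.
#' @return List: `multicellular` (`ohci_labels`, relabeled consecutively),
#'   `single_cells` (point set), `nuclei_per_object` (integer vector over the
#'   relabeled objects), `nucleus_object` (per-nucleus multicellular object
#'   id, 0 = single cell).
#' @export
classify_objects <- function(objects, nuclei, config = default_config()) {
  scd <- config$classification$single_cell_max_diameter
  if (!is.numeric(scd) || scd <= 0)
    stop_validation("classification$single_cell_max_diameter must be positive")
  lab <- objects$labels
  n <- objects$n
  voxvol <- objects$voxel_size_xy^2 * objects$z_step
  nuc_lab <- if (nrow(nuclei)) lab[cbind(nuclei$y, nuclei$x, nuclei$z)] else integer(0)
  if (n == 0L) {
    return(list(multicellular = objects, single_cells = nuclei,
                nuclei_per_object = integer(0),
                nucleus_object = rep(0L, nrow(nuclei))))
  }
  sizes <- tabulate(lab[lab > 0L], n)
  eqd <- (6 * sizes * voxvol / pi)^(1 / 3)
  nnuc <- tabulate(nuc_lab[nuc_lab > 0L], n)
  is_mc <- eqd >= scd & nnuc >= config$classification$min_nuclei
  remap <- integer(n)
  remap[is_mc] <- seq_len(sum(is_mc))
  mc <- lab
  mc[mc > 0L] <- remap[mc[mc > 0L]]
  dim(mc) <- dim(lab)
  nucleus_object <- ifelse(nuc_lab > 0L, remap[pmax(nuc_lab, 1L)], 0L)
  nucleus_object[nuc_lab == 0L] <- 0L
  singles <- nuclei[nucleus_object == 0L, , drop = FALSE]
  attr(singles, "kind") <- "nucleus"
  list(multicellular = label_volume(mc, sum(is_mc), objects$voxel_size_xy,
                                    objects$z_step,
                                    provenance = objects$provenance),
       single_cells = singles,
       nuclei_per_object = tabulate(nucleus_object[nucleus_object > 0L], sum(is_mc)),
       nucleus_object = as.integer(nucleus_object))
}
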