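# Rendering: turn a ground-truth scene into the multi-channel stack a
# high-content imager would record. Nuclei and tracker cells are Gaussian
# blobs, tumoroid bodies are uniformly bright in the actin channel, single
# cells carry a thin actin shell; constant background plus Poisson shot noise
# on signal and Gaussian read noise everywhere.

#' Imaging calibration and noise parameters for [render_well()]
#' @param config an [default_config()] list.
#' @return List of calibration, intensity and noise parameters.
#' @export
imaging_defaults <- function(config = default_config()) {
  c(config$calibration, config$generator[c("background", "read_noise_sd",
    "actin_intensity", "shell_intensity", "nucleus_peak", "tracker_peak",
    "nucleus_sigma", "single_cell_diameter")])
}

# Paint filled spheres (or shells, when r_inner > 0) into a (y,x,z) array.
paint_spheres <- function(arr, cx, cy, cz, r, value, vox, zst, r_inner = NULL) {
  d <- dim(arr)
  for (i in seq_along(cx)) {
    ix <- max(1L, floor((cx[i] - r[i]) / vox)):min(d[2], ceiling((cx[i] + r[i]) / vox) + 1L)
    iy <- max(1L, floor((cy[i] - r[i]) / vox)):min(d[1], ceiling((cy[i] + r[i]) / vox) + 1L)
    iz <- max(1L, floor((cz[i] - r[i]) / zst)):min(d[3], ceiling((cz[i] + r[i]) / zst) + 1L)
    dx2 <- ((ix - 0.5) * vox - cx[i])^2
    dy2 <- ((iy - 0.5) * vox - cy[i])^2
    dz2 <- ((iz - 0.5) * zst - cz[i])^2
    d2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
    m <- d2 <= r[i]^2
    if (!is.null(r_inner)) m <- m & d2 >= r_inner[i]^2
    sub <- arr[iy, ix, iz, drop = FALSE]
    sub[m] <- pmax(sub[m], value)
    arr[iy, ix, iz] <- sub
  }
  arr
}

# Accumulate Gaussian blobs at continuous positions (µm) into a (y,x,z) array.
paint_blobs <- function(arr, px, py, pz, peak, sigma, vox, zst) {
  n <- length(px)
  if (n == 0L) return(arr)
  d <- dim(arr)
  hxy <- max(1L, ceiling(2 * sigma / vox))
  hz <- if (zst > 3 * sigma) 0L else max(1L, ceiling(2 * sigma / zst))
  iy0 <- pmin(pmax(ceiling(py / vox), 1L), d[1])
  ix0 <- pmin(pmax(ceiling(px / vox), 1L), d[2])
  iz0 <- pmin(pmax(ceiling(pz / zst), 1L), d[3])
  idxs <- vals <- vector("list", (2 * hxy + 1)^2 * (2 * hz + 1))
  k <- 0L
  for (dz in -hz:hz) for (dx in -hxy:hxy) for (dy in -hxy:hxy) {
    yy <- iy0 + dy; xx <- ix0 + dx; zz <- iz0 + dz
    ok <- yy >= 1L & yy <= d[1] & xx >= 1L & xx <= d[2] & zz >= 1L & zz <= d[3]
    if (!any(ok)) next
    # physical offset from blob centre to voxel centre
    ddy <- (yy[ok] - 0.5) * vox - py[ok]
    ddx <- (xx[ok] - 0.5) * vox - px[ok]
    # wide optical sections integrate the whole slab: a blob contributes its
    # full axial weight to the section containing it (hz = 0); only when the
    # z-step resolves the blob is the axial Gaussian evaluated
    ddz <- if (hz == 0L) 0 else (zz[ok] - 0.5) * zst - pz[ok]
    w <- exp(-(ddy^2 + ddx^2 + ddz^2) / (2 * sigma^2))
    k <- k + 1L
    idxs[[k]] <- yy[ok] + (xx[ok] - 1) * d[1] + (zz[ok] - 1) * d[1] * d[2]
    vals[[k]] <- peak * w
  }
  idx <- unlist(idxs[seq_len(k)], use.names = FALSE)
  val <- unlist(vals[seq_len(k)], use.names = FALSE)
  out <- scatter_add(arr, idx, val)
  dim(out) <- d
  out
}

#' Render a well scene into an image stack
#'
#' @param scene an [sample_scene()] result.
#' @param imaging calibration and noise parameters (see
#'   [default_config()]`$calibration` and the intensity/noise fields of
#'   `$generator`); internally assembled by `imaging_defaults()`.
#' @param seed integer; rendering (noise) is deterministic per seed.
#' @return An [image_stack()] with `nuclei` and `actin` channels, plus a
#'   `tracker` channel when the scene contains labeled cells.
#' @export
render_well <- function(scene, imaging = imaging_defaults(), seed = 1L) {
  im <- imaging
  assert_scalar_pos(im$voxel_size_xy, "voxel_size_xy")
  assert_scalar_pos(im$z_step, "z_step")
  if (!all(is.finite(c(im$background, im$read_noise_sd))))
    stop_validation("noise parameters must be finite")
  vox <- im$voxel_size_xy; zst <- im$z_step
  ny <- nx <- as.integer(round(im$field_xy / vox))
  nz <- as.integer(im$n_sections)
  tum <- scene$tumoroids
  if (nrow(tum) &&
      (max(tum$x + tum$equivalent_diameter_um / 2) > im$field_xy ||
       max(tum$y + tum$equivalent_diameter_um / 2) > im$field_xy ||
       max(tum$z + tum$equivalent_diameter_um / 2) > nz * zst))
    stop_generation("imaging field too small for the scene extent")
  set.seed(as.integer(seed))

  actin <- array(0, c(ny, nx, nz))
  if (nrow(tum))
    actin <- paint_spheres(actin, tum$x, tum$y, tum$z,
                           tum$equivalent_diameter_um / 2, im$actin_intensity, vox, zst)
  sc <- scene$single_cells
  if (nrow(sc)) {
    r_out <- rep(im$single_cell_diameter / 2, nrow(sc))
    actin <- paint_spheres(actin, sc$x, sc$y, sc$z, r_out, im$shell_intensity,
                           vox, zst, r_inner = r_out * 0.5)
  }

  nucl <- array(0, c(ny, nx, nz))
  npx <- c(scene$nuclei$x, sc$x, scene$labeled_cells$x)
  npy <- c(scene$nuclei$y, sc$y, scene$labeled_cells$y)
  npz <- c(scene$nuclei$z, sc$z, scene$labeled_cells$z)
  nucl <- paint_blobs(nucl, npx, npy, npz, im$nucleus_peak, im$nucleus_sigma, vox, zst)

  has_tracker <- nrow(scene$labeled_cells) > 0 || isTRUE(scene$params_used$tracker)
  channels <- list(nuclei = nucl, actin = actin)
  if (has_tracker) {
    trk <- array(0, c(ny, nx, nz))
    lc <- scene$labeled_cells
    trk <- paint_blobs(trk, lc$x, lc$y, lc$z, im$tracker_peak, im$nucleus_sigma, vox, zst)
    channels$tracker <- trk
  }

  channels <- lapply(channels, add_camera_noise,
                     background = im$background, read_sd = im$read_noise_sd)
  image_stack(channels, names(channels), vox, zst, well_id = NA_character_)
}

#' Simulate a whole screening plate with ground truth
#'
#' Per-well seeds are derived deterministically from `master_seed` and the
#' well id, so plates are reproducible and wells independent. Wells of the
#' same sample share a seeding intensity: the sample's tumoroid count
#' is drawn uniformly from the configured range and each well's count is
#' Poisson around it (clamped to the range), mirroring replicate dispensing
#' from a single suspension.
#'
#' @param layout an [plate_layout()]; every condition present must have an
#'   entry in `effects` (control conditions may rely on the `control`
#'   fallback, a null effect).
#' @param effects named list of [effect_model()]s keyed by condition.
#' @param master_seed integer.
#' @param config an [default_config()] list.
#' @param outdir optional run directory: writes one TIFF per well per
#'   channel, per-well truth tables (CSV) and the parameter echo (YAML).
#' @param keep_stacks return rendered stacks in memory (default only when no
#'   `outdir` is given; a full plate of stacks is large).
#' @return List with `truth` (named list of `ohci_scene`), `stacks` (named
#'   list of `ohci_stack`, if kept), `paths` (if written), and `layout`.
#' @export
simulate_plate <- function(layout, effects, master_seed = 1L,
                           config = default_config(), outdir = NULL,
                           keep_stacks = is.null(outdir)) {
  conds <- unique(layout$condition)
  miss <- setdiff(conds, names(effects))
  ctrl_conds <- unique(layout$condition[layout$is_control])
  miss <- setdiff(miss, ctrl_conds)  # controls default to the null effect
  if (length(miss))
    stop_validation(sprintf("no effect model for condition(s): %s",
                            paste(miss, collapse = ", ")))
  for (cc in setdiff(ctrl_conds, names(effects))) effects[[cc]] <- null_effect()

  params <- scene_defaults(config)
  imaging <- imaging_defaults(config)
  group_count <- group_seed_counts(layout, params, master_seed)

  truth <- stacks <- list()
  paths <- list()
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (i in seq_len(nrow(layout))) {
    wid <- layout$well_id[i]
    wseed <- derive_seed(master_seed, wid)
    p <- params
    p$count_fixed <- well_count(group_count[[layout$sample_id[i]]], wseed, params)
    scene <- sample_scene(p, effects[[layout$condition[i]]], seed = wseed)
    stk <- render_well(scene, imaging, seed = derive_seed(master_seed, paste0(wid, ":img")))
    stk$well_id <- wid
    truth[[wid]] <- scene
    if (keep_stacks) stacks[[wid]] <- stk
    if (!is.null(outdir)) {
      paths[[wid]] <- write_stack(stk, outdir, prefix = wid)
      tdir <- file.path(outdir, "truth")
      if (!dir.exists(tdir)) dir.create(tdir)
      write.csv(scene$tumoroids, file.path(tdir, sprintf("%s_tumoroids.csv", wid)),
                row.names = FALSE)
      write.csv(scene$labeled_cells, file.path(tdir, sprintf("%s_labeled_cells.csv", wid)),
                row.names = FALSE)
    }
  }
  if (!is.null(outdir)) {
    write_config(config, file.path(outdir, "params.yaml"))
    write.csv(as.data.frame(layout), file.path(outdir, "layout.csv"), row.names = FALSE)
  }
  invisible(list(truth = truth, stacks = stacks, paths = paths, layout = layout))
}

# Per-sample seeding intensity drawn uniformly from the count range: all
# wells of a sample are dispensed from one cell suspension, so they share a
# seeding density; per-well counts are Poisson around it.
group_seed_counts <- function(layout, params, master_seed) {
  samples <- unique(layout$sample_id)
  out <- lapply(samples, function(s) {
    set.seed(derive_seed(master_seed, paste0("sample:", s)))
    runif(1, params$count_range[1], params$count_range[2])
  })
  names(out) <- samples
  out
}

well_count <- function(lambda, wseed, params) {
  set.seed(derive_seed(wseed, "count"))
  min(max(rpois(1, lambda), params$count_range[1]), params$count_range[2])
}
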