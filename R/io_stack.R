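#' Construct a multi-channel 3D image stack
#'
#' The in-memory container for one well: one 3D voxel grid per channel plus
#' physical calibration. Channels are stored as `(y, x, z)` arrays; voxel
#' `(i, j, k)` is centred at `((i - 0.5) * voxel_size_xy, (j - 0.5) *
#' voxel_size_xy, (k - 0.5) * z_step)` µm.
#'
#' @param channels list of 3D numeric arrays, all of identical dimension.
#' @param channel_roles character vector, one of `"nuclei"`, `"actin"`,
#'   `"tracker"` per channel.
#' @param voxel_size_xy,z_step physical voxel spacing in µm.
#' @param well_id optional plate coordinate such as `"B07"`.
#' @return An object of class `ohci_stack`.
#' @details Stacks with fewer than 20 or more than 80 sections, or a z-step
#'   outside 20-50 µm, are accepted with a warning: acquisition for these
#'   assays uses 20-80 sections at 20-50 µm steps to span the gel.
#' @export
image_stack <- function(channels, channel_roles, voxel_size_xy, z_step,
                        well_id = NA_character_) {
  if (!is.list(channels) || length(channels) == 0L)
    stop_validation("`channels` must be a non-empty list of 3D arrays")
  if (length(channel_roles) != length(channels))
    stop_validation("one role per channel is required")
  bad <- setdiff(channel_roles, c("nuclei", "actin", "tracker"))
  if (length(bad))
    stop_validation(sprintf("unknown channel role(s): %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(channel_roles))
    stop_validation("channel roles must be unique")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop_format("every channel must be a 3D (y, x, z) array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop_format("all channels must share an identical (y, x, z) shape")
  for (ch in channels) {
    if (!all(is.finite(ch))) stop_validation("intensities must be finite")
    if (min(ch) < 0) stop_validation("intensities must be non-negative")
  }
  assert_scalar_pos(voxel_size_xy, "voxel_size_xy")
  assert_scalar_pos(z_step, "z_step")
  nz <- dims[[1]][3]
  if (nz < 20L || nz > 80L)
    warning(sprintf("stack has %d sections; acquisition typically uses 20-80", nz))
  if (z_step < 20 || z_step > 50)
    warning(sprintf("z_step %.1f um outside the typical 20-50 um range", z_step))
  structure(
    list(channels = channels, channel_roles = as.character(channel_roles),
         voxel_size_xy = voxel_size_xy, z_step = z_step, well_id = well_id),
    class = "ohci_stack")
}

#' @export
print.ohci_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<ohci_stack> well %s: %d channel(s) [%s], %dx%d px x %d sections, %.2g um/px, z-step %.3g um\n",
              x$well_id, length(x$channels), paste(x$channel_roles, collapse = ", "),
              d[1], d[2], d[3], x$voxel_size_xy, x$z_step))
  invisible(x)
}

#' Extract one channel of a stack by role
#' @param stack an `ohci_stack`.
#' @param role `"nuclei"`, `"actin"` or `"tracker"`.
#' @return The 3D array, or `NULL` if the role is absent.
#' @export
get_channel <- function(stack, role) {
  i <- match(role, stack$channel_roles)
  if (is.na(i)) NULL else stack$channels[[i]]
}

stack_dim <- function(stack) dim(stack$channels[[1]])

#' Read a multi-channel z-stack from per-channel TIFF files
#'
#' Each path must point to a multi-page TIFF holding one channel's z-stack
#' (one page per section, identical page size across channels). Integer
#' sample values are read as-is, so voxel sums round-trip exactly.
#'
#' @param paths character vector of TIFF files, named by channel role
#'   (`nuclei`, `actin`, optionally `tracker`), or unnamed with `roles` given.
#' @param voxel_size_xy,z_step calibration in µm (acquisition metadata; TIFFs
#'   do not carry it reliably).
#' @param roles channel roles when `paths` is unnamed.
#' @param well_id optional well identifier.
#' @return An [image_stack()].
#' @export
read_stack <- function(paths, voxel_size_xy, z_step, roles = names(paths),
                       well_id = NA_character_) {
  if (is.null(roles)) stop_validation("channel roles must be supplied")
  missing <- !file.exists(paths)
  if (any(missing))
    stop_format(sprintf("file(s) not found: %s", paste(paths[missing], collapse = ", ")))
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr
  })
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L)
    stop_format("channel stacks have mismatched shapes")
  image_stack(channels, roles, voxel_size_xy, z_step, well_id)
}

#' Write a stack as one 16-bit multi-page TIFF per channel
#'
#' @param stack an `ohci_stack`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; files are `<prefix>_<role>.tif`.
#' @return Named character vector of the written paths.
#' @export
write_stack <- function(stack, dir, prefix = stack$well_id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.na(prefix) || !nzchar(prefix)) prefix <- "stack"
  out <- character(0)
  for (i in seq_along(stack$channels)) {
    role <- stack$channel_roles[i]
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, role))
    arr <- stack$channels[[i]]
    pages <- lapply(seq_len(dim(arr)[3]), function(k)
      pmin(pmax(arr[, , k], 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    out[role] <- path
  }
  out
}
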