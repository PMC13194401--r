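# Ground-truth scene generation: tumoroids, single cells and labeled immune
# cells in a virtual well, with treatment effects applied analytically so
# every downstream measurement can be checked against exact truth.

#' Describe a treatment effect for the simulator
#'
#' The phenomenology the readouts must capture: immune-mediated killing
#' shrinks tumoroids (volume reduction), eliminates some entirely (object
#' loss), drives labeled immune cells into tumoroid bodies (infiltration),
#' and expands the free single-cell fraction (immune proliferation).
#'
#' @param volume_reduction_fraction fraction of each tumoroid's volume lost,
#'   in `[0, 1]`.
#' @param object_loss_fraction probability that a tumoroid is eliminated
#'   outright, in `[0, 1]`.
#' @param infiltration_rate probability that a labeled immune cell sits
#'   inside a tumoroid body, in `[0, 1]`.
#' @param single_cell_growth_factor multiplier (>= 0) on the free single-cell
#'   count; 1 = no change.
#' @param effector_target_ratio labeled effector cells added per
#'   tumoroid-resident cell (E:T ratio; co-cultures use 5:1-10:1).
#' @return An object of class `ohci_effect`.
#' @export
effect_model <- function(volume_reduction_fraction = 0,
                         object_loss_fraction = 0,
                         infiltration_rate = 0,
                         single_cell_growth_factor = 1,
                         effector_target_ratio = 5) {
  assert_fraction(volume_reduction_fraction, "volume_reduction_fraction")
  assert_fraction(object_loss_fraction, "object_loss_fraction")
  assert_fraction(infiltration_rate, "infiltration_rate")
  if (!is.numeric(single_cell_growth_factor) || single_cell_growth_factor < 0)
    stop_validation("`single_cell_growth_factor` must be >= 0")
  if (!is.numeric(effector_target_ratio) || effector_target_ratio < 0)
    stop_validation("`effector_target_ratio` must be >= 0")
  structure(list(volume_reduction_fraction = volume_reduction_fraction,
                 object_loss_fraction = object_loss_fraction,
                 infiltration_rate = infiltration_rate,
                 single_cell_growth_factor = single_cell_growth_factor,
                 effector_target_ratio = effector_target_ratio),
            class = "ohci_effect")
}

null_effect <- function() effect_model()

# Truncated log-normal diameters via rejection; vectorized, deterministic
# given the RNG state.
draw_diameters <- function(n, meanlog, sdlog, range) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    d <- rlnorm(max(2L * n, 16L), meanlog, sdlog)
    out <- c(out, d[d > range[1] & d < range[2]])
    guard <- guard + 1L
    if (guard > 1000L)
      stop_generation("diameter distribution incompatible with the truncation range")
  }
  out[seq_len(n)]
}

# Non-overlapping sphere placement by rejection sampling; `gap` is the
# minimum surface-to-surface clearance (seeded clusters disperse in the gel).
# Spheres are placed largest-first (dense configurations pack reliably that
# way) and positions returned in the caller's order.
place_tumoroids <- function(diam, field_xy, depth, max_tries, gap = 0) {
  n <- length(diam)
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  ord <- order(diam, decreasing = TRUE)
  diam <- diam[ord]
  x <- y <- z <- numeric(n)
  r <- diam / 2
  if (any(2 * r >= field_xy) || any(2 * r >= depth))
    stop_generation("tumoroid diameter exceeds the field extent")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      px <- runif(1, r[i], field_xy - r[i])
      py <- runif(1, r[i], field_xy - r[i])
      pz <- runif(1, r[i], depth - r[i])
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        ok <- all((x[j] - px)^2 + (y[j] - py)^2 + (z[j] - pz)^2 >= (r[j] + r[i] + gap)^2)
      }
      if (ok) { x[i] <- px; y[i] <- py; z[i] <- pz; placed <- TRUE; break }
    }
    if (!placed)
      stop_generation(sprintf(
        "could not place %d non-overlapping tumoroids in a %g x %g x %g um field",
        n, field_xy, field_xy, depth))
  }
  inv <- integer(n); inv[ord] <- seq_len(n)
  data.frame(x = x[inv], y = y[inv], z = z[inv])
}

# Nuclei inside a sphere: jittered 3D grid at the configured spacing (a cheap
# blue-noise stand-in for Poisson-disc sampling). Guarantees >= 1 nucleus.
nuclei_in_sphere <- function(center, radius, spacing) {
  margin <- min(radius * 0.5, 4)
  g <- seq(-radius, radius, by = spacing)
  g <- g + runif(1, -spacing / 2, spacing / 2)  # random grid phase
  pts <- expand.grid(dx = g, dy = g, dz = g)
  jit <- matrix(runif(nrow(pts) * 3, -0.3 * spacing, 0.3 * spacing), ncol = 3)
  pts <- pts + jit
  keep <- pts$dx^2 + pts$dy^2 + pts$dz^2 <= (radius - margin)^2
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L) pts <- data.frame(dx = 0, dy = 0, dz = 0)
  data.frame(x = center[1] + pts$dx, y = center[2] + pts$dy, z = center[3] + pts$dz)
}

#' Generator parameters for [sample_scene()] derived from a configuration
#' @param config an [default_config()] list.
#' @return List of generator parameters plus the field extent (`field_xy`,
#'   `depth` in µm) implied by the imaging calibration.
#' @export
scene_defaults <- function(config = default_config()) {
  c(config$generator,
    list(field_xy = config$calibration$field_xy,
         depth = config$calibration$z_step * config$calibration$n_sections))
}

#' Sample a ground-truth well scene
#'
#' Draws a virtual well: `count_range` (default 50-300) tumoroids with
#' truncated log-normal diameters inside the configured range (default
#' 50-200 µm, the seeded cluster sizes of the ex vivo tissue assay), nuclei
#' packed inside each body, free single cells, and - when the assay has a
#' tracker channel - labeled immune cells at the configured E:T ratio. The
#' treatment effect is then applied analytically: diameters scaled so volumes
#' shrink by `volume_reduction_fraction`, a Bernoulli subset of tumoroids
#' removed, labeled cells placed inside surviving tumoroids with probability
#' `infiltration_rate`, and the single-cell count rescaled.
#'
#' Effect randomness is coupled across effect settings: the same seed with a
#' stronger effect removes a superset of tumoroids, so total true volume is
#' monotone in both fractions, and an all-zero effect reproduces the control
#' scene exactly.
#'
#' @param params generator parameters; see [default_config()]`$generator`.
#'   Obtained via `scene_defaults()` internally; a plain list with the same
#'   fields (plus `field_xy`, `depth`) is accepted. `count_fixed` (optional)
#'   overrides the uniform draw from `count_range`.
#' @param effect an [effect_model()].
#' @param seed integer seed; scenes are pure functions of `(params, effect, seed)`.
#' @return An object of class `ohci_scene`: data.frames `tumoroids` (id,
#'   centroid µm, `equivalent_diameter_um`, `nucleus_count`,
#'   `true_volume_um3`), `single_cells`, `labeled_cells` (centroid,
#'   `infiltrated`, `host_tumoroid_id`), `nuclei` (per-nucleus positions used
#'   for rendering), plus `params_used` and `seed`.
#' @export
sample_scene <- function(params = scene_defaults(), effect = null_effect(), seed = 1L) {
  if (!inherits(effect, "ohci_effect")) stop_validation("`effect` must be an effect_model()")
  p <- params
  if (p$diameter_range[2] >= min(p$field_xy, p$depth))
    stop_validation("diameter range must lie inside the field extent")
  set.seed(as.integer(seed))

  n_tum <- if (!is.null(p$count_fixed)) as.integer(p$count_fixed) else {
    rng <- p$count_range[1]:p$count_range[2]
    rng[sample.int(length(rng), 1L)]
  }
  if (n_tum < 0L) stop_validation("tumoroid count must be non-negative")
  diam0 <- draw_diameters(n_tum, p$diameter_meanlog, p$diameter_sdlog, p$diameter_range)
  pos <- place_tumoroids(diam0, p$field_xy, p$depth, p$max_place_tries,
                         gap = if (is.null(p$min_gap)) 0 else p$min_gap)

  nuc <- vector("list", n_tum)
  for (i in seq_len(n_tum)) {
    nn <- nuclei_in_sphere(c(pos$x[i], pos$y[i], pos$z[i]), diam0[i] / 2, p$nucleus_spacing)
    nn$tumoroid_id <- i
    nuc[[i]] <- nn
  }
  nuclei <- if (n_tum > 0L) do.call(rbind, nuc) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               tumoroid_id = integer(0))

  n_single0 <- rpois(1, p$single_cell_mean)
  singles0 <- data.frame(x = runif(n_single0, 0, p$field_xy),
                         y = runif(n_single0, 0, p$field_xy),
                         z = runif(n_single0, 0, p$depth))

  ## ---- effect block (base-scene RNG consumed above, in fixed order) ----
  shrink <- (1 - effect$volume_reduction_fraction)^(1 / 3)
  diam <- diam0 * shrink
  # nuclei follow the shrinking body
  if (shrink < 1) {
    cid <- nuclei$tumoroid_id
    nuclei$x <- pos$x[cid] + (nuclei$x - pos$x[cid]) * shrink
    nuclei$y <- pos$y[cid] + (nuclei$y - pos$y[cid]) * shrink
    nuclei$z <- pos$z[cid] + (nuclei$z - pos$z[cid]) * shrink
  }
  u_loss <- runif(n_tum)            # always drawn: couples scenes across effects
  keep <- u_loss >= effect$object_loss_fraction

  n_single <- round(n_single0 * effect$single_cell_growth_factor)
  if (n_single <= n_single0) {
    singles <- singles0[seq_len(n_single), , drop = FALSE]
  } else {
    extra <- n_single - n_single0
    singles <- rbind(singles0,
                     data.frame(x = runif(extra, 0, p$field_xy),
                                y = runif(extra, 0, p$field_xy),
                                z = runif(extra, 0, p$depth)))
  }

  labeled <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        infiltrated = logical(0), host_tumoroid_id = integer(0))
  if (isTRUE(p$tracker) && effect$effector_target_ratio > 0) {
    frac_in <- if (is.null(p$labeled_fraction_in_field)) 1 else p$labeled_fraction_in_field
    n_lab <- round(effect$effector_target_ratio * nrow(nuclei) * frac_in)
    if (n_lab > 0) {
      u_inf <- runif(n_lab)
      infiltrated <- u_inf < effect$infiltration_rate
      hosts <- which(keep)
      if (length(hosts) == 0L) infiltrated[] <- FALSE
      host_id <- rep(NA_integer_, n_lab)
      lx <- ly <- lz <- numeric(n_lab)
      n_in <- sum(infiltrated)
      if (n_in > 0) {
        w <- diam[hosts]^3
        h <- hosts[sample.int(length(hosts), n_in, replace = TRUE, prob = w)]
        host_id[infiltrated] <- h
        # uniform in the host sphere (kept a small margin inside)
        rmax <- pmax(diam[h] / 2 - 3, 0.5)
        u <- runif(n_in)^(1 / 3) * rmax
        phi <- runif(n_in, 0, 2 * pi); cth <- runif(n_in, -1, 1)
        sth <- sqrt(1 - cth^2)
        lx[infiltrated] <- pos$x[h] + u * sth * cos(phi)
        ly[infiltrated] <- pos$y[h] + u * sth * sin(phi)
        lz[infiltrated] <- pos$z[h] + u * cth
      }
      n_out <- sum(!infiltrated)
      if (n_out > 0) {
        ox <- runif(n_out, 0, p$field_xy)
        oy <- runif(n_out, 0, p$field_xy)
        oz <- runif(n_out, 0, p$depth)
        # push points that landed inside a surviving tumoroid back outside
        if (length(hosts)) {
          for (t in 1:20) {
            inside <- rep(FALSE, n_out)
            for (j in hosts) {
              d2 <- (ox - pos$x[j])^2 + (oy - pos$y[j])^2 + (oz - pos$z[j])^2
              inside <- inside | d2 < (diam[j] / 2)^2
            }
            if (!any(inside)) break
            ox[inside] <- runif(sum(inside), 0, p$field_xy)
            oy[inside] <- runif(sum(inside), 0, p$field_xy)
            oz[inside] <- runif(sum(inside), 0, p$depth)
          }
        }
        lx[!infiltrated] <- ox; ly[!infiltrated] <- oy; lz[!infiltrated] <- oz
      }
      labeled <- data.frame(x = lx, y = ly, z = lz,
                            infiltrated = infiltrated, host_tumoroid_id = host_id)
    }
  }

  tum <- data.frame(id = seq_len(n_tum),
                    x = pos$x, y = pos$y, z = pos$z,
                    equivalent_diameter_um = diam,
                    nucleus_count = as.integer(tabulate(nuclei$tumoroid_id, n_tum)),
                    true_volume_um3 = pi / 6 * diam^3)
  tum <- tum[keep, , drop = FALSE]
  nuclei <- nuclei[keep[nuclei$tumoroid_id], , drop = FALSE]

  structure(list(tumoroids = tum,
                 single_cells = singles,
                 labeled_cells = labeled,
                 nuclei = nuclei,
                 params_used = p, effect_used = unclass(effect),
                 seed = as.integer(seed)),
            class = "ohci_scene")
}

#' @export
print.ohci_scene <- function(x, ...) {
  cat(sprintf("<ohci_scene> seed %d: %d tumoroids (d %.0f-%.0f um, total %.3g mm3), %d single cells, %d labeled cells (%d infiltrated)\n",
              x$seed, nrow(x$tumoroids),
              if (nrow(x$tumoroids)) min(x$tumoroids$equivalent_diameter_um) else NA,
              if (nrow(x$tumoroids)) max(x$tumoroids$equivalent_diameter_um) else NA,
              sum(x$tumoroids$true_volume_um3) / 1e9,
              nrow(x$single_cells), nrow(x$labeled_cells), sum(x$labeled_cells$infiltrated)))
  invisible(x)
}
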