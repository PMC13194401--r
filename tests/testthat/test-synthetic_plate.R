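# Generator contracts: seeding ranges, effect semantics, determinism,
# rendering geometry.

test_that("evpt default scenes respect the seeded count and diameter ranges", {
  for (seed in c(2, 17, 101)) {
    sc <- sample_scene(seed = seed)
    expect_gte(nrow(sc$tumoroids), 50)
    expect_lte(nrow(sc$tumoroids), 300)
    expect_true(all(sc$tumoroids$equivalent_diameter_um > 50))
    expect_true(all(sc$tumoroids$equivalent_diameter_um < 200))
    expect_equal(sc$tumoroids$true_volume_um3,
                 pi / 6 * sc$tumoroids$equivalent_diameter_um^3)
  }
})

test_that("a null effect is the identity on the scene", {
  a <- small_scene(seed = 9)
  b <- small_scene(seed = 9, effect = effect_model(volume_reduction_fraction = 0))
  expect_identical(a, b)
})

test_that("volume reduction scales total true volume exactly", {
  a <- small_scene(seed = 11)
  b <- small_scene(seed = 11, effect = effect_model(volume_reduction_fraction = 0.5))
  expect_equal(sum(b$tumoroids$true_volume_um3),
               0.5 * sum(a$tumoroids$true_volume_um3), tolerance = 1e-12)
  # nuclei stay inside the shrunken bodies
  r <- b$tumoroids$equivalent_diameter_um[match(b$nuclei$tumoroid_id, b$tumoroids$id)] / 2
  d <- sqrt((b$nuclei$x - b$tumoroids$x[match(b$nuclei$tumoroid_id, b$tumoroids$id)])^2 +
            (b$nuclei$y - b$tumoroids$y[match(b$nuclei$tumoroid_id, b$tumoroids$id)])^2 +
            (b$nuclei$z - b$tumoroids$z[match(b$nuclei$tumoroid_id, b$tumoroids$id)])^2)
  expect_true(all(d <= r))
})

test_that("total volume is monotone in both effect fractions at fixed seed", {
  vol_at <- function(f_vol, f_loss)
    sum(small_scene(seed = 21, effect = effect_model(
      volume_reduction_fraction = f_vol,
      object_loss_fraction = f_loss))$tumoroids$true_volume_um3)
  vols_v <- vapply(c(0, 0.25, 0.5, 0.75, 0.9), vol_at, 1.0, f_loss = 0)
  expect_true(all(diff(vols_v) <= 0))
  vols_l <- vapply(c(0, 0.25, 0.5, 0.75, 0.9), function(f) vol_at(0, f), 1.0)
  expect_true(all(diff(vols_l) <= 0))
})

test_that("infiltrated labeled cells lie inside their host tumoroid", {
  cfg <- small_config("reconstituted")
  sc <- small_scene(seed = 31, cfg = cfg,
                    effect = effect_model(infiltration_rate = 0.6))
  lc <- sc$labeled_cells
  expect_gt(nrow(lc), 0)
  inf <- lc[lc$infiltrated, ]
  expect_gt(nrow(inf), 0)
  host <- match(inf$host_tumoroid_id, sc$tumoroids$id)
  expect_false(anyNA(host))
  d <- sqrt((inf$x - sc$tumoroids$x[host])^2 + (inf$y - sc$tumoroids$y[host])^2 +
            (inf$z - sc$tumoroids$z[host])^2)
  expect_true(all(d <= sc$tumoroids$equivalent_diameter_um[host] / 2))
  expect_true(all(is.na(lc$host_tumoroid_id[!lc$infiltrated])))
})

test_that("infeasible packing raises a generation error", {
  p <- scene_defaults(small_config())
  p$field_xy <- 420; p$depth <- 420
  p$diameter_range <- c(180, 200)
  p$diameter_meanlog <- log(190); p$diameter_sdlog <- 0.05
  p$count_fixed <- 60
  p$max_place_tries <- 20L
  expect_error(sample_scene(p, seed = 1), class = "ohci_generation_error")
})

test_that("rendering rejects fields smaller than the scene extent", {
  cfg <- small_config()
  sc <- small_scene(seed = 45, n_tumoroids = 5, cfg = cfg)
  im <- imaging_defaults(cfg)
  im$field_xy <- 300
  expect_error(render_well(sc, im, seed = 46), class = "ohci_generation_error")
})

test_that("rendering is bit-identical for a fixed seed", {
  sc <- small_scene(seed = 41, n_tumoroids = 5)
  a <- render_well(sc, imaging_defaults(small_config()), seed = 42)
  b <- render_well(sc, imaging_defaults(small_config()), seed = 42)
  expect_identical(a$channels, b$channels)
})

test_that("an empty scene renders essentially no foreground", {
  cfg <- small_config()
  cfg$generator$single_cell_mean <- 0
  sc <- small_scene(seed = 51, cfg = cfg, n_tumoroids = 0)
  expect_equal(nrow(sc$tumoroids), 0L)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 52)
  ch <- stk$channels[[which(stk$channel_roles == "actin")]]
  bg <- median(ch); s <- sd(ch)
  expect_lt(mean(ch > bg + 5 * s), 1e-4)
})

test_that("a rendered 100 um tumoroid has near-analytic bright volume", {
  cfg <- small_config()
  cfg$generator$single_cell_mean <- 0
  p <- scene_defaults(cfg)
  p$count_fixed <- 1
  p$diameter_range <- c(99.9, 100.1)
  p$diameter_meanlog <- log(100); p$diameter_sdlog <- 1e-3
  sc <- sample_scene(p, seed = 61)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 62)
  ch <- stk$channels[[which(stk$channel_roles == "actin")]]
  bg <- median(ch); s <- mad(ch)
  vol <- sum(ch > bg + 5 * s) * cfg$calibration$voxel_size_xy^2 * cfg$calibration$z_step
  expect_lt(abs(vol - pi / 6 * 100^3) / (pi / 6 * 100^3), 0.15)
})

test_that("simulate_plate run directories are reproducible per master seed", {
  lay <- suppressWarnings(design_layout(c("control", "t"), n_replicates = 2,
                                        assay_kind = "evpt"))
  eff <- list(t = effect_model(volume_reduction_fraction = 0.3))
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_plate(lay, eff, master_seed = 7, config = cfg, outdir = d1,
                 keep_stacks = FALSE)
  simulate_plate(lay, eff, master_seed = 7, config = cfg, outdir = d2,
                 keep_stacks = FALSE)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  sums1 <- tools::md5sum(file.path(d1, sort(f1)))
  sums2 <- tools::md5sum(file.path(d2, sort(f1)))
  expect_equal(unname(sums1), unname(sums2))
  expect_error(simulate_plate(lay, list(), master_seed = 7, config = cfg),
               class = "ohci_validation_error")
})
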