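# Segmentation: blob detection, actin object segmentation, classification.

blank_stack <- function(cfg = small_config(), seed = 1,
                        roles = c("nuclei", "actin")) {
  cal <- cfg$calibration
  n <- round(cal$field_xy / cal$voxel_size_xy)
  set.seed(seed)
  chans <- lapply(roles, function(r)
    array(pmax(round(100 + rnorm(n * n * cal$n_sections, 0, 10)), 0),
          c(n, n, cal$n_sections)))
  image_stack(chans, roles, cal$voxel_size_xy, cal$z_step)
}

test_that("blank wells yield no nuclei and no objects", {
  stk <- blank_stack()
  expect_equal(nrow(detect_nuclei(stk, small_config())), 0L)
  lab <- segment_actin_objects(stk, small_config())
  expect_equal(lab$n, 0L)
  expect_true(all(lab$labels == 0L))
})

test_that("well-separated single cells are counted within 5%", {
  cfg <- small_config()
  cfg$generator$single_cell_mean <- 150
  cfg$generator$read_noise_sd <- 5
  sc <- small_scene(seed = 71, cfg = cfg, n_tumoroids = 0)
  n_true <- nrow(sc$single_cells)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 72)
  det <- detect_nuclei(stk, cfg)
  expect_lt(abs(nrow(det) - n_true) / n_true, 0.05)
})

test_that("blobs closer than the minimum separation merge into one", {
  cfg <- small_config()
  cal <- cfg$calibration
  n <- 64
  arr <- array(0, c(n, n, 20))
  # two nuclei 6 um apart (< 10 um min separation), one isolated pair 100 um away
  pts <- data.frame(x = c(100, 106, 200), y = c(100, 100, 200), z = c(250, 250, 250))
  arr <- organoidhci:::paint_blobs(arr, pts$x, pts$y, pts$z, 3000, 4,
                                   cal$voxel_size_xy, cal$z_step)
  arr <- arr + 100
  stk <- image_stack(list(arr), "nuclei", cal$voxel_size_xy, cal$z_step)
  det <- detect_nuclei(stk, cfg)
  expect_equal(nrow(det), 2L)
})

test_that("synthetic tumoroids are segmented 1:1 and matched by centroid", {
  cfg <- small_config()
  cfg$generator$read_noise_sd <- 5
  sc <- small_scene(seed = 81, cfg = cfg, n_tumoroids = 12)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 82)
  nuc <- detect_nuclei(stk, cfg)
  lab <- segment_actin_objects(stk, cfg)
  cls <- classify_objects(lab, nuc, cfg)
  objs <- measure_objects(cls$multicellular, nuc)
  expect_equal(nrow(objs), nrow(sc$tumoroids))
  # greedy 1:1 match by centroid distance < tumoroid radius
  tt <- sc$tumoroids
  dmat <- outer(seq_len(nrow(objs)), seq_len(nrow(tt)), function(i, j)
    sqrt((objs$x_um[i] - tt$x[j])^2 + (objs$y_um[i] - tt$y[j])^2 +
         (objs$z_um[i] - tt$z[j])^2))
  nearest <- apply(dmat, 1, which.min)
  expect_equal(sort(nearest), seq_len(nrow(tt)))  # bijection
  expect_true(all(dmat[cbind(seq_len(nrow(objs)), nearest)] <
                  tt$equivalent_diameter_um[nearest] / 2))
})

test_that("two touching tumoroids merge into one component", {
  cfg <- small_config()
  cal <- cfg$calibration
  arr <- array(0, c(120, 120, 20))
  # two 80 um spheres whose surfaces touch (centres 80 um apart)
  arr <- organoidhci:::paint_spheres(arr, cx = c(240, 320), cy = c(300, 300),
                                     cz = c(250, 250), r = c(40, 40),
                                     value = 2000, vox = cal$voxel_size_xy,
                                     zst = cal$z_step)
  set.seed(3); arr <- arr + 100 + array(rnorm(length(arr), 0, 5), dim(arr))
  stk <- image_stack(list(pmax(arr, 0)), "actin", cal$voxel_size_xy, cal$z_step)
  lab <- segment_actin_objects(stk, cfg)
  expect_equal(lab$n, 1L)
})

test_that("tracker detection tolerates a missing channel and bright actin", {
  stk <- blank_stack(roles = c("nuclei", "actin"))
  expect_warning(ts <- detect_tracker_cells(stk, small_config()), "tracker")
  expect_equal(nrow(ts), 0L)

  cfg <- small_config("reconstituted")
  cfg$generator$read_noise_sd <- 5
  cfg$generator$labeled_fraction_in_field <- 0.02  # sparse enough to resolve
  sc <- small_scene(seed = 91, cfg = cfg, n_tumoroids = 6,
                    effect = effect_model(infiltration_rate = 1))
  expect_true(all(sc$labeled_cells$infiltrated))   # all inside bright bodies
  expect_gt(nrow(sc$labeled_cells), 10)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 92)
  det <- detect_tracker_cells(stk, cfg)
  expect_gt(nrow(det), 0.8 * nrow(sc$labeled_cells))
})

test_that("tracker count recovers truth within 5% on sparse labeled cells", {
  cfg <- small_config("reconstituted")
  cfg$generator$read_noise_sd <- 5
  cfg$generator$labeled_fraction_in_field <- 0.02   # sparse, well-separated
  sc <- small_scene(seed = 95, cfg = cfg, n_tumoroids = 10)
  m <- nrow(sc$labeled_cells)
  expect_gt(m, 20)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 96)
  det <- detect_tracker_cells(stk, cfg)
  expect_lt(abs(nrow(det) - m) / m, 0.05)
})

test_that("classification follows the diameter and nuclei rules", {
  cfg <- small_config()
  vox <- 5; zst <- 25
  mk_points <- function(coords)
    organoidhci:::point_set(coords, "nucleus", vox, zst)

  big <- sphere_labels(100, vox, zst)
  ny <- dim(big$labels)[1]; nz <- dim(big$labels)[3]
  inside <- which(big$labels == 1L, arr.ind = TRUE)
  set.seed(1)
  nuc40 <- mk_points(inside[sample(nrow(inside), 40), , drop = FALSE])
  cls <- classify_objects(big, nuc40, cfg)
  expect_equal(cls$multicellular$n, 1L)
  expect_equal(cls$nuclei_per_object, 40L)
  expect_equal(nrow(cls$single_cells), 0L)

  # 60 um component with exactly 1 nucleus -> single cell (nuclei rule wins)
  mid <- sphere_labels(60, vox, zst)
  in60 <- which(mid$labels == 1L, arr.ind = TRUE)
  one <- mk_points(in60[1, , drop = FALSE])
  cls1 <- classify_objects(mid, one, cfg)
  expect_equal(cls1$multicellular$n, 0L)
  expect_equal(nrow(cls1$single_cells), 1L)

  # 12 um shell-sized component -> below the 30 um gate even with 2 nuclei
  tiny <- sphere_labels(12, vox, zst)
  in12 <- which(tiny$labels == 1L, arr.ind = TRUE)
  two <- mk_points(in12[seq_len(min(2, nrow(in12))), , drop = FALSE])
  cls2 <- classify_objects(tiny, two, cfg)
  expect_equal(cls2$multicellular$n, 0L)

  bad <- cfg; bad$classification$single_cell_max_diameter <- 0
  expect_error(classify_objects(big, nuc40, bad), class = "ohci_validation_error")
})

test_that("every nucleus is assigned exactly once (partition identity)", {
  cfg <- small_config()
  sc <- small_scene(seed = 101, cfg = cfg)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 102)
  nuc <- detect_nuclei(stk, cfg)
  lab <- segment_actin_objects(stk, cfg)
  cls <- classify_objects(lab, nuc, cfg)
  expect_identical(nrow(cls$single_cells) + sum(cls$nuclei_per_object), nrow(nuc))
})

test_that("counts are invariant under global intensity scaling", {
  cfg <- small_config()
  sc <- small_scene(seed = 111, cfg = cfg, n_tumoroids = 8)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 112)
  scaled <- stk
  scaled$channels <- lapply(stk$channels, function(a) a * 3.7)
  n1 <- nrow(detect_nuclei(stk, cfg)); n2 <- nrow(detect_nuclei(scaled, cfg))
  o1 <- segment_actin_objects(stk, cfg)$n
  o2 <- segment_actin_objects(scaled, cfg)$n
  expect_equal(n2, n1)
  expect_equal(o2, o1)
})
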