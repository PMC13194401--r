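# QC gates: control window, image quality, CV, edge effects, plate report.

ctrl_layout <- function(n = 8) {
  suppressWarnings(design_layout("control", n_replicates = n, assay_kind = "evpt"))
}

test_that("the control window gate is inclusive at both thresholds", {
  lay <- ctrl_layout(4)
  ids <- lay$well_id
  m <- fake_measurements(ids,
                         object_count = c(50L, 49L, 50L, 0L),
                         total_volume_mm3 = c(0.01, 0.05, 0.0099, 0))
  res <- control_window_qc(m, lay)
  expect_equal(res$wells$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(res$samples$pass)  # 3/4 failing > 50%
  ok <- fake_measurements(ids, rep(60L, 4), rep(0.02, 4))
  expect_true(control_window_qc(ok, lay)$samples$pass)
  nolayout <- lay; nolayout$is_control <- FALSE
  expect_error(control_window_qc(ok, nolayout), class = "ohci_validation_error")
})

test_that("raising control-window thresholds never rescues a failing well", {
  lay <- ctrl_layout(8)
  set.seed(5)
  m <- fake_measurements(lay$well_id,
                         object_count = sample(30:80, 8, replace = TRUE),
                         total_volume_mm3 = runif(8, 0.005, 0.02))
  base <- control_window_qc(m, lay)$wells$pass
  for (k in 1:5) {
    stricter <- control_window_qc(m, lay,
                                  min_objects = 50 + 10 * k,
                                  min_total_volume = 0.01 + 0.002 * k)$wells$pass
    expect_true(all(stricter <= base))
  }
})

test_that("image QC fails blanks and saturation but passes healthy wells", {
  cfg <- small_config()
  blank <- image_stack(list(array(pmax(100 + rnorm(64 * 64 * 20, 0, 10), 0),
                                  c(64, 64, 20))), "actin", 5, 25)
  r <- image_well_qc(blank, NULL, cfg)
  expect_false(r$pass)
  expect_match(r$reason, "empty_or_low_signal")

  sat <- array(100, c(64, 64, 20))
  sat[, , 1:12] <- 60000                       # 60% saturated sections
  r2 <- image_well_qc(image_stack(list(sat), "actin", 5, 25), NULL, cfg)
  expect_false(r2$pass)
  expect_match(r2$reason, "debris_or_overgrowth")

  sc <- small_scene(seed = 151, cfg = cfg)
  stk <- render_well(sc, imaging_defaults(cfg), seed = 152)
  lab <- segment_actin_objects(stk, cfg)
  cls <- classify_objects(lab, detect_nuclei(stk, cfg), cfg)
  r3 <- image_well_qc(stk, cls$multicellular, cfg)
  expect_true(r3$pass)
  expect_gt(r3$metrics$coverage, cfg$qc$min_coverage)
})

test_that("cv_percent follows the sample-SD definition and its contracts", {
  expect_equal(cv_percent(c(90, 100, 110)), 10 / 100)
  expect_equal(cv_percent(rep(7, 4)), 0)
  expect_equal(cv_percent(3.7 * c(90, 100, 110)), cv_percent(c(90, 100, 110)))
  expect_error(cv_percent(5), class = "ohci_validation_error")
  expect_error(cv_percent(c(-1, 2)), class = "ohci_validation_error")
})

test_that("edge effects are detected only when injected", {
  rows <- c(rep(1, 5), rep(8, 8))
  wells <- data.frame(
    well_id = sprintf("%s%02d", LETTERS[rows], c(2:6, 2:9)),
    sample_id = "S", condition = "control", replicate_group = "g",
    is_control = TRUE, stringsAsFactors = FALSE)
  lay <- suppressWarnings(plate_layout(wells))
  expect_equal(sum(lay$is_edge), 5L)
  set.seed(9)
  vals <- rep(0.1, 13) * exp(rnorm(13, 0, 0.02))
  same <- fake_measurements(lay$well_id, 60L, vals)
  r <- edge_effect_check(same, lay, small_config())
  expect_equal(r$verdict, "no_edge_effect")

  halved <- vals; halved[lay$is_edge] <- halved[lay$is_edge] * 0.5
  r2 <- edge_effect_check(fake_measurements(lay$well_id, 60L, halved), lay,
                          small_config())
  expect_equal(r2$verdict, "edge_effect")
  expect_lt(r2$median_ratio, 0.8)

  two_edge <- c(1, 2, 6:13)   # only 2 edge wells left
  r3 <- edge_effect_check(same[two_edge, ], lay[two_edge, ], small_config())
  expect_equal(r3$verdict, "not_evaluable")
})

test_that("plate exclusion fraction matches the 4% convention", {
  n <- 260
  rows <- rep(2:15, length.out = n)
  cols <- unlist(lapply(seq_len(n), function(i) 2 + (i - 1) %/% 14))
  wells <- data.frame(
    well_id = sprintf("%s%02d", LETTERS[rows], cols),
    sample_id = "S", condition = "control", replicate_group = "g",
    is_control = TRUE, stringsAsFactors = FALSE)
  lay <- suppressWarnings(plate_layout(wells))
  flags <- rep("pass", n); flags[1:10] <- "fail_image_quality"
  m <- fake_measurements(lay$well_id, 60L, 0.02, qc_flag = flags)
  rep10 <- plate_qc_report(m, lay, small_config())
  expect_equal(rep10$exclusion_fraction, 10 / 260, tolerance = 1e-12)
  expect_equal(rep10$n_excluded, 10L)

  all_pass <- fake_measurements(lay$well_id, 60L, 0.02)
  expect_equal(plate_qc_report(all_pass, lay, small_config())$exclusion_fraction, 0)

  flags30 <- rep("pass", n); flags30[1:30] <- "analysis_failed"
  m30 <- fake_measurements(lay$well_id, 60L, 0.02, qc_flag = flags30)
  expect_warning(plate_qc_report(m30, lay, small_config()), "excluded")
})
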