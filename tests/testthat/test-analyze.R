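# Normalization, aggregation, response categories, group statistics.

test_that("percent-of-control arithmetic and self-normalization", {
  ctrl <- c(0.009, 0.010, 0.011)
  expect_equal(percent_of_control(0.005, rep(0.010, 4)), 50)
  expect_equal(percent_of_control(mean(ctrl), ctrl), 100)
  expect_equal(mean(percent_of_control(ctrl, ctrl)), 100)  # controls average to 100
  expect_equal(mean(percent_of_control(percent_of_control(ctrl, ctrl),
                                       percent_of_control(ctrl, ctrl))), 100)
  expect_error(percent_of_control(1, numeric(0)),
               class = "ohci_normalization_error")
  expect_error(percent_of_control(1, c(0, 0)),
               class = "ohci_normalization_error")
})

test_that("replicate aggregation follows the median/mean convention", {
  a <- aggregate_replicates(c(40, 50, 200), "total_volume")
  expect_equal(a$summary, 50)        # median shrugs off the outlier well
  expect_equal(aggregate_replicates(c(40, 50, 200), "object_count")$summary, 50)
  b <- aggregate_replicates(c(100, 300), "single_cell_count")
  expect_equal(b$summary, 200)       # mean
  expect_equal(aggregate_replicates(c(0.2, 0.4), "infiltration_fraction")$summary, 0.3)
  s <- aggregate_replicates(85, "total_volume")
  expect_true(s$low_n)
  expect_equal(s$summary, 85)
  expect_error(aggregate_replicates(numeric(0), "total_volume"),
               class = "ohci_validation_error")
})

test_that("response categories are the printed bins on a half-open grid", {
  expect_equal(as.character(classify_response(c(0, -25, 9.99))),
               rep("non-responder", 3))
  expect_equal(as.character(classify_response(c(10, 30, 30.5))), rep("10-30", 3))
  expect_equal(as.character(classify_response(c(31, 45, 50.9))), rep("31-50", 3))
  expect_equal(as.character(classify_response(c(51, 70.99))), rep("51-70", 2))
  expect_equal(as.character(classify_response(c(71, 80, 100))), rep(">71", 3))
  # total monotone step function over a fine scan
  scan <- classify_response(seq(-50, 150, by = 0.25))
  expect_false(anyNA(scan))
  expect_true(all(diff(as.integer(scan)) >= 0))
})

test_that("one-way ANOVA and Tukey agree with textbook formulas", {
  g <- list(A = c(10, 12, 14), B = c(20, 22, 24), C = c(30, 32, 34))
  df <- data.frame(value = unlist(g), group = rep(names(g), each = 3))
  # independent oracle: explicit sums of squares
  k <- 3; n <- 9
  grand <- mean(df$value)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1.0))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1.0))
  F_oracle <- (ss_b / (k - 1)) / (ss_w / (n - k))
  p_oracle <- pf(F_oracle, k - 1, n - k, lower.tail = FALSE)
  res <- compare_groups(df)
  expect_equal(res$anova$F[1], F_oracle, tolerance = 1e-6)
  expect_equal(res$anova$p[1], p_oracle, tolerance = 1e-6)
  # Tukey p for A vs C from the studentized range distribution directly
  mse <- ss_w / (n - k)
  q_ac <- abs(mean(g$C) - mean(g$A)) / sqrt(mse / 3)
  p_ac <- ptukey(q_ac, k, n - k, lower.tail = FALSE)
  got <- res$comparisons
  expect_equal(got$p_adj[got$comparison == "C-A"], p_ac, tolerance = 1e-6)
  expect_equal(which.min(got$p_adj), which(got$comparison == "C-A"))
  expect_equal(got$stars[got$comparison == "C-A"], "****")
})

test_that("identical groups give F = 0 and p = 1", {
  df <- data.frame(value = c(1, 2, 3, 1, 2, 3), group = rep(c("a", "b"), each = 3))
  res <- compare_groups(df)
  expect_equal(res$anova$F[1], 0)
  expect_equal(res$anova$p[1], 1)
  expect_equal(res$comparisons$p_adj, 1)
})

test_that("Dunnett compares every group to the named reference only", {
  set.seed(42)
  df <- data.frame(value = c(rnorm(4, 100), rnorm(4, 60), rnorm(4, 100)),
                   group = rep(c("control", "drug", "iso"), each = 4))
  res <- compare_groups(df, reference = "control")
  expect_equal(res$method, "Dunnett")
  expect_equal(nrow(res$comparisons), 2L)
  expect_true(all(grepl("- control$", res$comparisons$comparison)))
  drug_p <- res$comparisons$p_adj[grepl("^drug", res$comparisons$comparison)]
  iso_p <- res$comparisons$p_adj[grepl("^iso", res$comparisons$comparison)]
  expect_lt(drug_p, 0.01)
  expect_gt(iso_p, 0.05)
})

test_that("degenerate groups are dropped with a warning", {
  df <- data.frame(value = c(1, 2, 3, 4, 9), group = c("a", "a", "b", "b", "c"))
  expect_warning(res <- compare_groups(df), "fewer than 2")
  expect_equal(nrow(res$comparisons), 1L)
  expect_error(suppressWarnings(
    compare_groups(data.frame(value = c(1, 2, 9), group = c("a", "a", "c")))),
    class = "ohci_validation_error")
})

test_that("two-way designs add a second factor without changing the contrasts", {
  set.seed(7)
  df <- data.frame(value = c(rnorm(8, 100), rnorm(8, 60)),
                   group = rep(c("control", "drug"), each = 8),
                   group2 = rep(rep(c("d1", "d2"), each = 4), 2))
  res <- compare_groups(df, design = "two-way")
  expect_true(all(c("group", "group2") %in% res$anova$term))
  expect_equal(nrow(res$comparisons), 1L)
  expect_lt(res$comparisons$p_adj, 0.001)
  expect_error(compare_groups(df[, 1:2], design = "two-way"),
               class = "ohci_validation_error")
})

test_that("dose tables flag monotone trends by rank correlation", {
  tab <- data.frame(sample_id = "S", condition = "cmpdX",
                    dose = c(0.1, 1, 10), readout = "total_volume",
                    summary = c(90, 60, 30))
  out <- build_dose_table(tab)
  expect_equal(unique(out$trend), "decreasing")
  flat <- tab; flat$summary <- c(80, 80, 80)
  expect_equal(unique(build_dose_table(flat)$trend), "")
  one <- tab[2, ]
  expect_equal(build_dose_table(one)$trend, "")
  up <- tab; up$summary <- c(30, 61, 90)
  expect_equal(unique(build_dose_table(up)$trend), "increasing")
})
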