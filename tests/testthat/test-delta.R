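long_feat <- function(ids, week, dose, value)
  data.frame(patient_id = ids, week = week, dose_gy = dose, value = value,
             stringsAsFactors = FALSE)

test_that("delta features reproduce their defining arithmetic", {
  rows <- long_feat("P1", c(0, 1, 4, 7), c(0, 10, 40, 70),
                    c(12, 10, 9, 8))
  d <- compute_delta_features(rows)
  expect_equal(d$net_change, (8 - 10) / 10)   # week1 10 -> final 8
  expect_equal(d$week_last, 8)
  expect_equal(d$week1, 10)
  expect_equal(d$week0, 12)
  # exact line: values (2,4,6) at doses (0,10,20) -> slope 0.2 per Gy
  rows2 <- long_feat("P1", 1:3, c(0, 10, 20), c(2, 4, 6))
  expect_equal(compute_delta_features(rows2)$slope, 0.2)
  # no change between first and last weekly value
  rows3 <- long_feat("P1", c(1, 2), c(10, 20), c(5, 5))
  expect_equal(compute_delta_features(rows3)$net_change, 0)
})

test_that("degenerate trajectories are missing-flagged, not fatal", {
  d0 <- compute_delta_features(long_feat("P1", 1:2, c(10, 20), c(0, 4)))
  expect_true(is.na(d0$net_change))   # week-1 value 0
  d1 <- compute_delta_features(long_feat("P1", 1, 10, 4))
  expect_true(is.na(d1$slope))        # single week
  expect_equal(d1$week_last, 4)
})

test_that("delta features obey their scaling invariances", {
  set.seed(6)
  rows <- long_feat(rep("P1", 6), 1:6, seq(10, 60, 10), rnorm(6, 10))
  base <- compute_delta_features(rows)
  scaled <- rows; scaled$value <- scaled$value * 3.7
  ds <- compute_delta_features(scaled)
  expect_equal(ds$net_change, base$net_change)       # scale-invariant
  expect_equal(ds$slope, 3.7 * base$slope)           # equivariant
  shifted <- rows; shifted$dose_gy <- shifted$dose_gy + 25
  expect_equal(compute_delta_features(shifted)$slope, base$slope)
})

test_that("BH adjustment matches the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  # monotone, order preserving, never decreasing
  set.seed(10)
  for (i in 1:10) {
    p <- runif(20)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # order preserving
  }
})

test_that("the dose LMM separates a deterministic trend from flat data", {
  set.seed(8)
  ids <- rep(sprintf("P%d", 1:10), each = 5)
  dose <- rep(seq(0, 40, 10), 10)
  # near-deterministic line with patient offsets: slope recovered
  off <- rep(rnorm(10), each = 5)
  rows <- data.frame(patient_id = ids, dose_gy = dose,
                     value = 0.5 * dose + off + rnorm(50, 0, 1e-4))
  fit <- fit_dose_lmm(rows)
  expect_equal(fit$beta_dose, 0.5, tolerance = 1e-3)
  expect_lt(fit$p, 1e-10)
  # per-patient constants carry no dose signal
  flat <- data.frame(patient_id = ids, dose_gy = dose, value = off)
  expect_gt(fit_dose_lmm(flat)$p, 0.9)
  expect_error(fit_dose_lmm(data.frame(patient_id = "P1", dose_gy = 1,
                                       value = 1)), "2 patients")
})

test_that("group-level delta significance combines its three screens", {
  co <- small_cohort(30, seed = 44)
  tabs <- generate_feature_tables(co)
  sig <- delta_significance(tabs$longitudinal)
  dec <- sig$decisions
  # dose-responsive features pass; the static feature fails
  expect_true(dec$pass[dec$feature == "ngtdm_strength"])
  expect_true(dec$pass[dec$feature == "glcm_energy"])
  expect_false(dec$pass[dec$feature == "ih_mean"])
  # covariate table carries the conventional suffixes
  dc <- delta_covariates(sig)
  expect_true(all(c("ngtdm_strength_netPercentChange",
                    "ngtdm_strength_Slope",
                    "ngtdm_strength_WeekLast") %in% names(dc)))
  expect_false(any(grepl("ih_mean", names(dc))))
})

test_that("all-zero group changes are not declared significant", {
  rows <- do.call(rbind, lapply(1:5, function(i)
    long_feat(sprintf("P%d", i), 1:3, c(10, 20, 30), c(4, 4, 4))))
  rows$feature <- "f"
  sig <- suppressWarnings(delta_significance(rows))
  expect_false(sig$decisions$pass)
})

test_that("a clear mean shift is detected by the group t-test", {
  # net changes drawn around 0.3 with small spread: BH-significant
  set.seed(30)
  rows <- do.call(rbind, lapply(1:30, function(i) {
    net <- rnorm(1, 0.3, 0.05)
    long_feat(sprintf("P%d", i), 1:2, c(10, 70), c(10, 10 * (1 + net)))
  }))
  rows$feature <- "f"
  sig <- delta_significance(rows)
  expect_lt(sig$decisions$q_net, 0.05)
})
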