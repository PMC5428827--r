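surv_from <- function(cohort, endpoint = "OS")
  build_survival_table(cohort, endpoint)

long_one <- function(ids, values, feature = "f", variant = "raw")
  data.frame(patient_id = ids, feature = feature, variant = variant,
             value = values, stringsAsFactors = FALSE)

test_that("constant features get p = 1 with a flag in the Cox screen", {
  co <- small_cohort(30, seed = 14)
  surv <- surv_from(co)
  feats <- long_one(surv$patient_id, rep(3.2, nrow(surv)))
  expect_warning(res <- univariate_cox_screen(feats, surv), "constant")
  expect_equal(res$cox_p, 1)
  expect_true(res$flagged)
})

test_that("the true log-hazard passes and a permuted copy is uniform", {
  co <- generate_cohort(cohort_config(60, seed = 23))
  surv <- surv_from(co)
  lp <- co$config$beta_shape * co$latent$shape_z +
    co$config$beta_delta * co$latent$risk +
    co$config$beta_clinical * co$clinical$t34
  res <- univariate_cox_screen(long_one(surv$patient_id, lp), surv)
  expect_lt(res$cox_p, 0.10)
  # permutation null: screen p-values are uniform (KS at alpha 0.01)
  set.seed(99)
  ps <- replicate(200, {
    univariate_cox_screen(long_one(surv$patient_id, sample(lp)),
                          surv)$cox_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the rank-sum scanner screen has its exact small-sample value", {
  feats <- long_one(sprintf("P%d", 1:4), c(1, 2, 3, 4))
  scanner <- data.frame(patient_id = sprintf("P%d", 1:4),
                        scanner = c("A", "A", "B", "B"))
  res <- scanner_dependence_test(feats, scanner)
  expect_equal(res$scanner_p, 1 / 3)  # 2 of 6 rank assignments as extreme
  # complete separation at moderate n is detected
  feats2 <- long_one(sprintf("P%d", 1:20), c(rnorm(10), rnorm(10) + 100))
  scanner2 <- data.frame(patient_id = sprintf("P%d", 1:20),
                         scanner = rep(c("A", "B"), each = 10))
  expect_lt(scanner_dependence_test(feats2, scanner2)$scanner_p, 0.05)
  expect_error(scanner_dependence_test(feats,
                                       data.frame(patient_id = sprintf("P%d", 1:4),
                                                  scanner = "A")),
               "two scanner")
})

test_that("permuted scanner labels give uniform rank-sum p-values", {
  set.seed(41)
  ids <- sprintf("P%d", 1:30)
  vals <- rnorm(30)
  ps <- replicate(200, {
    sc <- data.frame(patient_id = ids,
                     scanner = sample(rep(c("A", "B"), 15)))
    scanner_dependence_test(long_one(ids, vals), sc)$scanner_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Spearman correlation handles monotone and rank-tie cases", {
  vol <- data.frame(patient_id = sprintf("P%d", 1:3),
                    volume_cm3 = c(10, 20, 30))
  expect_equal(volume_correlation(long_one(vol$patient_id, c(1, 5, 9)),
                                  vol)$rho, 1)
  expect_equal(volume_correlation(long_one(vol$patient_id, -c(10, 20, 30)),
                                  vol)$rho, -1)
  # ranks (1,2,3) vs (2,1,3): rho = 1 - 6*2/(3*8) = 0.5
  expect_equal(volume_correlation(long_one(vol$patient_id, c(2, 1, 3)),
                                  vol)$rho, 0.5)
  resc <- volume_correlation(long_one(vol$patient_id, c(1, 1, 1)), vol)
  expect_equal(resc$rho, 0)
  expect_true(resc$rho_flagged)
})

test_that("variant selection implements the keep/drop/tie-break rules", {
  scr <- data.frame(
    feature = rep(c("a", "b", "c"), each = 4),
    variant = rep(variant_ids(), 3),
    cox_p = c(0.5, 0.6, 0.7, 0.8,      # a: never significant -> dropped
              0.05, 0.5, 0.5, 0.5,     # b: exactly one eligible
              0.02, 0.03, 0.5, 0.5),   # c: two eligible, tie-break on rho
    scanner_p = c(rep(0.5, 4),
                  0.5, 0.5, 0.01, 0.5,
                  rep(0.5, 4)),
    rho = c(rep(0, 4), rep(0.1, 4), 0.6, 0.2, 0, 0))
  sel <- select_variants(scr)
  expect_false("a" %in% sel$feature)
  expect_equal(sel$variant[sel$feature == "b"], "raw")
  expect_equal(sel$variant[sel$feature == "c"], "smooth")  # |rho| 0.2 < 0.6
  # scanner-dependent variants are ineligible even when prognostic
  scr2 <- scr[scr$feature == "b", ]
  scr2$scanner_p <- 0.01
  expect_equal(nrow(select_variants(scr2)), 0)
})

test_that("raising the Cox alpha never shrinks the selected set", {
  set.seed(17)
  for (i in 1:20) {
    scr <- data.frame(feature = rep(letters[1:6], each = 4),
                      variant = rep(variant_ids(), 6),
                      cox_p = runif(24), scanner_p = runif(24),
                      rho = runif(24, -1, 1))
    s1 <- select_variants(scr, cox_alpha = 0.05)
    s2 <- select_variants(scr, cox_alpha = 0.20)
    expect_true(all(s1$feature %in% s2$feature))
    expect_false(any(duplicated(s2$feature)))
  }
})

test_that("a large planted scanner offset is rejected by the screen", {
  set.seed(29)
  ids <- sprintf("P%d", 1:40)
  rejected <- replicate(20, {
    sc <- data.frame(patient_id = ids,
                     scanner = sample(rep(c("A", "B"), 20)))
    v <- rnorm(40)
    v[sc$scanner == "B"] <- v[sc$scanner == "B"] + 3  # 3-SD offset
    scanner_dependence_test(long_one(ids, v), sc)$scanner_p < 0.05
  })
  expect_gte(mean(rejected), 0.9)
})
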