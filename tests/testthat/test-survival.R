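clin_covs <- c("sex_m", "age_ge65", "t34", "n23", "stage_3b_plus",
               "histology_squamous", "smoking_current", "pack_years_ge50",
               "kps_ge90", "dose_gt70")

test_that("landmark survival times are plain day arithmetic", {
  co <- small_cohort(5, seed = 1)
  co$clinical$entry_day <- 0
  sel <- co$outcomes$endpoint == "OS"
  co$outcomes$event_day[sel] <- c(400, 500, 300, 200, 150)
  co$outcomes$event[sel] <- c(1L, 0L, 1L, 1L, 0L)
  st <- build_survival_table(co, "OS")
  expect_equal(st$time, c(310, 410, 210, 110, 60))
  expect_equal(st$event, c(1, 0, 1, 1, 0))
  # a pre-landmark event must have been excluded upstream
  co$outcomes$event_day[sel][1] <- 80
  expect_error(build_survival_table(co, "OS"), "landmark")
})

test_that("Cox fitting matches an independent Newton-Raphson oracle", {
  set.seed(12)
  n <- 50
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  lp <- 0.7 * X[, 1] - 0.4 * X[, 2]
  time <- rexp(n, exp(lp) / 500)
  event <- rbinom(n, 1, 0.85)
  surv <- data.frame(patient_id = as.character(1:n), time = time,
                     event = event)
  fit <- deltarad:::fit_cox(surv, as.data.frame(X), c("a", "b"))
  beta <- oracle_cox_newton(X, time, event)
  expect_equal(unname(fit$coef), unname(beta), tolerance = 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
})

test_that("stepwise AIC keeps forced covariates and a planted effect", {
  co <- generate_cohort(cohort_config(60, seed = 15))
  surv <- build_survival_table(co, "OS")
  data <- co$clinical
  data$true_lp <- co$config$beta_shape * co$latent$shape_z +
    co$config$beta_delta * co$latent$risk
  set.seed(1)
  data$noise1 <- rnorm(60); data$noise2 <- rnorm(60)
  m <- stepwise_aic_cox(surv, data, c("true_lp", "noise1", "noise2"),
                        forced = "kps_ge90")
  expect_true("true_lp" %in% m$covariates)    # generating covariate kept
  expect_true("kps_ge90" %in% m$covariates)   # forced despite null effect
  expect_true(all(m$forced %in% m$covariates))
})

test_that("stepwise AIC prunes most pure-noise candidates", {
  kept <- vapply(1:8, function(s) {
    co <- generate_cohort(cohort_config(60, beta_shape = 0, beta_delta = 0,
                                        beta_clinical = 0, seed = 300 + s))
    surv <- build_survival_table(co, "OS")
    data <- co$clinical
    set.seed(s)
    for (k in 1:5) data[[paste0("noise", k)]] <- rnorm(60)
    m <- stepwise_aic_cox(surv, data, paste0("noise", 1:5))
    length(m$covariates)
  }, numeric(1))
  # AIC retains null covariates at roughly the p ~ 0.16 rate, so on
  # average most of the 5 candidates are dropped
  expect_true(all(kept <= 4))
  expect_lt(mean(kept), 2.5)
})

test_that("stepwise agrees with the reference stepAIC implementation", {
  skip_if_not_installed("MASS")
  co <- generate_cohort(cohort_config(60, seed = 7))
  surv <- build_survival_table(co, "LR")
  m <- stepwise_aic_cox(surv, co$clinical, clin_covs)
  df <- cbind(data.frame(time = surv$time, event = surv$event),
              co$clinical[clin_covs])
  full <- survival::coxph(survival::Surv(time, event) ~ .,
                          data = df, ties = "breslow")
  ref <- MASS::stepAIC(full, direction = "both", trace = 0)
  expect_setequal(m$covariates, names(coef(ref)))
  expect_equal(m$aic, stats::AIC(ref))
})

test_that("LOOCV selection runs one iteration per patient and nests levels", {
  co <- generate_cohort(cohort_config(30, seed = 22))
  surv <- build_survival_table(co, "OS")
  tabs <- generate_feature_tables(co)
  data <- merge(co$clinical, tabs$pretx[, c("patient_id",
                                            "shape_compactness2",
                                            "noise_f1")],
                by = "patient_id")
  data <- data[match(surv$patient_id, data$patient_id), ]
  freq <- nested_loocv_selection(surv, data, clin_covs[1:4],
                                 c("shape_compactness2"), c("noise_f1"))
  expect_equal(freq$n_iter, 30)
  expect_true(all(freq$counts$count <= 30))
  models <- finalize_models(freq, surv, data)
  expect_true(all(models[[1]]$covariates %in% models[[2]]$covariates))
  expect_true(all(models[[2]]$covariates %in% models[[3]]$covariates))
})

test_that("the retention threshold is strictly greater than one half", {
  freq <- structure(list(
    counts = data.frame(level = c(1, 1, 2), covariate = c("a", "b", "c"),
                        count = c(10, 11, 20)),
    n_iter = 20,
    candidates = list(clinical = c("a", "b"), pretx = "c",
                      delta = character(0))),
    class = "selection_frequency")
  surv <- data.frame(patient_id = as.character(1:20),
                     time = seq(100, 2000, 100), event = rep(1, 20))
  set.seed(2)
  data <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  models <- finalize_models(freq, surv, data)
  expect_false("a" %in% models[[1]]$covariates)  # exactly 50%: excluded
  expect_true("b" %in% models[[1]]$covariates)   # 55%: retained
  expect_true("c" %in% models[[2]]$covariates)
  expect_equal(selection_frequency(freq, "a", 1), 0.5)
  expect_equal(selection_frequency(freq, "zzz", 1), 0)
})

test_that("likelihood-ratio comparisons follow the nesting rules", {
  surv <- data.frame(patient_id = as.character(1:40),
                     time = seq(50, 2000, 50), event = rep(1, 40))
  set.seed(3)
  data <- data.frame(x = rnorm(40), y = rnorm(40))
  m0 <- deltarad:::fit_cox(surv, data, character(0))
  mx <- deltarad:::fit_cox(surv, data, "x")
  mxy <- deltarad:::fit_cox(surv, data, c("x", "y"))
  # identical covariate sets: no test possible (reported NA)
  expect_true(is.na(likelihood_ratio_test(mx, mx)$p))
  lr <- likelihood_ratio_test(m0, mxy)
  expect_equal(lr$df, 2)
  expect_gte(lr$statistic, 0)
  expect_error(likelihood_ratio_test(mxy, mx), "not nested")
})

test_that("LRT p-values are uniform when the added covariate is noise", {
  set.seed(55)
  ps <- replicate(200, {
    n <- 40
    surv <- data.frame(patient_id = as.character(1:n),
                       time = rexp(n, 1 / 500), event = rbinom(n, 1, 0.8))
    data <- data.frame(x = rnorm(n))
    likelihood_ratio_test(deltarad:::fit_cox(surv, data, character(0)),
                          deltarad:::fit_cox(surv, data, "x"))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LOOCV predictions honor the leave-one-out contract", {
  co <- generate_cohort(cohort_config(40, seed = 33))
  surv <- build_survival_table(co, "OS")
  data <- co$clinical
  data$lp <- co$config$beta_shape * co$latent$shape_z +
    co$config$beta_delta * co$latent$risk
  preds <- loocv_predict(surv, data, list(null = character(0), m = "lp"))
  expect_true(all(preds[, "null"] == 0))
  # planted cohort: predictions track the generating log-hazard
  expect_gt(cor(preds[, "m"], data$lp, method = "spearman"), 0.9)
  # patient 1's prediction cannot depend on patient 1's outcome
  surv2 <- surv
  surv2$time[1] <- surv2$time[1] + 500
  surv2$event[1] <- 1 - surv2$event[1]
  preds2 <- loocv_predict(surv2, data, list(m = "lp"))
  expect_equal(preds2[1, "m"], preds[1, "m"])
})

test_that("the concordance index matches pair enumeration and its symmetry", {
  surv3 <- data.frame(patient_id = c("a", "b", "c"), time = c(5, 10, 20),
                      event = c(1, 1, 1))
  # pairs: (a,b) discordant, (a,c) and (b,c) concordant -> 2/3
  expect_equal(concordance_index(c(0.2, 0.9, 0.1), surv3), 2 / 3)
  # risk equal to reversed event-time rank: perfect concordance
  expect_equal(concordance_index(c(3, 2, 1), surv3), 1)
  expect_equal(concordance_index(c(0, 0, 0), surv3), 0.5)
  # c(x) + c(-x) = 1 without ties
  set.seed(9)
  n <- 30
  sv <- data.frame(patient_id = as.character(1:n), time = runif(n, 1, 100),
                   event = rbinom(n, 1, 0.7))
  x <- rnorm(n)
  expect_equal(concordance_index(x, sv) + concordance_index(-x, sv), 1)
  expect_error(concordance_index(c(1, 2), data.frame(patient_id = 1:2,
                                                     time = c(5, 5),
                                                     event = c(0, 0))),
               "comparable")
})

test_that("the concordance index agrees with the survival package", {
  set.seed(18)
  n <- 60
  sv <- data.frame(patient_id = as.character(1:n),
                   time = round(runif(n, 1, 1000)) + runif(n), # no ties
                   event = rbinom(n, 1, 0.7))
  x <- rnorm(n)
  ref <- survival::concordance(survival::Surv(sv$time, sv$event) ~ x,
                               reverse = TRUE)
  expect_equal(concordance_index(x, sv), unname(ref$concordance),
               tolerance = 1e-12)
})

test_that("median-split stratification and log-rank behave at the edges", {
  # two construction-identical groups: statistic 0, p = 1
  tt <- c(100, 200, 300, 400, 500, 600)
  sv <- data.frame(patient_id = as.character(1:12), time = rep(tt, 2),
                   event = rep(1, 12))
  res <- median_split_km(c(rep(0, 6), rep(1, 6)), sv)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # KM starts at survival 1
  expect_true(all(res$km$surv <= 1))
  expect_equal(unname(summary(res$km, times = 0)$surv), c(1, 1))
  # perfectly separated event times are strongly significant
  sv2 <- data.frame(patient_id = as.character(1:20),
                    time = c(1:10 * 10, 1:10 * 10 + 2000),
                    event = rep(1, 20))
  res2 <- median_split_km(c(rep(1, 10), rep(0, 10)), sv2)
  expect_lt(res2$p, 0.01)
  # ties at the median go to the low-risk group
  p3 <- c(1, 1, 2, 2, 3, 3)  # median 2; the two 2s are assigned low
  res3 <- median_split_km(p3, sv[1:6, ])
  expect_equal(as.character(res3$group),
               c("low", "low", "low", "low", "high", "high"))
  expect_error(median_split_km(rep(1, 6), sv[1:6, ]), "identical")
})
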