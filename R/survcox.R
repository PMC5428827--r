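#' Landmark-adjusted survival table
#'
#' Measures time to each endpoint from a fixed landmark (default 90
#' days after trial entry), the standard guard against responder
#' survivorship bias when predictors are accumulated during treatment:
#' `time = event/censoring day - entry day - landmark`. Censored
#' patients are censored at their last follow-up. Patients with
#' non-positive landmark time should have been excluded upstream
#' ([apply_exclusions()]) and raise an error here.
#'
#' @param cohort A `"synthetic_cohort"` (or any list with `clinical`
#'   and `outcomes` of the same layout).
#' @param endpoint One of `"OS"`, `"DM"`, `"LR"`.
#' @param landmark_days Landmark offset in days (default 90).
#' @return Data.frame: `patient_id`, `time` (days), `event` (0/1).
#' @export
build_survival_table <- function(cohort, endpoint = c("OS", "DM", "LR"),
                                 landmark_days = 90) {
  endpoint <- match.arg(endpoint)
  oc <- cohort$outcomes[cohort$outcomes$endpoint == endpoint, ]
  m <- match(oc$patient_id, cohort$clinical$patient_id)
  tt <- oc$event_day - cohort$clinical$entry_day[m] - landmark_days
  if (any(tt <= 0))
    stop("non-positive landmark time: pre-landmark events must be excluded",
         call. = FALSE)
  data.frame(patient_id = oc$patient_id, time = tt, event = oc$event,
             stringsAsFactors = FALSE)
}

# Fit a Cox model on a fixed covariate set via the survival package's
# fitting engine (Breslow ties); returns a light-weight FittedCoxModel
# list, or NULL on failure. The formula interface is bypassed because
# the stepwise/LOOCV loops fit thousands of small models.
fit_cox <- function(surv, data, covariates, forced = character(0)) {
  y <- survival::Surv(surv$time, surv$event)
  if (length(covariates) == 0) {
    dummy <- matrix(0, nrow(surv), 1)
    null_ll <- survival::coxph.fit(dummy, y, strata = NULL, offset = NULL,
                                   init = NULL,
                                   control = survival::coxph.control(),
                                   weights = NULL, method = "breslow",
                                   rownames = NULL)$loglik[1]
    return(structure(list(covariates = character(0), forced = forced,
                          coef = numeric(0), loglik = null_ll,
                          aic = -2 * null_ll, k = 0L),
                     class = "fitted_cox"))
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(X, y, strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = "breslow",
                          rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
  structure(list(covariates = covariates, forced = forced,
                 coef = setNames(as.numeric(fit$coefficients), covariates),
                 loglik = fit$loglik[2],
                 aic = -2 * fit$loglik[2] + 2 * length(covariates),
                 k = length(covariates)),
            class = "fitted_cox")
}

#' @exportS3Method print fitted_cox
print.fitted_cox <- function(x, ...) {
  cat("Cox model:", if (x$k == 0) "(null model)"
      else paste(x$covariates, collapse = " + "), "\n")
  cat("  logLik:", format(x$loglik), " AIC:", format(x$aic), "\n")
  if (x$k > 0) print(round(x$coef, 4))
  invisible(x)
}

#' Bidirectional stepwise-AIC Cox model search with forced nesting
#'
#' Starts from the full scope (forced covariates plus all candidates)
#' and repeatedly applies the single add/drop move that most decreases
#' `AIC = -2 logL + 2k` (partial likelihood; Breslow ties), until no
#' move improves. Forced covariates are never droppable, which
#' implements the forced nesting of lower-level models inside
#' higher-level ones. Determinism: on equal AIC, drops are preferred
#' over adds, then candidate order; moves whose Cox fit fails to
#' converge are skipped with a warning.
#'
#' @param surv Survival table ([build_survival_table()]).
#' @param data Data.frame of covariate columns aligned to `surv`
#'   rows.
#' @param candidates Candidate covariate names (disjoint from
#'   `forced`).
#' @param forced Covariates that must remain in the model.
#' @return A `"fitted_cox"` object for the selected model.
#' @export
stepwise_aic_cox <- function(surv, data, candidates,
                             forced = character(0)) {
  stopifnot(!any(candidates %in% forced))
  usable <- vapply(candidates, function(v) {
    x <- data[[v]]
    !is.null(x) && all(is.finite(x)) && sd(x) > 0
  }, logical(1))
  candidates <- candidates[usable]
  current <- c(forced, candidates)
  best <- fit_cox(surv, data, current, forced)
  if (is.null(best)) {
    # fall back to forced-only start if the full model fails
    current <- forced
    best <- fit_cox(surv, data, current, forced)
    if (is.null(best)) stop("Cox fit failed for the forced model",
                            call. = FALSE)
  }
  repeat {
    moves <- list()
    for (v in intersect(candidates, best$covariates))  # drops first
      moves[[length(moves) + 1L]] <- setdiff(best$covariates, v)
    for (v in setdiff(candidates, best$covariates))    # then adds
      moves[[length(moves) + 1L]] <- c(best$covariates, v)
    if (!length(moves)) break
    fits <- lapply(moves, function(cv) fit_cox(surv, data, cv, forced))
    failed <- vapply(fits, is.null, logical(1))
    if (any(failed))
      warning("skipped ", sum(failed), " non-convergent stepwise move(s)",
              call. = FALSE)
    fits <- fits[!failed]
    if (!length(fits)) break
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    i <- which.min(aics)  # first minimum: drop-before-add tie-break
    if (aics[i] < best$aic - 1e-10) best <- fits[[i]] else break
  }
  best
}

#' Covariate selection frequencies from nested LOOCV
#'
#' The model-building loop: for each left-out patient, (1) a stepwise
#' model over the clinical factors, (2) a stepwise model over the
#' pretreatment radiomics features with model 1's covariates forced,
#' (3) a stepwise model over the delta-radiomics features with model
#' 2's covariates forced. The number of iterations in which each
#' covariate appears at each level is tabulated; covariates selected
#' in more than half the iterations are later retained
#' ([finalize_models()]). An iteration whose fit fails contributes no
#' selections at that level.
#'
#' @param surv Survival table.
#' @param data Covariate data.frame aligned to `surv`.
#' @param clinical,pretx,delta Character vectors naming the candidate
#'   columns at each level.
#' @return An object of class `"selection_frequency"`: list with
#'   `counts` (data.frame level x covariate x count) and `n_iter`.
#' @export
nested_loocv_selection <- function(surv, data, clinical, pretx, delta) {
  n <- nrow(surv)
  stopifnot(nrow(data) == n)
  tallies <- list(`1` = character(0), `2` = character(0),
                  `3` = character(0))
  for (i in seq_len(n)) {
    s <- surv[-i, , drop = FALSE]
    d <- data[-i, , drop = FALSE]
    m1 <- tryCatch(stepwise_aic_cox(s, d, clinical),
                   error = function(e) NULL)
    sel1 <- if (is.null(m1)) character(0) else m1$covariates
    m2 <- tryCatch(stepwise_aic_cox(s, d, pretx, forced = sel1),
                   error = function(e) NULL)
    sel2 <- if (is.null(m2)) sel1 else m2$covariates
    m3 <- tryCatch(stepwise_aic_cox(s, d, delta, forced = sel2),
                   error = function(e) NULL)
    sel3 <- if (is.null(m3)) sel2 else m3$covariates
    tallies[["1"]] <- c(tallies[["1"]], sel1)
    tallies[["2"]] <- c(tallies[["2"]], sel2)
    tallies[["3"]] <- c(tallies[["3"]], sel3)
  }
  counts <- do.call(rbind, lapply(names(tallies), function(lv) {
    tb <- table(tallies[[lv]])
    if (!length(tb)) return(NULL)
    data.frame(level = as.integer(lv), covariate = names(tb),
               count = as.integer(tb), stringsAsFactors = FALSE)
  }))
  structure(list(counts = counts, n_iter = n,
                 candidates = list(clinical = clinical, pretx = pretx,
                                   delta = delta)),
            class = "selection_frequency")
}

#' Selection frequency of a covariate at a level
#'
#' @param freq A `"selection_frequency"` object.
#' @param covariate Covariate name.
#' @param level Model level (1, 2 or 3).
#' @return Fraction of LOOCV iterations selecting the covariate.
#' @export
selection_frequency <- function(freq, covariate, level) {
  cc <- freq$counts
  hit <- cc$count[cc$level == level & cc$covariate == covariate]
  if (!length(hit)) 0 else hit / freq$n_iter
}

#' Final nested models from the selection frequencies
#'
#' Per level, retains covariates selected in strictly more than
#' `threshold` of the LOOCV iterations, enforces nesting (level k
#' contains level k-1's covariates) and refits the final Cox models on
#' all patients. A level that adds nothing new reuses the previous
#' level's model (the null model at level 1).
#'
#' @param freq A `"selection_frequency"` object.
#' @param surv,data As in [nested_loocv_selection()].
#' @param threshold Retention threshold as a fraction (default 0.5,
#'   strict).
#' @return List of three `"fitted_cox"` models (levels 1..3).
#' @export
finalize_models <- function(freq, surv, data, threshold = 0.5) {
  cc <- freq$counts
  keep_level <- function(lv, pool) {
    if (is.null(cc)) return(character(0))
    k <- cc$covariate[cc$level == lv &
                        cc$count / freq$n_iter > threshold]
    intersect(pool, k)
  }
  pools <- list(freq$candidates$clinical,
                c(freq$candidates$clinical, freq$candidates$pretx),
                c(freq$candidates$clinical, freq$candidates$pretx,
                  freq$candidates$delta))
  sets <- list()
  prev <- character(0)
  for (lv in 1:3) {
    sets[[lv]] <- union(prev, keep_level(lv, pools[[lv]]))
    prev <- sets[[lv]]
  }
  lapply(sets, function(cv) fit_cox(surv, data, cv))
}

#' Likelihood-ratio test between nested Cox models
#'
#' `2 (logL_large - logL_small)` referred to chi-squared with
#' `k_large - k_small` degrees of freedom. Models with identical
#' covariate sets return `NA` (no test possible).
#'
#' @param model_small,model_large `"fitted_cox"` objects fitted to the
#'   same data, with `model_small`'s covariates a subset of
#'   `model_large`'s.
#' @return List with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(model_small, model_large) {
  if (!all(model_small$covariates %in% model_large$covariates))
    stop("models are not nested", call. = FALSE)
  df <- model_large$k - model_small$k
  if (df == 0)
    return(list(statistic = NA_real_, df = 0L, p = NA_real_))
  stat <- max(0, 2 * (model_large$loglik - model_small$loglik))
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Unbiased LOOCV risk predictions for fixed covariate sets
#'
#' For each model's frozen covariate set, refits the coefficients with
#' each patient left out in turn and records the left-out patient's
#' uncentered linear predictor `x_i' beta`. No covariate reduction
#' happens here, so the left-out prediction is unbiased. An empty
#' covariate set predicts 0 for everyone; a failed refit yields `NA`.
#'
#' @param surv Survival table.
#' @param data Covariate data.frame aligned to `surv`.
#' @param covariate_sets List of character vectors (e.g. the covariate
#'   sets of the finalized models).
#' @return Matrix of predictions, patients x models.
#' @export
loocv_predict <- function(surv, data, covariate_sets) {
  n <- nrow(surv)
  out <- matrix(NA_real_, n, length(covariate_sets))
  colnames(out) <- names(covariate_sets)
  for (k in seq_along(covariate_sets)) {
    cv <- covariate_sets[[k]]
    if (length(cv) == 0) { out[, k] <- 0; next }
    for (i in seq_len(n)) {
      fit <- fit_cox(surv[-i, , drop = FALSE], data[-i, , drop = FALSE],
                     cv)
      if (is.null(fit)) next
      out[i, k] <- sum(fit$coef * as.numeric(data[i, cv]))
    }
  }
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risks are
#' concordant with the observed event ordering: a pair is comparable
#' when the earlier time belongs to a patient with an observed event
#' (pairs tied on time are not compared); concordance requires the
#' earlier-event patient to have the higher risk score, ties in the
#' score count 0.5. Values range from 0 to 1; 0.5 is chance level.
#'
#' @param predictions Risk scores (higher = earlier event expected).
#' @param surv Survival table aligned to `predictions`.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(predictions, surv) {
  ok <- !is.na(predictions)
  p <- predictions[ok]
  tt <- surv$time[ok]
  ev <- surv$event[ok]
  n <- length(p)
  num <- den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (tt[i] == tt[j]) next
      a <- if (tt[i] < tt[j]) i else j
      b <- if (tt[i] < tt[j]) j else i
      if (ev[a] != 1) next
      den <- den + 1
      if (p[a] > p[b]) num <- num + 1
      else if (p[a] == p[b]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  num / den
}

#' Median-split Kaplan-Meier stratification and log-rank test
#'
#' Stratifies patients as high risk (prediction strictly above the
#' median; ties at the median go to the low-risk group) versus low
#' risk, estimates Kaplan-Meier curves per stratum and tests the
#' stratification with the two-group log-rank test.
#'
#' @param predictions Risk scores.
#' @param surv Survival table aligned to `predictions`.
#' @return List with `group` (factor `"low"`/`"high"`), `km`
#'   (`survfit` object), `chisq` and `p`.
#' @export
median_split_km <- function(predictions, surv) {
  if (length(unique(predictions)) < 2)
    stop("all predictions identical: stratification undefined",
         call. = FALSE)
  grp <- factor(ifelse(predictions > median(predictions), "high", "low"),
                levels = c("low", "high"))
  if (min(table(grp)) < 2)
    stop("need >= 2 patients per stratum", call. = FALSE)
  df <- data.frame(time = surv$time, event = surv$event, group = grp)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(group = grp, km = km, chisq = sdf$chisq,
       p = pchisq(sdf$chisq, df = 1, lower.tail = FALSE))
}
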