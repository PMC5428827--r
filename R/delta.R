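#' Mixed-effects dose-response screen for one feature
#'
#' Fits the random-intercept model
#' `value ~ dose + (1 | patient)` by maximum likelihood and tests the
#' dose term with a likelihood-ratio test against the nested model
#' without dose (chi-squared, 1 df). ML (not REML) is used because the
#' two models differ in their fixed effects. Singular fits (zero
#' between-patient variance) fall back to the boundary model, which
#' remains valid for the LRT.
#'
#' @param rows Data.frame with columns `patient_id`, `dose_gy`,
#'   `value` (one feature's longitudinal measurements).
#' @return List with `p` (LRT p-value), `beta_dose` (ML estimate) and
#'   `statistic`.
#' @export
fit_dose_lmm <- function(rows) {
  stopifnot(all(c("patient_id", "dose_gy", "value") %in% names(rows)))
  rows <- rows[complete.cases(rows[, c("patient_id", "dose_gy", "value")]), ]
  if (length(unique(rows$patient_id)) < 2)
    stop("need >= 2 patients", call. = FALSE)
  # exactly-constant values within every patient: the dose effect is
  # identically zero and the residual variance degenerates, so the
  # profiled likelihoods are numerically meaningless; report the exact
  # answer instead of optimizer noise
  wvar <- tapply(rows$value, rows$patient_id, function(v) var(v))
  if (all(is.na(wvar) | wvar == 0))
    return(list(p = 1, beta_dose = 0, statistic = 0))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  quiet_lmer <- function(formula)
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = rows, REML = FALSE, control = ctrl)))
  full <- quiet_lmer(value ~ dose_gy + (1 | patient_id))
  null <- quiet_lmer(value ~ 1 + (1 | patient_id))
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  list(p = pchisq(stat, df = 1, lower.tail = FALSE),
       beta_dose = unname(lme4::fixef(full)["dose_gy"]),
       statistic = stat)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `p_(i) <- min_(j >= i) (m p_(j) / j)`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Per-patient delta-radiomics features
#'
#' Summarizes each patient's longitudinal trajectory of one feature
#' into the delta-radiomics triplet: the relative net change
#' `(value_weekFinal - value_week1) / value_week1`, the ordinary
#' least-squares slope of the feature on cumulative dose (per Gy), and
#' the last-week value. Week 1 is the first weekly intra-treatment
#' scan; the pretreatment scan (week 0) is reported separately as
#' `week0`. Missing weeks are simply omitted from the slope fit. The
#' relative net change is flagged missing when the week-1 value is 0,
#' and the slope when fewer than two weekly values exist.
#'
#' @param rows Data.frame with columns `patient_id`, `week`, `dose_gy`,
#'   `value` for a single feature (week 0 optional).
#' @return Data.frame with one row per patient: `patient_id`,
#'   `net_change`, `slope`, `week_last`, `week1`, `week0`.
#' @export
compute_delta_features <- function(rows) {
  stopifnot(all(c("patient_id", "week", "dose_gy", "value") %in% names(rows)))
  out <- lapply(split(rows, rows$patient_id), function(d) {
    d <- d[order(d$week), ]
    wk <- d[d$week >= 1 & !is.na(d$value), ]
    w0 <- d$value[d$week == 0]
    if (nrow(wk) == 0)
      return(data.frame(patient_id = d$patient_id[1], net_change = NA_real_,
                        slope = NA_real_, week_last = NA_real_,
                        week1 = NA_real_,
                        week0 = if (length(w0)) w0[1] else NA_real_))
    v1 <- wk$value[1]
    vf <- wk$value[nrow(wk)]
    net <- if (v1 != 0) (vf - v1) / v1 else NA_real_
    slope <- if (nrow(wk) >= 2 && sd(wk$dose_gy) > 0)
      unname(coef(lm(value ~ dose_gy, data = wk))["dose_gy"]) else NA_real_
    data.frame(patient_id = d$patient_id[1], net_change = net,
               slope = slope, week_last = vf, week1 = v1,
               week0 = if (length(w0)) w0[1] else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Dose-response significance decision per feature
#'
#' Combines, for each feature, the mixed-effects dose screen with
#' one-sample two-tailed t-tests of the group's relative net changes
#' and slopes against 0. All three p-value families are
#' Benjamini-Hochberg adjusted across features; a feature passes the
#' delta stage only if all three adjusted p-values fall below `alpha`.
#' A zero-variance t-test is defined as p = 0 when the mean is nonzero
#' and p = 1 otherwise (flagged).
#'
#' @param longitudinal Long data.frame (`patient_id`, `week`,
#'   `dose_gy`, `feature`, `value`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with `decisions` (data.frame: feature, the three raw
#'   and adjusted p-values, `pass`) and `delta` (named list of
#'   per-feature delta tables from [compute_delta_features()]).
#' @export
delta_significance <- function(longitudinal, alpha = 0.05) {
  feats <- unique(longitudinal$feature)
  safe_t <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    if (sd(x) == 0) {
      warning("zero-variance delta feature", call. = FALSE)
      return(if (mean(x) != 0) 0 else 1)
    }
    t.test(x, mu = 0)$p.value
  }
  rows <- lapply(feats, function(f) {
    d <- longitudinal[longitudinal$feature == f, ]
    lmm <- fit_dose_lmm(d)
    dl <- compute_delta_features(d)
    data.frame(feature = f, p_lmm = lmm$p, p_net = safe_t(dl$net_change),
               p_slope = safe_t(dl$slope), stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, rows)
  dec$q_lmm <- bh_adjust(dec$p_lmm)
  dec$q_net <- bh_adjust(dec$p_net)
  dec$q_slope <- bh_adjust(dec$p_slope)
  dec$pass <- dec$q_lmm < alpha & dec$q_net < alpha & dec$q_slope < alpha
  delta <- lapply(setNames(feats, feats), function(f)
    compute_delta_features(longitudinal[longitudinal$feature == f, ]))
  list(decisions = dec, delta = delta)
}

#' Assemble the delta-radiomics covariate table
#'
#' Turns the per-feature delta tables of the features passing the
#' dose-response screen into one wide covariate table, using the
#' conventional suffixes `netPercentChange`, `Slope` and `WeekLast`
#' (and `Week0` for the pretreatment value of longitudinal features).
#'
#' @param sig Result of [delta_significance()].
#' @param include_week0 Also emit the `_Week0` columns.
#' @return Wide data.frame keyed by `patient_id`.
#' @export
delta_covariates <- function(sig, include_week0 = FALSE) {
  keep <- sig$decisions$feature[sig$decisions$pass]
  ids <- unique(unlist(lapply(sig$delta, function(d) d$patient_id)))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (f in keep) {
    d <- sig$delta[[f]]
    m <- match(out$patient_id, d$patient_id)
    out[[paste0(f, "_netPercentChange")]] <- d$net_change[m]
    out[[paste0(f, "_Slope")]] <- d$slope[m]
    out[[paste0(f, "_WeekLast")]] <- d$week_last[m]
    if (include_week0) out[[paste0(f, "_Week0")]] <- d$week0[m]
  }
  out
}
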