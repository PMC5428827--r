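#' Univariate Cox screen of pretreatment features
#'
#' Fits, for every (feature, variant) combination, a one-covariate Cox
#' proportional-hazards model of the landmark-adjusted survival times
#' on the z-scored pretreatment feature, and reports the
#' likelihood-ratio p-value against the null model (does the feature
#' alone fit better than no covariate). No multiplicity correction is
#' applied: these p-values steer feature selection, not hypothesis
#' tests. Constant features and monotone-likelihood divergences are
#' flagged and assigned p = 1.
#'
#' @param features Long data.frame with columns `patient_id`,
#'   `feature`, `variant`, `value` (pretreatment values).
#' @param surv Data.frame with `patient_id`, `time`, `event` (see
#'   [build_survival_table()]).
#' @return Data.frame: `feature`, `variant`, `cox_p`, `flagged`.
#' @export
univariate_cox_screen <- function(features, surv) {
  key <- interaction(features$feature, features$variant, drop = TRUE)
  rows <- lapply(split(features, key), function(d) {
    m <- match(d$patient_id, surv$patient_id)
    ok <- !is.na(m) & !is.na(d$value)
    res <- data.frame(feature = d$feature[1], variant = d$variant[1],
                      cox_p = 1, flagged = FALSE, stringsAsFactors = FALSE)
    x <- d$value[ok]
    if (sum(ok) < 3 || sd(x) == 0) {
      res$flagged <- TRUE
      warning("constant or unusable feature in Cox screen: ",
              d$feature[1], "/", d$variant[1], call. = FALSE)
      return(res)
    }
    z <- (x - mean(x)) / sd(x)
    df <- data.frame(time = surv$time[m[ok]], event = surv$event[m[ok]],
                     z = z)
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ z, data = df),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(coef(fit)) || abs(coef(fit)) > 15) {
      res$flagged <- TRUE
      return(res)
    }
    stat <- 2 * (fit$loglik[2] - fit$loglik[1])
    res$cox_p <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scanner-dependence screen
#'
#' Two-sided Wilcoxon rank-sum test of each (feature, variant)'s
#' first-week values between the two CT scanner models. The exact
#' distribution is used for combined sample sizes up to 20, the
#' tie-corrected normal approximation otherwise. A small p-value means
#' the feature tracks the scanner rather than the tumor.
#'
#' @param features Long data.frame of week-1 values (`patient_id`,
#'   `feature`, `variant`, `value`).
#' @param scanner Data.frame with `patient_id` and `scanner` (two
#'   labels).
#' @return Data.frame: `feature`, `variant`, `scanner_p`.
#' @export
scanner_dependence_test <- function(features, scanner) {
  labs <- unique(scanner$scanner)
  if (length(labs) != 2)
    stop("need exactly two scanner groups", call. = FALSE)
  key <- interaction(features$feature, features$variant, drop = TRUE)
  rows <- lapply(split(features, key), function(d) {
    grp <- scanner$scanner[match(d$patient_id, scanner$patient_id)]
    x <- d$value[grp == labs[1] & !is.na(d$value)]
    y <- d$value[grp == labs[2] & !is.na(d$value)]
    if (length(x) == 0 || length(y) == 0)
      stop("empty scanner group for feature ", d$feature[1], call. = FALSE)
    p <- suppressWarnings(
      wilcox.test(x, y, exact = (length(x) + length(y)) <= 20)$p.value)
    data.frame(feature = d$feature[1], variant = d$variant[1],
               scanner_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volume-correlation tie-break statistic
#'
#' Spearman rank correlation (average ranks on ties) between each
#' (feature, variant)'s pretreatment values and the gross tumor
#' volume. Among variants that survive both screens, the one least
#' correlated with volume (smallest absolute rho) is preferred, since
#' volume itself is already a shape feature. A constant feature has
#' undefined rho and is recorded as 0 with a flag.
#'
#' @param features Long data.frame (`patient_id`, `feature`,
#'   `variant`, `value`).
#' @param volumes Data.frame with `patient_id`, `volume_cm3`.
#' @return Data.frame: `feature`, `variant`, `rho`, `rho_flagged`.
#' @export
volume_correlation <- function(features, volumes) {
  key <- interaction(features$feature, features$variant, drop = TRUE)
  rows <- lapply(split(features, key), function(d) {
    v <- volumes$volume_cm3[match(d$patient_id, volumes$patient_id)]
    ok <- !is.na(d$value) & !is.na(v)
    if (sum(ok) < 3) stop("need >= 3 patients", call. = FALSE)
    flag <- sd(d$value[ok]) == 0
    rho <- if (flag) 0 else
      suppressWarnings(cor(d$value[ok], v[ok], method = "spearman"))
    data.frame(feature = d$feature[1], variant = d$variant[1], rho = rho,
               rho_flagged = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature-specific preprocessing selection
#'
#' Combines the three screens into the final feature set: a variant is
#' eligible if its univariate Cox p-value is below `cox_alpha` and its
#' scanner p-value is above `scanner_alpha`; a feature with no
#' eligible variant is dropped entirely; among several eligible
#' variants the one with the smallest absolute volume correlation
#' wins, ties broken by the fixed variant order raw, smooth,
#' resample8, smooth_resample8.
#'
#' @param screen Data.frame with columns `feature`, `variant`,
#'   `cox_p`, `scanner_p`, `rho` (merge of the three screen outputs).
#' @param cox_alpha Univariate significance threshold (default 0.10).
#' @param scanner_alpha Scanner-dependence threshold (default 0.05).
#' @return Data.frame manifest: `feature`, `variant`, plus the
#'   screening values of the chosen variant.
#' @export
select_variants <- function(screen, cox_alpha = 0.10, scanner_alpha = 0.05) {
  stopifnot(all(c("feature", "variant", "cox_p", "scanner_p", "rho") %in%
                  names(screen)))
  order_ids <- c(variant_ids(), "none")
  rows <- lapply(split(screen, screen$feature), function(d) {
    el <- d[d$cox_p < cox_alpha & d$scanner_p > scanner_alpha, ,
            drop = FALSE]
    if (nrow(el) == 0) return(NULL)
    el <- el[order(abs(el$rho), match(el$variant, order_ids)), ,
             drop = FALSE]
    el[1, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(screen[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}
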