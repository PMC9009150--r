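#' Kaplan--Meier product-limit estimate
#'
#' Product-limit survival curve via [survival::survfit()]; censored subjects
#' leave the risk set after their time, and events precede censorings tied
#' at the same time (the standard convention).
#'
#' @param time positive survival times (days).
#' @param event 0/1 event indicators.
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv` (the step value of S-hat just after `time`).
#' @export
km_estimate <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survfit(Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], surv = fit$surv[keep])
}

# KM median survival: smallest event time with S(t) <= 0.5; +Inf when the
# curve never reaches 0.5 (long survivors)
km_median <- function(time, event) {
  km <- km_estimate(time, event)
  if (nrow(km) == 0L || all(km$surv > 0.5)) return(Inf)
  min(km$time[km$surv <= 0.5])
}

#' Two-group log-rank test
#'
#' Observed-minus-expected log-rank comparison via [survival::survdiff()];
#' p from chi-square with 1 df.
#'
#' @param time positive survival times. @param event 0/1 indicators.
#' @param group vector with exactly two distinct labels.
#' @return list with `chisq`, `p`, `n` (per-group sizes).
#' @export
logrank_test <- function(time, event, group) {
  if (any(time <= 0)) stop("survival times must be positive")
  group <- as.character(group)
  if (length(unique(group)) != 2L) stop("need exactly two groups")
  if (sum(event) < 1) stop("need at least one event")
  sd0 <- survdiff(Surv(time, event) ~ group)
  chisq <- unname(sd0$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       n = as.vector(table(group)))
}

#' Univariate Cox proportional-hazards fit
#'
#' One-covariate Cox partial-likelihood fit via [survival::coxph()] with
#' Efron tie handling. A monotone partial likelihood (perfect separation)
#' is reported with `converged = FALSE` rather than an error; downstream
#' consumers must not use `beta` from an unconverged fit.
#'
#' @param time positive survival times. @param event 0/1 indicators.
#' @param x real covariate (non-constant).
#' @return list with `beta`, `hr`, `se`, `z`, `p`, `converged`, `n`,
#'   `n_events`.
#' @export
cox_univariate <- function(time, event, x) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (sum(event) < 1) stop("need at least one event")
  if (length(unique(x)) < 2L) stop("covariate is constant")
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, ties = "efron",
          control = coxph.control(eps = 1e-10, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  z <- beta / se
  list(beta = beta, hr = exp(beta), se = se, z = z,
       p = 2 * pnorm(-abs(z)), converged = converged,
       n = fit$n, n_events = fit$nevent)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the two-group log-rank statistic at every distinct score value
#' whose split keeps both groups inside the admissibility window (default:
#' low-group fraction between 10% and 90%) and returns the maximizing
#' threshold. Samples with score <= threshold form the low group. The
#' reported p is the unadjusted log-rank p at the selected threshold and is
#' selection-biased (flagged); no minP correction is applied.
#'
#' @param scores per-sample scores (non-constant, >= 20 subjects).
#' @param time positive survival times. @param event 0/1 indicators.
#' @param quantile_range admissibility window for the low-group fraction
#'   (default `c(0.10, 0.90)`).
#' @return list with `threshold`, `chisq`, `p`, `n_low`, `n_high`,
#'   `selection_biased = TRUE`.
#' @export
optimal_cutpoint <- function(scores, time, event,
                             quantile_range = c(0.10, 0.90)) {
  n <- length(scores)
  if (n < 20L) stop("need at least 20 subjects for cutpoint selection")
  if (length(unique(scores)) < 2L) stop("scores are constant; no admissible split")
  if (sum(event) < 1) stop("need at least one event")
  cand <- sort(unique(scores))
  cand <- cand[-length(cand)]  # splitting at the max leaves high empty
  frac_low <- vapply(cand, function(cc) mean(scores <= cc), numeric(1))
  ok <- frac_low >= quantile_range[1L] & frac_low <= quantile_range[2L]
  if (!any(ok)) stop("no admissible split inside the quantile window")
  cand <- cand[ok]
  stat <- vapply(cand, function(cc) {
    g <- scores > cc
    sd0 <- survdiff(Surv(time, event) ~ g)
    unname(sd0$chisq)
  }, numeric(1))
  best <- which.max(stat)
  thr <- cand[best]
  lr <- logrank_test(time, event, ifelse(scores > thr, "high", "low"))
  list(threshold = thr, chisq = lr$chisq, p = lr$p,
       n_low = sum(scores <= thr), n_high = sum(scores > thr),
       selection_biased = TRUE)
}

#' Classify cancer types by the survival direction of the NET score
#'
#' Per cancer type, dichotomizes samples at the maximally selected NET-score
#' cutpoint and tests high vs low survival with the log-rank test. A type is
#' `favorable` when p < `p_sig` and the high-score group has the larger
#' Kaplan--Meier median survival, `poor` when p < `p_sig` and it has the
#' smaller, else `neutral`. Direction is decided by KM medians (undefined
#' medians count as +Inf; if both are undefined the Cox HR sign decides).
#' The reported HR is high-vs-low from a univariate Cox fit on the group
#' indicator.
#'
#' @param scores named per-sample NET scores.
#' @param clinical clinical data.frame (needs `sample`, `cancer_type`,
#'   `time`, `event`).
#' @param cfg configuration from [analysis_config()].
#' @return data.frame, one row per classified cancer type: `cancer_type`,
#'   `class`, `p`, `hr`, `threshold`, `n_high`, `n_low`, `median_high`,
#'   `median_low`. Types with fewer than 20 subjects with survival (or no
#'   events) are skipped with a warning.
#' @export
classify_net_survival <- function(scores, clinical, cfg = analysis_config()) {
  clinical <- check_clinical(clinical)
  rows <- list()
  for (ct in unique(clinical$cancer_type)) {
    cl <- clinical[clinical$cancer_type == ct & clinical$tissue == "tumor" &
                     !is.na(clinical$time) & !is.na(clinical$event) &
                     clinical$time > 0, , drop = FALSE]
    cl <- cl[cl$sample %in% names(scores), , drop = FALSE]
    if (nrow(cl) < 20L || sum(cl$event) < 1L) {
      warning("cancer type '", ct, "' skipped: <20 subjects with survival ",
              "or no events")
      next
    }
    sc <- scores[cl$sample]
    cut <- tryCatch(
      optimal_cutpoint(sc, cl$time, cl$event,
                       quantile_range = cfg$cutpoint_quantile_range),
      error = function(e) NULL)
    if (is.null(cut)) {
      warning("cancer type '", ct, "' skipped: no admissible cutpoint")
      next
    }
    high <- sc > cut$threshold
    med_hi <- km_median(cl$time[high], cl$event[high])
    med_lo <- km_median(cl$time[!high], cl$event[!high])
    cx <- cox_univariate(cl$time, cl$event, as.numeric(high))
    cls <- "neutral"
    if (cut$p < cfg$p_sig) {
      direction <- if (is.infinite(med_hi) && is.infinite(med_lo)) {
        if (cx$beta < 0) "favorable" else "poor"
      } else if (med_hi > med_lo) "favorable" else "poor"
      cls <- direction
    }
    rows[[ct]] <- data.frame(
      cancer_type = ct, class = cls, p = cut$p, hr = cx$hr,
      threshold = cut$threshold, n_high = cut$n_high, n_low = cut$n_low,
      median_high = med_hi, median_low = med_lo, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no cancer type had enough survival data to classify")
  if (all(out$class == "neutral"))
    warning("every cancer type classified neutral; the NRG screen needs ",
            "both survival classes")
  rownames(out) <- NULL
  out
}
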