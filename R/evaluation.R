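#' Kaplan-Meier curves, log-rank test and pairwise hazard ratios
#'
#' Product-limit estimates per group, the k-group log-rank test, and
#' pairwise Cox hazard ratios (Efron ties) with Wald 95% confidence
#' intervals against the first group level.  A group whose curve never
#' crosses 0.5 has an undefined median, reported as `NA`.
#'
#' @param groups factor (or coercible) of group labels, each with at
#'   least one subject.
#' @param time,event survival endpoint.
#' @return list of class `survival_comparison`: `medians`, `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, `hr_table`, `fit` (the `survfit` object).
#' @export
km_logrank <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop_invalid("need at least 2 non-empty groups")
  if (any(table(groups) == 0L)) stop_invalid("every group needs >= 1 subject")
  y <- survival::Surv(time, event)
  fit <- survival::survfit(y ~ groups)
  med <- summary(fit)$table[, "median"]
  names(med) <- levels(groups)
  sd_ <- survival::survdiff(y ~ groups)
  df <- nlevels(groups) - 1L
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  ref <- levels(groups)[1]
  hr <- lapply(levels(groups)[-1], function(g) {
    sel <- groups %in% c(ref, g)
    cf <- survival::coxph(survival::Surv(time[sel], event[sel]) ~
                            I(groups[sel] == g), ties = "efron")
    ci <- summary(cf)$conf.int
    data.frame(group = g, reference = ref, hr = unname(ci[1, 1]),
               lower = unname(ci[1, 3]), upper = unname(ci[1, 4]),
               p = unname(summary(cf)$coefficients[1, "Pr(>|z|)"]))
  })
  structure(list(medians = med, logrank_chisq = unname(sd_$chisq),
                 logrank_df = df, logrank_p = unname(p),
                 hr_table = do.call(rbind, hr), fit = fit),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> log-rank chisq %.3f (df %d), p = %.4g\n",
              x$logrank_chisq, x$logrank_df, x$logrank_p))
  cat("medians (months):\n"); print(round(x$medians, 2))
  invisible(x)
}

## Harrell comparability/concordance over all ordered pairs:
## pair (i, j) is comparable when the earlier time is an observed event
## (ties in time comparable only when exactly one is an event, the event
## being the earlier failure); ties in score credit 1/2.
concordance_counts <- function(scores, time, event) {
  ti <- outer(time, time, "<")
  te <- outer(time, time, "==")
  ei <- matrix(event == 1, length(event), length(event))
  ej <- t(ei)
  comp <- (ti & ei) | (te & ei & !ej)       # i fails first, observed
  si <- outer(scores, scores, ">")
  se <- outer(scores, scores, "==")
  conc <- sum(comp & si) + 0.5 * sum(comp & se)
  list(concordant = conc, comparable = sum(comp))
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the earlier-failing
#' patient has the higher risk score, with score ties credited 0.5.  The
#' confidence interval comes from a seeded patient-level bootstrap.
#'
#' @param scores numeric risk scores (higher = earlier failure expected).
#' @param time,event survival endpoint.
#' @param ci compute a bootstrap confidence interval.
#' @param n_boot bootstrap draws (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return list of class `c_index`: `c_index`, `n_comparable`, and with
#'   `ci = TRUE` the `lower`/`upper` percentile bounds.
#' @export
c_index <- function(scores, time, event, ci = FALSE, n_boot = 2000,
                    seed = 1, conf = 0.95) {
  cc <- concordance_counts(scores, time, event)
  if (cc$comparable == 0L) stop_invalid("no comparable pair")
  out <- list(c_index = cc$concordant / cc$comparable,
              n_comparable = cc$comparable)
  if (ci) {
    set.seed(as.integer(seed))
    n <- length(scores)
    bs <- vapply(seq_len(n_boot), function(b) {
      k <- sample.int(n, n, replace = TRUE)
      ccb <- concordance_counts(scores[k], time[k], event[k])
      if (ccb$comparable == 0L) NA_real_ else ccb$concordant / ccb$comparable
    }, numeric(1))
    qs <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    out$lower <- unname(qs[1]); out$upper <- unname(qs[2])
  }
  class(out) <- "c_index"
  out
}

#' @export
print.c_index <- function(x, ...) {
  cat(sprintf("C-index %.3f%s (%d comparable pairs)\n", x$c_index,
              if (!is.null(x$lower)) sprintf(" [%.3f, %.3f]", x$lower, x$upper) else "",
              x$n_comparable))
  invisible(x)
}

## inverse-probability-of-censoring weights for event status at `horizon`:
## events before the horizon weight 1/G(t-), survivors 1/G(horizon),
## records censored before the horizon weight 0 (status unknowable)
ipcw_weights <- function(time, event, horizon) {
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv))
  Gm <- function(t) {  # left-continuous G(t-)
    vapply(t, function(tt) G(max(tt - 1e-9, 0)), numeric(1))
  }
  is_event <- time <= horizon & event == 1
  is_surv <- time > horizon
  w <- numeric(length(time))
  w[is_event] <- 1 / pmax(Gm(time[is_event]), 1e-8)
  w[is_surv] <- 1 / pmax(G(horizon), 1e-8)
  list(status = ifelse(is_event, 1L, ifelse(is_surv, 0L, NA_integer_)), w = w)
}

nri_idi_point <- function(risk_new, risk_old, status, w) {
  ev <- !is.na(status) & status == 1L
  ne <- !is.na(status) & status == 0L
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  p_up_e <- wmean(up[ev], w[ev]); p_dn_e <- wmean(down[ev], w[ev])
  p_up_n <- wmean(up[ne], w[ne]); p_dn_n <- wmean(down[ne], w[ne])
  nri <- (p_up_e - p_dn_e) - (p_up_n - p_dn_n)
  idi <- (wmean(risk_new[ev], w[ev]) - wmean(risk_new[ne], w[ne])) -
    (wmean(risk_old[ev], w[ev]) - wmean(risk_old[ne], w[ne]))
  c(nri = nri, idi = idi)
}

#' Continuous NRI and IDI between two risk models
#'
#' Category-free net reclassification improvement and integrated
#' discrimination improvement of `risk_new` over `risk_old` for event
#' status at `horizon` months.  Censoring before the horizon is handled
#' by inverse-probability-of-censoring weighting; p-values come from a
#' seeded patient-level bootstrap (normal approximation on the bootstrap
#' standard error).
#'
#' @param risk_new,risk_old per-patient risks from the two models, on the
#'   same patients (probabilities for a meaningful IDI; any monotone risk
#'   scale for the NRI).
#' @param time,event survival endpoint.
#' @param horizon evaluation horizon in months (default 6), within
#'   follow-up.
#' @param n_boot bootstrap draws for the p-values.
#' @param seed integer seed.
#' @return list of class `nri_idi`: `nri`, `idi`, `nri_p`, `idi_p`,
#'   `horizon`.
#' @export
nri_idi <- function(risk_new, risk_old, time, event, horizon = 6,
                    n_boot = 1000, seed = 1) {
  if (horizon > max(time)) stop_invalid("horizon lies beyond all follow-up")
  if (length(risk_new) != length(risk_old) || length(risk_new) != length(time))
    stop_invalid("both models must score the same patients")
  ip <- ipcw_weights(time, event, horizon)
  est <- nri_idi_point(risk_new, risk_old, ip$status, ip$w)
  set.seed(as.integer(seed))
  n <- length(time)
  bs <- vapply(seq_len(n_boot), function(b) {
    k <- sample.int(n, n, replace = TRUE)
    ipb <- ipcw_weights(time[k], event[k], horizon)
    nri_idi_point(risk_new[k], risk_old[k], ipb$status, ipb$w)
  }, numeric(2))
  se <- apply(bs, 1, sd, na.rm = TRUE)
  pv <- ifelse(se > 0, 2 * pnorm(-abs(est) / se), ifelse(est == 0, 1, NA))
  structure(list(nri = unname(est["nri"]), idi = unname(est["idi"]),
                 nri_p = unname(pv[1]), idi_p = unname(pv[2]),
                 horizon = horizon),
            class = "nri_idi")
}

#' Decision-curve net benefit
#'
#' Net benefit at threshold probability Pt is the proportion of true
#' positives minus the proportion of false positives weighted by
#' `Pt / (1 - Pt)`: `NB(Pt) = TP/n - (FP/n) * Pt/(1 - Pt)`.  The
#' treat-all curve is `prevalence - (1 - prevalence) * Pt/(1 - Pt)` and
#' the treat-none curve is identically zero.
#'
#' @param predicted risk probabilities in `[0, 1]` (a patient is treated
#'   when `predicted >= Pt`), or logical high-risk flags (fixed policy
#'   across thresholds).
#' @param outcome binary event outcomes (0/1 or logical).
#' @param thresholds grid of threshold probabilities, strictly inside
#'   `(0, 1)`; values at 1 are excluded.
#' @return data.frame of class `net_benefit_curve` with columns
#'   `threshold`, `nb`, `nb_all`, `nb_none`.
#' @export
net_benefit <- function(predicted, outcome, thresholds = seq(0.01, 0.6, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  if (length(thresholds) == 0L) stop_invalid("empty threshold grid inside (0, 1)")
  outcome <- as.integer(outcome)
  n <- length(outcome)
  prev <- mean(outcome)
  flagged <- function(pt) if (is.logical(predicted)) predicted else predicted >= pt
  nb <- vapply(thresholds, function(pt) {
    f <- flagged(pt)
    tp <- sum(f & outcome == 1L); fp <- sum(f & outcome == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, nb = nb, nb_all = nb_all,
                    nb_none = 0)
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Clinical impact curve
#'
#' For each threshold probability, the number of patients (per 100)
#' flagged high-risk by the model and the number of those flagged who
#' truly experience the event, with percentile bootstrap confidence
#' intervals.
#'
#' @inheritParams net_benefit
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return data.frame: `threshold`, `n_high` (+ CI), `n_high_event` (+ CI),
#'   all per 100 patients.
#' @export
clinical_impact <- function(predicted, outcome,
                            thresholds = seq(0.01, 0.6, by = 0.01),
                            n_boot = 500, seed = 1, conf = 0.95) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  outcome <- as.integer(outcome)
  n <- length(outcome)
  counts <- function(pred, out_) {
    vapply(thresholds, function(pt) {
      f <- if (is.logical(pred)) pred else pred >= pt
      c(sum(f), sum(f & out_ == 1L)) * 100 / length(out_)
    }, numeric(2))
  }
  est <- counts(predicted, outcome)
  set.seed(as.integer(seed))
  bs <- array(NA_real_, c(2, length(thresholds), n_boot))
  for (b in seq_len(n_boot)) {
    k <- sample.int(n, n, replace = TRUE)
    bs[, , b] <- counts(predicted[k], outcome[k])
  }
  a <- (1 - conf) / 2
  data.frame(threshold = thresholds,
             n_high = est[1, ],
             n_high_lower = apply(bs[1, , , drop = FALSE], 2, quantile, a),
             n_high_upper = apply(bs[1, , , drop = FALSE], 2, quantile, 1 - a),
             n_high_event = est[2, ],
             n_high_event_lower = apply(bs[2, , , drop = FALSE], 2, quantile, a),
             n_high_event_upper = apply(bs[2, , , drop = FALSE], 2, quantile, 1 - a))
}

#' Calibration of predicted survival at a horizon
#'
#' Bins patients by model-predicted survival probability at the horizon
#' (quantile bins) and compares the per-bin mean prediction with the
#' Kaplan-Meier observed survival at the horizon.  Perfect calibration
#' lies on the identity line.  Bins emptied by heavy ties are merged with
#' a warning.
#'
#' @param predicted_survival predicted probability of being event-free at
#'   `horizon`, one per patient.
#' @param time,event survival endpoint.
#' @param horizon months (default 6), within follow-up.
#' @param bins number of quantile bins (>= 1).
#' @return data.frame: `bin`, `n`, `predicted`, `observed`.
#' @export
calibration <- function(predicted_survival, time, event, horizon = 6, bins = 5) {
  if (horizon > max(time)) stop_invalid("horizon lies beyond all follow-up")
  check_number(bins, "bins", lower = 1)
  if (bins == 1) {
    grp <- factor(rep(1L, length(time)))
  } else {
    br <- unique(quantile(predicted_survival, seq(0, 1, length.out = bins + 1)))
    if (length(br) - 1 < bins)
      warning("tied predictions: empty bins merged with neighbours")
    grp <- cut(predicted_survival, br, include.lowest = TRUE)
  }
  km_at <- function(sel) {
    f <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    s <- summary(f, times = horizon, extend = TRUE)
    s$surv
  }
  lv <- levels(grp)
  data.frame(bin = lv,
             n = as.integer(table(grp)),
             predicted = vapply(lv, function(g) mean(predicted_survival[grp == g]), numeric(1)),
             observed = vapply(lv, function(g) km_at(grp == g), numeric(1)),
             row.names = NULL)
}

#' Kruskal-Wallis balance check of demographics across strata
#'
#' Rank-based k-sample test of each demographic variable across the risk
#' strata; a constant variable gets p = 1 with a note.
#'
#' @param demographics data.frame of numeric (or ordinal-coded) variables.
#' @param strata factor with at least 2 levels present.
#' @return data.frame: `variable`, `statistic`, `p`, `note`.
#' @export
kruskal_wallis_balance <- function(demographics, strata) {
  strata <- droplevels(as.factor(strata))
  if (nlevels(strata) < 2L) stop_invalid("need at least 2 strata")
  rows <- lapply(colnames(demographics), function(v) {
    x <- demographics[[v]]
    if (length(unique(x[!is.na(x)])) < 2L)
      return(data.frame(variable = v, statistic = NA_real_, p = 1,
                        note = "constant variable"))
    kt <- kruskal.test(x, strata)
    data.frame(variable = v, statistic = unname(kt$statistic),
               p = unname(kt$p.value), note = "")
  })
  do.call(rbind, rows)
}

#' Map ordinal risk strata to horizon event probabilities
#'
#' Assigns every patient the Kaplan-Meier event probability of their
#' stratum at the horizon, turning a 3-level index into the probability
#' scale required by decision curves and IDI.
#'
#' @param strata factor of stratum labels.
#' @param time,event survival endpoint.
#' @param horizon months.
#' @return numeric vector of event probabilities, one per patient.
#' @export
stratum_event_probability <- function(strata, time, event, horizon = 6) {
  strata <- as.factor(strata)
  probs <- vapply(levels(strata), function(g) {
    sel <- strata == g
    if (!any(sel)) return(NA_real_)
    f <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    1 - summary(f, times = horizon, extend = TRUE)$surv
  }, numeric(1))
  unname(probs[as.integer(strata)])
}
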