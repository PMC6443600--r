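#' Configuration of a full pipeline run
#'
#' Bundles the per-stage configurations.  The single `seed` fans out to
#' per-stage seeds through [split_seed()] (stage names: "cohort",
#' "lasso", "boot"), so each stage is independently rerunnable and the
#' whole run is reproducible bit-for-bit.
#'
#' @param cohort a [cohort_config()]; its own `seed` field is overridden
#'   by `split_seed(seed, "cohort")`.
#' @param bank a [feature_bank_config()].
#' @param registry clinical cut-off registry.
#' @param horizon evaluation horizon in months for calibration, NRI/IDI
#'   and decision curves.
#' @param min_group_frac group-size floor of the cut-point search.
#' @param lambda_rule lambda selection rule for the LASSO ("1se"/"min").
#' @param n_boot_ci bootstrap draws for C-index confidence intervals.
#' @param n_boot_nri bootstrap draws for NRI/IDI p-values.
#' @param seed master integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), bank = feature_bank_config(),
                       registry = default_cutoff_registry(), horizon = 6,
                       min_group_frac = 0.1, lambda_rule = "1se",
                       n_boot_ci = 2000, n_boot_nri = 1000, seed = 1) {
  cohort$seed <- split_seed(seed, "cohort")
  structure(list(cohort = cohort, bank = bank, registry = registry,
                 horizon = horizon, min_group_frac = min_group_frac,
                 lambda_rule = lambda_rule, n_boot_ci = n_boot_ci,
                 n_boot_nri = n_boot_nri, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full prognostic-index pipeline
#'
#' Executes simulate -> extract -> signature -> stratify -> evaluate on a
#' synthetic cohort: generates images and endpoints, extracts the
#' 592-feature bank, screens features by univariate Cox and fits the
#' LASSO-Cox signature, dichotomises it at the maximally selected
#' log-rank cut-point, selects PIM indices by multivariable Cox over the
#' signature status and the significant clinical risk statuses, builds
#' the comparison stratifiers (clinical-factor model, Glasgow Prognostic
#' Score, signature-only, RECIST response), and evaluates all five models
#' on time to progression (C-index, NRI/IDI, decision and clinical-impact
#' curves, calibration, demographic balance) plus the PIM on overall
#' survival and the EGFR-TKI validation arm.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all tabular outputs and
#'   `report.json` are written there.
#' @return a `run_report` list with elements `cohort`, `features`,
#'   `screening`, `signature`, `cutpoint`, `scores`, `strata`, `pim`,
#'   `evaluation`, `os`, `tki`, `provenance`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) stop_invalid("`config` must be a run_config")

  cohort <- stage("simulate", generate_cohort(config$cohort))
  co <- cohort$cohort
  chemo <- co$arm == "chemo"

  features <- stage("extract", {
    if (is.null(cohort$phantoms))
      stop_invalid("pipeline requires images; set include_images = TRUE")
    extract_cohort_features(cohort, config$bank)
  })

  scr <- stage("signature", {
    usable <- apply(features[chemo, , drop = FALSE], 2,
                    function(x) all(is.finite(x)))
    univariate_screen(features[chemo, usable, drop = FALSE],
                      co$ttp_months[chemo], co$ttp_event[chemo])
  })
  kept <- scr$id[scr$kept]
  model <- stage("signature", {
    if (length(kept) < 2L)
      stop_invalid("fewer than 2 features pass univariate screening")
    fit1 <- function(...) fit_lasso_cox(features[chemo, kept, drop = FALSE],
                                        co$ttp_months[chemo], co$ttp_event[chemo],
                                        seed = split_seed(config$seed, "lasso"),
                                        ...)
    # small cohorts can leave the 1-SE model empty; fall back to the
    # cross-validation minimum, then to a near-unpenalised fit
    tryCatch(fit1(lambda_rule = config$lambda_rule),
             error = function(e1)
               tryCatch(fit1(lambda_rule = "min"),
                        error = function(e2) fit1(lambda = 1e-3)))
  })
  scores <- score_signature(model, features)
  cut <- stage("signature",
               find_optimal_cutpoint(scores[chemo], co$ttp_months[chemo],
                                     co$ttp_event[chemo],
                                     config$min_group_frac))
  model$cutoff <- cut$cutoff
  sig_group <- stratify_by_signature(scores, model$cutoff)

  strata <- stage("stratify", {
    cl <- co[clinical_variables()]
    status <- dichotomize_clinical(cl, config$registry)
    status$signature <- factor(ifelse(sig_group == "poor-TTP", "risk", "normal"),
                               levels = c("normal", "risk"))
    flags <- risk_flags(status[chemo, , drop = FALSE])
    usable <- vapply(flags, sd, numeric(1)) > 0
    uni <- univariate_screen(as.matrix(flags[, usable, drop = FALSE]),
                             co$ttp_months[chemo], co$ttp_event[chemo],
                             standardize = FALSE)
    clin_sig <- setdiff(uni$id[uni$kept], "signature")
    # at very small cohort sizes nothing may reach multivariable
    # significance; the index then degenerates to the signature status
    pim_sel <- tryCatch(
      select_pim_indices(status[chemo, c("signature", clin_sig), drop = FALSE],
                         co$ttp_months[chemo], co$ttp_event[chemo]),
      error = function(e) {
        warning("no independently significant index; PIM reduced to the signature status")
        list(indices = "signature", fit_table = NULL)
      })
    pim <- compute_pim(status, pim_sel$indices)
    clin_sel <- tryCatch(
      select_pim_indices(status[chemo, clin_sig, drop = FALSE],
                         co$ttp_months[chemo], co$ttp_event[chemo]),
      error = function(e) list(indices = clin_sig, fit_table = NULL))
    clinical_stratum <- if (length(clin_sel$indices) > 0)
      stratify_clinical_model(status[clin_sel$indices])
    else factor(rep("0", nrow(co)), levels = c("0", "1", ">=2"))
    gps <- compute_gps(co$crp, co$alb)
    response_group <- stratify_response(co$response)
    list(status = status, uni_clinical = uni, pim_selection = pim_sel,
         pim = pim, clinical_selection = clin_sel,
         clinical_stratum = clinical_stratum, gps = gps,
         response_group = response_group)
  })

  ev <- stage("evaluate", {
    tt <- co$ttp_months[chemo]; te <- co$ttp_event[chemo]
    h <- config$horizon
    bseed <- split_seed(config$seed, "boot")
    pim_sc <- strata$pim$pim_score[chemo]
    pim_st <- droplevels(strata$pim$pim_stratum[chemo])
    clin_st <- droplevels(strata$clinical_stratum[chemo])
    gps_c <- strata$gps[chemo]
    resp <- droplevels(strata$response_group[chemo])
    sig_sc <- scores[chemo]

    risk_prob <- list(
      pim = stratum_event_probability(pim_st, tt, te, h),
      clinical = stratum_event_probability(clin_st, tt, te, h),
      signature = stratum_event_probability(droplevels(sig_group[chemo]), tt, te, h),
      response = stratum_event_probability(resp, tt, te, h))

    cidx <- list(
      pim = c_index(pim_sc, tt, te, ci = TRUE, n_boot = config$n_boot_ci,
                    seed = bseed),
      clinical = c_index(as.integer(clin_st), tt, te, ci = TRUE,
                         n_boot = config$n_boot_ci, seed = bseed),
      signature = c_index(sig_sc, tt, te, ci = TRUE,
                          n_boot = config$n_boot_ci, seed = bseed),
      response = c_index(as.integer(resp), tt, te, ci = TRUE,
                         n_boot = config$n_boot_ci, seed = bseed))
    ok_gps <- !is.na(gps_c)
    cidx$gps <- if (sum(ok_gps) >= 10 && sum(te[ok_gps]) >= 2)
      c_index(gps_c[ok_gps], tt[ok_gps], te[ok_gps], ci = TRUE,
              n_boot = config$n_boot_ci, seed = bseed) else NULL

    safe_km <- function(g, t_, e_) tryCatch(km_logrank(g, t_, e_),
                                            error = function(e) NULL)
    km <- list(
      pim = safe_km(pim_st, tt, te),
      clinical = safe_km(clin_st, tt, te),
      signature = safe_km(sig_group[chemo], tt, te),
      response = safe_km(resp, tt, te))
    km$gps <- if (length(unique(gps_c[ok_gps])) >= 2)
      km_logrank(gps_c[ok_gps], tt[ok_gps], te[ok_gps]) else NULL

    reclass <- lapply(c(clinical = "clinical", signature = "signature",
                        response = "response"), function(m)
      nri_idi(risk_prob$pim, risk_prob[[m]], tt, te, horizon = h,
              n_boot = config$n_boot_nri, seed = bseed))

    dca <- lapply(risk_prob, function(p) net_benefit(p, as.integer(tt <= h & te == 1)))
    impact <- clinical_impact(risk_prob$pim, as.integer(tt <= h & te == 1),
                              n_boot = 500, seed = bseed)

    cox_pim <- survival::coxph(survival::Surv(tt, te) ~ pim_sc, ties = "efron")
    pred_surv <- vapply(seq_along(pim_sc), function(i) {
      sf <- survival::survfit(cox_pim, newdata = data.frame(pim_sc = pim_sc[i]))
      summary(sf, times = h, extend = TRUE)$surv
    }, numeric(1))
    calib <- suppressWarnings(calibration(pred_surv, tt, te, horizon = h, bins = 3))

    demo <- co[chemo, c("gender", "age", "ecog", "smoke_amount",
                        "smoke_status", "history_lung_cancer", "family_history")]
    balance <- kruskal_wallis_balance(demo, pim_st)

    list(c_index = cidx, km = km, nri_idi = reclass, net_benefit = dca,
         clinical_impact = impact, calibration = calib, balance = balance)
  })

  os <- stage("evaluate", {
    ot <- co$os_months[chemo]; oe <- co$os_event[chemo]
    pim_st <- droplevels(strata$pim$pim_stratum[chemo])
    low <- factor(ifelse(pim_st == "low", "low", "other"),
                  levels = c("low", "other"))
    list(km_strata = km_logrank(pim_st, ot, oe),
         km_low_vs_rest = km_logrank(low, ot, oe),
         c_index = c_index(strata$pim$pim_score[chemo], ot, oe, ci = TRUE,
                           n_boot = config$n_boot_ci,
                           seed = split_seed(config$seed, "boot")))
  })

  tki <- stage("evaluate",
               validate_on_tki(strata$pim$pim_stratum[chemo],
                               co$ttp_months[chemo], co$ttp_event[chemo],
                               co$ttp_months[!chemo], co$ttp_event[!chemo]))

  report <- list(cohort = cohort, features = features, screening = scr,
                 signature = model, cutpoint = cut, scores = scores,
                 strata = strata, evaluation = ev, os = os, tki = tki,
                 provenance = list(seed = config$seed,
                                   config_hash = config_hash(config),
                                   n_features = ncol(features),
                                   n_kept = length(kept)))
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, config, out_dir)
  report
}

#' Compare the EGFR-TKI arm with each PIM stratum
#'
#' Log-rank test and hazard ratio (TKI as reference) of the TKI
#' validation arm against the patients of each chemotherapy PIM stratum.
#'
#' @param pim_strata factor of PIM strata of the chemotherapy arm.
#' @param chemo_time,chemo_event chemotherapy-arm endpoint.
#' @param tki_time,tki_event TKI-arm endpoint (non-empty).
#' @return list of class `tki_validation`, one `survival_comparison`-like
#'   entry per stratum: `hr`, `lower`, `upper`, `logrank_p`, `n`.
#' @export
validate_on_tki <- function(pim_strata, chemo_time, chemo_event,
                            tki_time, tki_event) {
  if (length(tki_time) == 0L) stop_invalid("TKI arm is empty")
  out <- lapply(levels(droplevels(as.factor(pim_strata))), function(s) {
    sel <- pim_strata == s
    grp <- factor(rep(c("tki", "stratum"), c(length(tki_time), sum(sel))),
                  levels = c("tki", "stratum"))
    km <- km_logrank(grp, c(tki_time, chemo_time[sel]),
                     c(tki_event, chemo_event[sel]))
    list(stratum = s, n_stratum = sum(sel), n_tki = length(tki_time),
         hr = km$hr_table$hr[1], lower = km$hr_table$lower[1],
         upper = km$hr_table$upper[1], logrank_p = km$logrank_p,
         medians = km$medians)
  })
  names(out) <- levels(droplevels(as.factor(pim_strata)))
  class(out) <- "tki_validation"
  out
}

#' Stable hash of a configuration (or any serialisable object)
#' @param x object.
#' @return md5 string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

## flatten the machine-readable part of a run report for report.json
report_summary <- function(report, config) {
  ev <- report$evaluation
  ci_row <- function(ci) if (is.null(ci)) NULL else
    list(c_index = ci$c_index, lower = ci$lower, upper = ci$upper)
  list(
    provenance = report$provenance,
    cohort = list(n_chemo = sum(report$cohort$cohort$arm == "chemo"),
                  n_tki = sum(report$cohort$cohort$arm == "tki"),
                  response_counts = as.list(table(report$cohort$cohort$response))),
    signature = list(n_features = length(report$signature$feature_ids),
                     feature_ids = report$signature$feature_ids,
                     weights = report$signature$weights,
                     lambda = report$signature$lambda,
                     cutoff = report$signature$cutoff),
    pim = list(indices = report$strata$pim_selection$indices,
               fit_table = report$strata$pim_selection$fit_table,
               stratum_sizes = as.list(table(
                 report$strata$pim$pim_stratum[report$cohort$cohort$arm == "chemo"]))),
    ttp = list(
      c_index = lapply(ev$c_index, ci_row),
      medians = lapply(ev$km, function(k) if (is.null(k)) NULL else as.list(k$medians)),
      logrank_p = lapply(ev$km, function(k) if (is.null(k)) NULL else k$logrank_p),
      nri_idi = lapply(ev$nri_idi, function(x)
        list(nri = x$nri, idi = x$idi, nri_p = x$nri_p, idi_p = x$idi_p)),
      calibration = ev$calibration,
      balance = ev$balance),
    os = list(c_index = ci_row(report$os$c_index),
              medians = as.list(report$os$km_strata$medians),
              low_vs_rest_hr = report$os$km_low_vs_rest$hr_table$hr[1],
              low_vs_rest_p = report$os$km_low_vs_rest$logrank_p),
    tki = lapply(unclass(report$tki), function(x)
      list(stratum = x$stratum, hr = x$hr, lower = x$lower, upper = x$upper,
           logrank_p = x$logrank_p)))
}

#' Write a run report to disk
#'
#' Writes `report.json` (all headline statistics, stamped with the config
#' hash and seed), `cohort.csv`, `features.csv`, `scores.csv`,
#' `strata.csv` and the evaluation curves under `curves/`.
#'
#' @param report a `run_report`.
#' @param config the [run_config()] that produced it.
#' @param dir output directory.
#' @return invisibly, the path of `report.json`.
#' @export
write_run_report <- function(report, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- report$cohort$cohort
  write.csv(co, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(data.frame(id = rownames(report$features), report$features,
                       check.names = FALSE),
            file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(data.frame(id = co$id, score = report$scores,
                       group = stratify_by_signature(report$scores,
                                                     report$signature$cutoff)),
            file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(data.frame(id = co$id, arm = co$arm,
                       pim_score = report$strata$pim$pim_score,
                       pim_stratum = report$strata$pim$pim_stratum,
                       clinical_stratum = report$strata$clinical_stratum,
                       gps = report$strata$gps,
                       response = report$strata$response_group),
            file.path(dir, "strata.csv"), row.names = FALSE)
  write_signature_model(report$signature, file.path(dir, "signature_model.json"))
  dir.create(file.path(dir, "curves"), showWarnings = FALSE)
  for (m in names(report$evaluation$net_benefit))
    write.csv(report$evaluation$net_benefit[[m]],
              file.path(dir, "curves", paste0("net_benefit_", m, ".csv")),
              row.names = FALSE)
  write.csv(report$evaluation$clinical_impact,
            file.path(dir, "curves", "clinical_impact_pim.csv"), row.names = FALSE)
  write.csv(report$evaluation$calibration,
            file.path(dir, "curves", "calibration_pim.csv"), row.names = FALSE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report_summary(report, config), path,
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(path)
}
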