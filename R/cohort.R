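#' Configuration of a synthetic LSCC cohort
#'
#' Describes the study conditions the generator emulates: a chemotherapy
#' arm of 96 patients plus 14 EGFR-TKI validation patients; two tumour
#' texture classes whose latent heterogeneity drives the hazard of
#' progression together with AST risk status; Weibull baseline time to
#' progression with median 7.2 months in the reference group (latent
#' texture risk 0, normal AST); overall survival equal to TTP plus an
#' independent exponential post-progression survival; and administrative
#' censoring of OS at roughly a 20% rate.
#'
#' @param n_chemo chemotherapy-arm size (>= 2), default 96.
#' @param n_tki validation-arm size, default 14.
#' @param texture_classes list of two or more [texture_params()]; class 1 is
#'   the low-heterogeneity reference, later classes carry latent risk 1.
#' @param hazard_coefs list with `beta_signature` and `beta_ast`, the log
#'   hazard ratios of the latent texture risk and of abnormal AST.
#'   Defaults `log(2.45)` and `log(3.66)`.
#' @param baseline list with Weibull `shape` and `scale` (months) of the
#'   reference-group TTP.  Default shape 1, scale `7.2 / log(2)` so the
#'   reference median TTP is 7.2 months.
#' @param censor_rate_os fraction of OS records administratively censored,
#'   in `[0, 1)`; default 0.2 (19 or so of 96).
#' @param pps_mean mean (months) of the exponential post-progression
#'   survival added to TTP to form OS; default 8.
#' @param ast_risk_rate marginal probability of abnormal (risk) AST.
#' @param p_high_texture probability a tumour belongs to a non-reference
#'   texture class.
#' @param ttp_censor logical; also censor TTP administratively at the OS
#'   cut-off (the follow-up horizon).  Off by default: progression is
#'   fully observed, as when every progression is documented.
#' @param include_images generate tumour phantoms (slower); when `FALSE`
#'   only the clinical table, latent risks and endpoints are produced.
#' @param phantom_shape voxel triple for generated phantoms.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_chemo = 96, n_tki = 14,
                          texture_classes = list(
                            texture_params(correlation_length = 2, contrast = 1),
                            texture_params(correlation_length = 4, contrast = 2)),
                          hazard_coefs = list(beta_signature = log(2.45),
                                              beta_ast = log(3.66)),
                          baseline = list(shape = 1, scale = 7.2 / log(2)),
                          censor_rate_os = 0.2,
                          pps_mean = 8,
                          ast_risk_rate = 0.3,
                          p_high_texture = 0.5,
                          ttp_censor = FALSE,
                          include_images = TRUE,
                          phantom_shape = c(24, 24, 24),
                          seed = 1) {
  check_number(n_chemo, "n_chemo", lower = 2)
  check_number(n_tki, "n_tki", lower = 0)
  check_number(censor_rate_os, "censor_rate_os", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(baseline$shape, "baseline$shape", lower = 0, strict_lower = TRUE)
  check_number(baseline$scale, "baseline$scale", lower = 0, strict_lower = TRUE)
  check_number(pps_mean, "pps_mean", lower = 0, strict_lower = TRUE)
  if (length(texture_classes) < 1L)
    stop_invalid("`texture_classes` must contain at least one class")
  texture_classes <- lapply(texture_classes, function(p)
    if (inherits(p, "texture_params")) p else do.call(texture_params, p))
  structure(list(n_chemo = as.integer(n_chemo), n_tki = as.integer(n_tki),
                 texture_classes = texture_classes, hazard_coefs = hazard_coefs,
                 baseline = baseline, censor_rate_os = censor_rate_os,
                 pps_mean = pps_mean, ast_risk_rate = ast_risk_rate,
                 p_high_texture = p_high_texture, ttp_censor = ttp_censor,
                 include_images = include_images,
                 phantom_shape = as.integer(phantom_shape),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate TTP and OS endpoints under proportional hazards
#'
#' TTP is drawn from a Weibull proportional-hazards model with hazard
#' multiplier `exp(linpred)` on a Weibull baseline; OS is TTP plus an
#' independent exponential post-progression survival, then administratively
#' censored at the empirical `(1 - censor_rate_os)` quantile of OS so that
#' approximately `censor_rate_os` of the records are censored.  All times
#' are months and strictly positive.
#'
#' @param linpred numeric vector of per-patient linear predictors (log
#'   hazard ratios relative to baseline).
#' @param baseline list with Weibull `shape` and `scale` (months).
#' @param censor_rate_os target OS censoring fraction in `[0, 1)`.
#' @param seed integer seed.
#' @param pps_mean mean of the exponential post-progression survival.
#' @param ttp_censor also censor TTP at the same administrative cut-off.
#' @return data.frame with columns `ttp_months`, `ttp_event`, `os_months`,
#'   `os_event` (event indicator 1 = observed, 0 = censored).
#' @export
simulate_endpoints <- function(linpred, baseline, censor_rate_os = 0,
                               seed = 1, pps_mean = 8, ttp_censor = FALSE) {
  if (any(!is.finite(linpred))) stop_invalid("linear predictors must be finite")
  if (censor_rate_os >= 1 || censor_rate_os < 0)
    stop_invalid("`censor_rate_os` must lie in [0, 1)")
  n <- length(linpred)
  set.seed(as.integer(seed))
  u <- runif(n)
  # inverse survival of Weibull PH: S(t) = exp(-(t/scale)^shape * e^linpred)
  ttp <- baseline$scale * (-log(u) * exp(-linpred))^(1 / baseline$shape)
  pps <- rexp(n, rate = 1 / pps_mean)
  os <- ttp + pps
  ttp_event <- rep(1L, n)
  os_event <- rep(1L, n)
  if (censor_rate_os > 0 && n > 1) {
    tau <- as.numeric(quantile(os, 1 - censor_rate_os, type = 1))
    cens <- os > tau
    os[cens] <- tau
    os_event[cens] <- 0L
    if (ttp_censor) {
      tc <- ttp > tau
      ttp[tc] <- tau
      ttp_event[tc] <- 0L
    }
  }
  data.frame(ttp_months = ttp, ttp_event = ttp_event,
             os_months = os, os_event = os_event)
}

## The 24 clinical/blood variables with generating distributions.  Units:
## counts 10^9/L (wbc..plt as conventional), U/L for transaminases, g/L for
## hb/alb/fg/tp, umol/L tbil, ng/mL cea.  Margins roughly follow the
## demographics of a stage III-IV LSCC chemotherapy cohort (mostly male,
## mostly smokers, about 40% stage IV).
draw_clinical <- function(n) {
  data.frame(
    gender = rbinom(n, 1, 0.85),               # 1 = male
    age = round(rnorm(n, 58, 7)),
    ecog = ifelse(rbinom(n, 1, 0.58) == 1, 2L, sample(0:1, n, replace = TRUE)),
    smoke_amount = round(rlnorm(n, log(9600), 1)),
    smoke_status = rbinom(n, 1, 0.81),
    history_lung_cancer = rbinom(n, 1, 0.25),
    family_history = rbinom(n, 1, 0.115),
    wbc = rlnorm(n, log(7), 0.25),
    ne = rlnorm(n, log(4.5), 0.3),
    ly = rlnorm(n, log(1.8), 0.3),
    mono = rlnorm(n, log(0.45), 0.3),
    eo = rlnorm(n, log(0.15), 0.6),
    hb = rnorm(n, 135, 15),
    plt = rnorm(n, 250, 60),
    alt = rlnorm(n, log(25), 0.4),
    tbil = rlnorm(n, log(12), 0.35),
    alb = rnorm(n, 40, 4),
    ast = NA_real_,                            # filled from the risk flag
    fg = rlnorm(n, log(3.2), 0.25),
    tp = rnorm(n, 68, 5),
    cea = rlnorm(n, log(3), 0.7),
    t_stage = sample(1:4, n, replace = TRUE, prob = c(0.15, 0.3, 0.3, 0.25)),
    n_stage = sample(0:3, n, replace = TRUE, prob = c(0.2, 0.25, 0.35, 0.2)),
    m_stage = rbinom(n, 1, 0.43),
    # CRP is recorded for only part of the cohort (Glasgow Prognostic
    # Score analyses are restricted to patients with both records)
    crp = ifelse(runif(n) < 0.25, NA_real_, rlnorm(n, log(8), 0.8))
  )
}

#' The 24 clinical variable names of the cohort table
#' @return character vector of length 24.
#' @export
clinical_variables <- function() {
  c("gender", "age", "ecog", "smoke_amount", "smoke_status",
    "history_lung_cancer", "family_history", "wbc", "ne", "ly", "mono",
    "eo", "hb", "plt", "alt", "tbil", "alb", "ast", "fg", "tp", "cea",
    "t_stage", "n_stage", "m_stage")
}

#' Generate a synthetic cohort
#'
#' Draws `n_chemo + n_tki` patients.  Each chemotherapy patient carries a
#' latent texture risk (membership in a high-heterogeneity texture class)
#' and an AST risk flag; the TTP hazard multiplier is
#' `exp(beta_signature * latent + beta_ast * ast_flag)`.  TKI-arm patients
#' progress at the baseline (reference) hazard.  RECIST response for the
#' chemotherapy arm is obtained by rank-thresholding a noisy copy of the
#' linear predictor so that the marginal counts are approximately
#' PR 28% / SD 58% / PD 14% (27/56/13 at n = 96).  Demographics are drawn
#' independently of the hazard.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: a list with `cohort`
#'   (data.frame: id, arm, the 24 clinical variables, `latent_risk`,
#'   `ast_risk`, `texture_class`, endpoints, `response`), `phantoms`
#'   (named list of [generate_tumor_phantom()] outputs, or NULL), and the
#'   echoed `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop_invalid("`config` must be a cohort_config")
  if (length(config$texture_classes) == 0L)
    stop_invalid("`texture_classes` must not be empty")
  n <- config$n_chemo + config$n_tki
  arm <- rep(c("chemo", "tki"), c(config$n_chemo, config$n_tki))

  set.seed(split_seed(config$seed, "clinical"))
  cl <- draw_clinical(n)
  ast_risk <- rbinom(n, 1, config$ast_risk_rate)
  cl$ast <- ifelse(ast_risk == 1, runif(n, 42, 90), runif(n, 14, 40))

  k <- length(config$texture_classes)
  tex_class <- if (k == 1L) rep(1L, n) else
    ifelse(rbinom(n, 1, config$p_high_texture) == 1L,
           sample(2:k, n, replace = TRUE), 1L)
  latent <- as.integer(tex_class > 1L)

  linpred <- config$hazard_coefs$beta_signature * latent +
    config$hazard_coefs$beta_ast * ast_risk
  # the TKI arm progresses at the reference hazard
  linpred[arm == "tki"] <- 0

  surv <- simulate_endpoints(linpred, config$baseline, config$censor_rate_os,
                             seed = split_seed(config$seed, "endpoints"),
                             pps_mean = config$pps_mean,
                             ttp_censor = config$ttp_censor)

  # RECIST by rank-thresholding a noisy latent risk (chemo arm only)
  set.seed(split_seed(config$seed, "response"))
  response <- rep(NA_character_, n)
  ic <- which(arm == "chemo")
  noisy <- linpred[ic] + rnorm(length(ic), 0, 0.8)
  rk <- rank(noisy, ties.method = "first")
  n_pr <- round(length(ic) * 27 / 96)
  n_pd <- round(length(ic) * 13 / 96)
  response[ic] <- ifelse(rk <= n_pr, "PR",
                         ifelse(rk > length(ic) - n_pd, "PD", "SD"))

  cohort <- cbind(
    data.frame(id = sprintf("P%03d", seq_len(n)), arm = arm,
               stringsAsFactors = FALSE),
    cl,
    data.frame(texture_class = tex_class, latent_risk = latent,
               ast_risk = ast_risk),
    surv,
    data.frame(response = response, stringsAsFactors = FALSE))

  phantoms <- NULL
  if (config$include_images) {
    phantoms <- vector("list", n)
    names(phantoms) <- cohort$id
    for (i in seq_len(n)) {
      phantoms[[i]] <- generate_tumor_phantom(
        config$texture_classes[[tex_class[i]]],
        shape = config$phantom_shape,
        seed = split_seed(config$seed, paste0("phantom_", i)))
    }
  }

  structure(list(cohort = cohort, phantoms = phantoms, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d chemo + %d tki patients%s\n",
              sum(x$cohort$arm == "chemo"), sum(x$cohort$arm == "tki"),
              if (is.null(x$phantoms)) " (no images)" else
                sprintf(", phantoms %s", paste(dim(x$phantoms[[1]]$volume), collapse = "x"))))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.csv`, a `config.json` echo of the generating
#' configuration, and (when phantoms are present) one NIfTI volume and
#' mask per patient under `dir/images` and `dir/masks`.
#'
#' @param x a `synthetic_cohort`.
#' @param dir output directory, created if absent.
#' @return invisibly, the path of `cohort.csv`.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cohort.csv")
  write.csv(x$cohort, csv, row.names = FALSE)
  cfg <- x$config
  cfg$texture_classes <- lapply(cfg$texture_classes, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(x$phantoms)) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (id in names(x$phantoms))
      write_phantom_nifti(x$phantoms[[id]],
                          file.path(dir, "images", paste0(id, ".nii.gz")),
                          file.path(dir, "masks", paste0(id, ".nii.gz")))
  }
  invisible(csv)
}
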