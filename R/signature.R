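#' Univariate Cox screening of a feature table
#'
#' Fits one Cox proportional-hazards model per feature (Efron tie
#' handling) against the given endpoint and keeps features with Wald
#' p < `alpha`.  Features are z-scored before fitting unless
#' `standardize = FALSE`; constant features are excluded with reason
#' "degenerate", and features on which the fit fails to converge are
#' dropped with a warning.
#'
#' @param features numeric matrix, rows = patients, columns = features.
#' @param time,event survival endpoint (months, 1 = event).
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @param standardize z-score features before fitting.
#' @param fdr apply Benjamini-Hochberg correction before thresholding
#'   (off by default: raw p-values are screened).
#' @return data.frame of class `screening_result` with one row per
#'   feature: `id`, `beta`, `wald`, `p`, `kept`, `reason`.
#' @export
univariate_screen <- function(features, time, event, alpha = 0.05,
                              standardize = TRUE, fdr = FALSE) {
  if (nrow(features) < 10L) stop_invalid("screening needs at least 10 patients")
  if (sum(event) < 1L) stop_invalid("screening needs at least one event")
  ids <- colnames(features)
  y <- survival::Surv(time, event)
  res <- lapply(seq_along(ids), function(j) {
    x <- features[, j]
    if (!all(is.finite(x)) || sd(x) == 0)
      return(data.frame(id = ids[j], beta = NA_real_, wald = NA_real_,
                        p = NA_real_, kept = FALSE, reason = "degenerate"))
    if (standardize) x <- (x - mean(x)) / sd(x)
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        # refit quietly; flag non-convergence below via the fit itself
        suppressWarnings(survival::coxph(y ~ x, ties = "efron"))
      })
    if (is.null(fit) || !is.finite(coef(fit)) || !is.finite(sqrt(fit$var[1, 1]))) {
      warning(sprintf("feature %s dropped: Cox fit did not converge", ids[j]))
      return(data.frame(id = ids[j], beta = NA_real_, wald = NA_real_,
                        p = NA_real_, kept = FALSE, reason = "nonconvergence"))
    }
    z <- coef(fit) / sqrt(fit$var[1, 1])
    data.frame(id = ids[j], beta = unname(coef(fit)), wald = unname(z^2),
               p = unname(2 * pnorm(-abs(z))), kept = NA, reason = "")
  })
  out <- do.call(rbind, res)
  p_eff <- if (fdr) stats::p.adjust(out$p, "BH") else out$p
  out$kept <- !is.na(p_eff) & p_eff < alpha
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Fit a LASSO-Cox prognostic signature
#'
#' L1-penalised Cox regression over the screened features; lambda is
#' chosen by cross-validated partial likelihood (the 1-SE rule by
#' default), with fold assignment derived from `seed` so the fit is
#' deterministic.  Features are z-scored internally; the returned model
#' stores the centring/scaling so scores are computed from raw feature
#' values.
#'
#' @param features numeric matrix (rows = patients) of the kept features.
#' @param time,event survival endpoint.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed lambda, bypassing cross-validation.
#' @param cutoff optional dichotomising cut-off to store in the model.
#' @return an object of class `signature_model`: `feature_ids`, `weights`
#'   (on the z-scored scale), `center`, `scale`, `cutoff`, `lambda`,
#'   `lambda_trace` (cross-validation curve), `reference_flag = FALSE`.
#' @export
fit_lasso_cox <- function(features, time, event, lambda_rule = c("1se", "min"),
                          cv_folds = 10, seed = 1, lambda = NULL,
                          cutoff = NA_real_) {
  lambda_rule <- match.arg(lambda_rule)
  if (ncol(features) < 2L) stop_invalid("LASSO needs at least 2 features")
  if (sum(event) < 2L) stop_invalid("LASSO needs at least 2 events")
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  if (any(scl == 0)) stop_invalid("constant feature passed to LASSO; screen first")
  x <- scale(features, ctr, scl)
  y <- survival::Surv(time, event)
  trace <- NULL
  if (is.null(lambda)) {
    set.seed(as.integer(seed))
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            standardize = FALSE)
    lambda <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
    trace <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
  }
  # for a user-fixed lambda, extend the path down to it so small penalties
  # are fitted exactly rather than extrapolated
  path <- if (is.null(trace) && lambda < 0.05)
    exp(seq(log(1), log(lambda), length.out = 100)) else NULL
  fit <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE,
                        lambda = path, thresh = 1e-11)
  w <- as.numeric(predict(fit, s = lambda, type = "coefficients"))
  nz <- which(w != 0)
  if (length(nz) == 0L)
    stop_invalid("all coefficients are zero at lambda = %g; use a smaller lambda",
                 lambda)
  structure(list(feature_ids = colnames(features)[nz], weights = w[nz],
                 center = ctr[nz], scale = scl[nz], cutoff = cutoff,
                 lambda = lambda, lambda_trace = trace,
                 reference_flag = FALSE),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model>%s %d features, cutoff %s\n",
              if (isTRUE(x$reference_flag)) " [reference]" else "",
              length(x$feature_ids),
              if (is.na(x$cutoff)) "unset" else format(x$cutoff)))
  print(setNames(x$weights, x$feature_ids))
  invisible(x)
}

#' Score patients with a signature model
#'
#' The score is the linear combination `sum_j w_j * f_j` (no intercept),
#' where `f_j` is the feature value after the model's stored centring and
#' scaling (identity for the reference model).
#'
#' @param model a `signature_model`.
#' @param features named numeric vector, or matrix with feature columns.
#' @return numeric score(s).
#' @export
score_signature <- function(model, features) {
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1, dimnames = list(NULL, names(features)))
  missing <- setdiff(model$feature_ids, colnames(features))
  if (length(missing) > 0)
    stop_invalid("missing feature(s) in input: %s", paste(missing, collapse = ", "))
  x <- features[, model$feature_ids, drop = FALSE]
  x <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  as.numeric(x %*% model$weights)
}

#' Maximally selected log-rank cut-point (X-tile style)
#'
#' Scans every midpoint between consecutive distinct order statistics of
#' the scores, subject to a minimum group-size floor, and returns the
#' cut-point maximising the two-group log-rank chi-square statistic.  Ties
#' in the statistic are broken toward the more balanced split.  The naive
#' log-rank p-value at the selected cut-point is anti-conservative because
#' the cut-point is chosen to maximise the statistic; it is reported as
#' `naive_p` without correction.
#'
#' @param scores numeric vector with at least 2 distinct values.
#' @param time,event survival endpoint.
#' @param min_group_frac minimum fraction of patients in either group,
#'   in `(0, 0.5)`; default 0.1.
#' @return list of class `cutpoint_result`: `cutoff`, `statistic`,
#'   `naive_p`, `group_sizes`, `trace` (candidate, statistic pairs).
#' @export
find_optimal_cutpoint <- function(scores, time, event, min_group_frac = 0.1) {
  if (length(unique(scores)) < 2L) stop_invalid("all scores are equal")
  if (min_group_frac <= 0 || min_group_frac >= 0.5)
    stop_invalid("`min_group_frac` must lie in (0, 0.5)")
  n <- length(scores)
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  sizes <- vapply(cand, function(cc) sum(scores <= cc), numeric(1))
  floor_n <- min_group_frac * n
  ok <- sizes >= floor_n & (n - sizes) >= floor_n
  if (!any(ok)) stop_invalid("no admissible split under the group-size floor")
  cand <- cand[ok]; sizes <- sizes[ok]
  stat <- vapply(cand, function(cc)
    logrank_chisq(scores > cc, time, event), numeric(1))
  # argmax; ties toward the more balanced split
  best <- which(stat == max(stat))
  if (length(best) > 1L) best <- best[which.min(abs(sizes[best] - n / 2))]
  cutoff <- cand[best]
  structure(list(cutoff = cutoff, statistic = stat[best],
                 naive_p = stats::pchisq(stat[best], df = 1, lower.tail = FALSE),
                 group_sizes = c(low = sizes[best], high = n - sizes[best]),
                 trace = data.frame(candidate = cand, statistic = stat)),
            class = "cutpoint_result")
}

## two-group log-rank chi-square, computed from the defining
## observed-minus-expected sums (Mantel-Haenszel form)
logrank_chisq <- function(group2, time, event) {
  dt <- sort(unique(time[event == 1]))
  at_risk <- outer(time, dt, ">=")
  n_tot <- colSums(at_risk)
  n_2 <- colSums(at_risk & group2)
  d_tot <- colSums(outer(time, dt, "==") & event == 1)
  d_2 <- colSums(outer(time, dt, "==") & event == 1 & group2)
  e_2 <- d_2 - d_tot * n_2 / n_tot
  v_2 <- d_tot * (n_2 / n_tot) * (1 - n_2 / n_tot) *
    (n_tot - d_tot) / pmax(n_tot - 1, 1)
  O_E <- sum(e_2)
  V <- sum(v_2)
  if (V <= 0) return(0)
  O_E^2 / V
}

#' Dichotomise signature scores into TTP risk groups
#'
#' Scores at or below the cut-off form the good-TTP group; higher scores
#' indicate faster progression and form the poor-TTP group.
#'
#' @param scores numeric vector of signature scores.
#' @param cutoff dichotomising cut-off.
#' @return factor with levels `good-TTP`, `poor-TTP`.
#' @export
stratify_by_signature <- function(scores, cutoff) {
  if (any(!is.finite(scores))) stop_invalid("scores must be finite")
  factor(ifelse(scores <= cutoff, "good-TTP", "poor-TTP"),
         levels = c("good-TTP", "poor-TTP"))
}

#' The published reference signature
#'
#' Loads the frozen eight-feature signature (cluster shade of
#' co-occurrence, first-order variance, low gray-level run emphasis, and
#' five Gabor response terms) with its published weights and
#' dichotomising cut-off of -1.117, shipped as
#' `inst/extdata/reference_model.json`.  This model scores raw feature
#' values directly (no centring/scaling); it is clearly separated from
#' models re-fit on synthetic cohorts by `reference_flag = TRUE`.  Note
#' that the published feature parameter indices are not recoverable, so
#' the reference model cannot be applied to this package's feature bank
#' ids; it is provided for scoring externally supplied values of the
#' named features.
#'
#' @return a `signature_model` with `reference_flag = TRUE`.
#' @export
reference_signature <- function() {
  path <- system.file("extdata", "reference_model.json", package = "lsccpim")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_ids = j$feature_ids, weights = j$weights,
                 center = rep(0, length(j$weights)),
                 scale = rep(1, length(j$weights)),
                 cutoff = j$cutoff, lambda = NA_real_, lambda_trace = NULL,
                 reference_flag = TRUE),
            class = "signature_model")
}

#' Serialise / load a signature model
#' @param model a `signature_model`.
#' @param path JSON file path.
#' @return `write_signature_model` returns the path invisibly;
#'   `read_signature_model` returns the model.
#' @export
write_signature_model <- function(model, path) {
  jsonlite::write_json(
    list(feature_ids = model$feature_ids, weights = model$weights,
         center = model$center, scale = model$scale, cutoff = model$cutoff,
         lambda = model$lambda, reference_flag = model$reference_flag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_ids = j$feature_ids, weights = j$weights,
                 center = j$center, scale = j$scale, cutoff = j$cutoff,
                 lambda = j$lambda, lambda_trace = NULL,
                 reference_flag = isTRUE(j$reference_flag)),
            class = "signature_model")
}
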