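#' Default clinical cut-off registry
#'
#' Maps each of the 24 clinical/blood variables to a dichotomising rule
#' `(threshold, direction)`: a patient is at *risk* when the value
#' strictly exceeds the threshold (`direction = "gt"`) or falls strictly
#' below it (`"lt"`); boundary values resolve to normal.  The smoking
#' cut-off (9,600 cigarettes, the cohort median) is anchored; the
#' remaining thresholds are conventional reference limits and are meant
#' to be overridden where local practice differs.
#'
#' @return data.frame with columns `variable`, `threshold`, `direction`,
#'   `source`.
#' @export
default_cutoff_registry <- function() {
  reg <- rbind(
    c("gender", 0, "gt", "male coded as the non-reference status"),
    c("age", 65, "gt", "conventional elderly threshold"),
    c("ecog", 1, "gt", "performance status 2 vs 0-1"),
    c("smoke_amount", 9600, "gt", "cohort median lifetime cigarettes"),
    c("smoke_status", 0, "gt", "ever-smoker"),
    c("history_lung_cancer", 0, "gt", "any history"),
    c("family_history", 0, "gt", "any family history"),
    c("wbc", 9.5, "gt", "upper reference limit, 10^9/L"),
    c("ne", 6.3, "gt", "upper reference limit, 10^9/L"),
    c("ly", 1.1, "lt", "lower reference limit, 10^9/L"),
    c("mono", 0.6, "gt", "upper reference limit, 10^9/L"),
    c("eo", 0.52, "gt", "upper reference limit, 10^9/L"),
    c("hb", 115, "lt", "lower reference limit, g/L"),
    c("plt", 350, "gt", "upper reference limit, 10^9/L"),
    c("alt", 40, "gt", "upper reference limit, U/L"),
    c("tbil", 21, "gt", "upper reference limit, umol/L"),
    c("alb", 35, "lt", "lower reference limit, g/L"),
    c("ast", 40, "gt", "upper reference limit, U/L"),
    c("fg", 4, "gt", "upper reference limit, g/L"),
    c("tp", 60, "lt", "lower reference limit, g/L"),
    c("cea", 5, "gt", "upper reference limit, ng/mL"),
    c("t_stage", 2, "gt", "T3-T4 vs T1-T2"),
    c("n_stage", 1, "gt", "N2-N3 vs N0-N1"),
    c("m_stage", 0, "gt", "any distant metastasis"))
  data.frame(variable = reg[, 1], threshold = as.numeric(reg[, 2]),
             direction = reg[, 3], source = reg[, 4],
             stringsAsFactors = FALSE)
}

#' Dichotomise clinical variables into normal/risk status
#'
#' Risk requires strict exceedance of the registered threshold in the
#' registered direction; values exactly at the threshold are normal.
#'
#' @param clinical data.frame of clinical variables (columns must all be
#'   covered by the registry).
#' @param registry cut-off registry as from [default_cutoff_registry()].
#' @return data.frame of the same shape with factor columns
#'   (`normal`/`risk`), of class `risk_status_table`, with the registry
#'   attached as attribute `registry`.
#' @export
dichotomize_clinical <- function(clinical, registry = default_cutoff_registry()) {
  missing <- setdiff(colnames(clinical), registry$variable)
  if (length(missing) > 0)
    stop_invalid("no registry entry for variable(s): %s",
                 paste(missing, collapse = ", "))
  out <- lapply(colnames(clinical), function(v) {
    e <- registry[registry$variable == v, ]
    x <- clinical[[v]]
    risk <- if (e$direction == "gt") x > e$threshold else x < e$threshold
    factor(ifelse(risk, "risk", "normal"), levels = c("normal", "risk"))
  })
  out <- as.data.frame(setNames(out, colnames(clinical)))
  attr(out, "registry") <- registry
  class(out) <- c("risk_status_table", "data.frame")
  out
}

risk_flags <- function(status) {
  one <- function(x)
    if (is.factor(x) || is.character(x)) as.integer(x == "risk") else as.integer(x)
  if (is.data.frame(status)) as.data.frame(lapply(status, one)) else one(status)
}

#' Select prognostic-index components by multivariable Cox regression
#'
#' Fits a multivariable Cox model on the candidate risk statuses (each a
#' binary normal/risk indicator that passed univariate screening) and
#' keeps the independently significant ones (Wald p < `alpha`) as PIM
#' indices.  Perfectly collinear candidates are detected and dropped with
#' a warning before fitting.
#'
#' @param statuses data.frame (or matrix) of candidate statuses, factor
#'   `normal`/`risk` or binary 0/1, one column per candidate.
#' @param time,event survival endpoint.
#' @param alpha significance level (default 0.05).
#' @return list of class `pim_index_selection`: `indices` (selected
#'   column names), `fit_table` (per-candidate HR, CI, beta, p).
#' @export
select_pim_indices <- function(statuses, time, event, alpha = 0.05) {
  x <- as.data.frame(lapply(as.data.frame(statuses), function(col)
    if (is.factor(col) || is.character(col)) as.integer(col == "risk") else as.numeric(col)))
  keep <- colnames(x)
  # drop exact duplicates / constants before the joint fit
  for (v in colnames(x)) {
    if (!(v %in% keep)) next
    if (sd(x[[v]]) == 0) {
      warning(sprintf("candidate %s is constant; dropped", v))
      keep <- setdiff(keep, v)
      next
    }
    dup <- keep[keep != v][vapply(keep[keep != v], function(w)
      isTRUE(all.equal(x[[v]], x[[w]])) ||
        (sd(x[[w]]) > 0 && abs(cor(x[[v]], x[[w]])) > 0.999), logical(1))]
    if (length(dup) > 0) {
      warning(sprintf("candidate(s) %s collinear with %s; retained %s only",
                      paste(dup, collapse = ", "), v, v))
      keep <- setdiff(keep, dup)
    }
  }
  if (length(keep) == 0L) stop_invalid("no usable candidate index")
  x <- x[keep]
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = x,
                         ties = "efron")
  sm <- summary(fit)
  tab <- data.frame(variable = keep,
                    hr = unname(sm$conf.int[, "exp(coef)"]),
                    lower = unname(sm$conf.int[, 3]),
                    upper = unname(sm$conf.int[, 4]),
                    beta = unname(coef(fit)),
                    p = unname(sm$coefficients[, "Pr(>|z|)"]))
  indices <- tab$variable[is.finite(tab$p) & tab$p < alpha]
  if (length(indices) == 0L)
    stop_invalid("no candidate is independently significant; the prognostic index is undefined")
  structure(list(indices = indices, fit_table = tab),
            class = "pim_index_selection")
}

#' Compute the risk-count prognostic index (PIM)
#'
#' The PIM score of a patient is the number of selected indices at risk
#' status; the stratum is `low` for score 0, `intermediate` for 1 and
#' `high` for 2 or more.
#'
#' @param statuses `risk_status_table` (or data.frame of
#'   `normal`/`risk` factors or 0/1 flags) covering all `indices`.
#' @param indices character vector of index column names.
#' @return data.frame of class `pim_model` with columns `pim_score`
#'   (integer) and `pim_stratum` (factor low/intermediate/high).
#' @export
compute_pim <- function(statuses, indices) {
  statuses <- as.data.frame(statuses)
  missing <- setdiff(indices, colnames(statuses))
  if (length(missing) > 0)
    stop_invalid("missing status for index(es): %s", paste(missing, collapse = ", "))
  flags <- risk_flags(statuses[indices])
  if (any(is.na(flags))) stop_invalid("missing status value")
  score <- as.integer(rowSums(flags))
  out <- data.frame(pim_score = score,
                    pim_stratum = pim_stratum(score))
  class(out) <- c("pim_model", "data.frame")
  out
}

#' @rdname compute_pim
#' @param score integer risk-count score(s).
#' @export
pim_stratum <- function(score) {
  factor(ifelse(score == 0, "low", ifelse(score == 1, "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' Glasgow Prognostic Score
#'
#' GPS 2 = C-reactive protein above 10 mg/L *and* albumin below 35 g/L;
#' GPS 0 = neither abnormality; GPS 1 otherwise (the original, unmodified
#' score).  Patients missing either measurement get `NA` and are excluded
#' from GPS-based analyses.
#'
#' @param crp C-reactive protein, mg/L.
#' @param albumin albumin, g/L.
#' @return integer vector with values 0, 1, 2 or `NA`.
#' @export
compute_gps <- function(crp, albumin) {
  as.integer((crp > 10) + (albumin < 35))
}

#' Stratify by the clinical-factor model
#'
#' Counts how many of the supplied clinical risk indices are at risk and
#' maps the count to the strata `0`, `1`, `>=2`, mirroring the risk-count
#' rule of the PIM with clinical indices only.
#'
#' @param statuses data.frame of `normal`/`risk` (or 0/1) columns for the
#'   clinical indices (e.g. AST and CEA).
#' @return factor with levels `0`, `1`, `>=2`.
#' @export
stratify_clinical_model <- function(statuses) {
  flags <- risk_flags(as.data.frame(statuses))
  if (any(is.na(flags))) stop_invalid("missing status value")
  n <- rowSums(flags)
  factor(ifelse(n == 0, "0", ifelse(n == 1, "1", ">=2")),
         levels = c("0", "1", ">=2"))
}

#' Group patients by RECIST tumour response
#'
#' @param response character vector with values among CR, PR, SD, PD
#'   (a CR group is allowed but may be empty).
#' @return factor with levels CR, PR, SD, PD.
#' @export
stratify_response <- function(response) {
  bad <- setdiff(unique(response[!is.na(response)]), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0)
    stop_invalid("unknown RECIST label(s): %s", paste(bad, collapse = ", "))
  factor(response, levels = c("CR", "PR", "SD", "PD"))
}
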