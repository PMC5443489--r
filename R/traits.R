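#' Insulin resistance index (HOMA-IR)
#'
#' Homeostasis-model assessment of insulin resistance:
#' `Ins0 (uU/mL) * Glu0 (mg/dL) / 405`. The 405 constant is the standard
#' mg/dL form of the index.
#'
#' @param Ins0 fasting insulin, uU/mL (> 0).
#' @param Glu0 fasting glucose, mg/dL (> 0).
#' @return numeric vector, dimensionless.
#' @examples
#' homa_ir(8.1, 100)  # 2
#' @export
homa_ir <- function(Ins0, Glu0) {
  if (any(Ins0 <= 0, na.rm = TRUE) || any(Glu0 <= 0, na.rm = TRUE))
    abort_fmt("Ins0 and Glu0 must be strictly positive")
  Ins0 * Glu0 / 405
}

#' Insulin sensitivity index (QUICKI)
#'
#' Quantitative insulin sensitivity check index:
#' `1 / (log10(Ins0) + log10(Glu0))`, base-10 logarithms (the index's
#' standard definition).
#'
#' @inheritParams homa_ir
#' @return numeric vector, dimensionless.
#' @examples
#' quicki(10, 100)  # 1/3
#' @export
quicki <- function(Ins0, Glu0) {
  if (any(Ins0 <= 0, na.rm = TRUE) || any(Glu0 <= 0, na.rm = TRUE))
    abort_fmt("Ins0 and Glu0 must be strictly positive")
  denom <- log10(Ins0) + log10(Glu0)
  if (any(denom == 0, na.rm = TRUE))
    abort_fmt("degenerate QUICKI denominator: log10(Ins0) + log10(Glu0) = 0")
  1 / denom
}

#' Classify subjects by 60-minute OGTT glucose excursion
#'
#' The high-glucose-response (hiGlu60) design splits subjects on the delta
#' between the 60-minute and fasting glucose of an oral glucose tolerance
#' test: a delta below 20 mg/dL marks a control (flat responder), above
#' 100 mg/dL a case (high responder); the middle band is excluded.
#'
#' @param Glu0 fasting glucose, mg/dL.
#' @param Glu60 60-minute OGTT glucose, mg/dL.
#' @return character vector: `"control"`, `"case"`, or `"excluded"`.
#' @examples
#' classify_hiGlu60(84, 102)   # delta 18 -> control
#' classify_hiGlu60(90, 204)   # delta 114 -> case
#' @export
classify_hiGlu60 <- function(Glu0, Glu60) {
  delta <- Glu60 - Glu0
  ifelse(delta < 20, "control", ifelse(delta > 100, "case", "excluded"))
}

#' Classify subjects as diabetic for the replication cohort
#'
#' Replication inclusion rule for diabetic cases: fasting glucose above
#' 126 mg/dL and 120-minute OGTT glucose above 200 mg/dL (both strict).
#'
#' @param Glu0 fasting glucose, mg/dL.
#' @param Glu120 120-minute OGTT glucose, mg/dL.
#' @return character vector: `"case"` or `"non_case"`.
#' @export
classify_t2d_replication <- function(Glu0, Glu120) {
  ifelse(Glu0 > 126 & Glu120 > 200, "case", "non_case")
}

#' Welch's two-sample t-test from group summaries
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, computed from printed group summaries (mean, SD, n per group).
#' This is the form needed to re-check published tables that report only
#' mean +/- SD. Algebraically identical to [welch_t()] on raw data with
#' matching summaries.
#'
#' @param mean_a,sd_a,n_a first group's mean, SD, size.
#' @param mean_b,sd_b,n_b second group's mean, SD, size.
#' @return list with `t`, `df`, `p` (two-sided), and `degenerate` (TRUE
#'   when both SDs are zero; `t` is then 0 or +/-Inf and `p` 1 or 0).
#' @export
welch_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    t <- if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
    return(list(t = t, df = n_a + n_b - 2,
                p = if (mean_a == mean_b) 1 else 0, degenerate = TRUE))
  }
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Welch's two-sample t-test from raw vectors
#'
#' @param raw_a,raw_b numeric vectors (n >= 2 each; NAs dropped).
#' @return list with `t`, `df`, `p`, `degenerate` as in
#'   [welch_t_from_summary()].
#' @export
welch_t <- function(raw_a, raw_b) {
  raw_a <- raw_a[!is.na(raw_a)]
  raw_b <- raw_b[!is.na(raw_b)]
  welch_t_from_summary(mean(raw_a), stats::sd(raw_a), length(raw_a),
                       mean(raw_b), stats::sd(raw_b), length(raw_b))
}

#' Covariate-adjusted association of a trait with target-CpG methylation
#'
#' Ordinary least squares of a clinical trait on the target-site
#' methylation plus covariates (age, sex, BMI, WBC, RBC by default —
#' sex as a single indicator with "female" as the reference level).
#' Returns the methylation coefficient (trait units per percentage point
#' of methylation) and its two-sided p-value. When the analysed trait is
#' itself a covariate (e.g. BMI), it is removed from the covariate set.
#'
#' @param traits data.frame with `methylation_target` plus the trait and
#'   covariate columns.
#' @param trait_name response column name.
#' @param covariates character vector of covariate column names.
#' @return list with `coefficient`, `p`, `n` (complete cases used), and
#'   `fit` (the underlying `lm` object).
#' @export
trait_regression <- function(traits, trait_name,
                             covariates = c("age", "sex", "BMI", "WBC", "RBC")) {
  stopifnot("methylation_target" %in% names(traits),
            trait_name %in% names(traits))
  covariates <- setdiff(covariates, trait_name)
  missing_cov <- setdiff(covariates, names(traits))
  if (length(missing_cov))
    abort_fmt("covariate column(s) absent: %s", paste(missing_cov, collapse = ", "))
  cols <- c(trait_name, "methylation_target", covariates)
  d <- traits[stats::complete.cases(traits[, cols, drop = FALSE]), cols,
              drop = FALSE]
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("female", "male"))
  p_terms <- length(covariates) + 1L
  if (nrow(d) < p_terms + 2L)
    abort_fmt("need at least %d complete cases, have %d", p_terms + 2L, nrow(d))
  rhs <- paste(c("methylation_target", covariates), collapse = " + ")
  fit <- stats::lm(stats::reformulate(c("methylation_target", covariates),
                                      response = trait_name), data = d)
  cf <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_fmt("collinear design: column(s) %s dropped by lm",
              paste(bad, collapse = ", "))
  }
  list(coefficient = cf["methylation_target", "Estimate"],
       p = cf["methylation_target", "Pr(>|t|)"],
       n = nrow(d), fit = fit)
}

#' Trait association table across several traits
#'
#' Convenience wrapper running [trait_regression()] for each trait and
#' assembling a coefficient/p table (the shape of a published
#' multi-trait association table).
#'
#' @inheritParams trait_regression
#' @param trait_names character vector of response columns.
#' @return data.frame: `trait`, `coefficient`, `p`, `n`.
#' @export
trait_association_table <- function(traits, trait_names,
                                    covariates = c("age", "sex", "BMI",
                                                   "WBC", "RBC")) {
  do.call(rbind, lapply(trait_names, function(tr) {
    r <- trait_regression(traits, tr, covariates)
    data.frame(trait = tr, coefficient = r$coefficient, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  }))
}
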