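#' Configuration for the clinical trait-table simulator
#'
#' Describes a case/control cohort of clinical variables (glucose at 0/60/
#' 120 min of an oral glucose tolerance test, fasting insulin, HbA1c, BMI,
#' blood counts) with an optional linear dependence of each trait on the
#' methylation level of a target CpG. Default per-arm means and standard
#' deviations are chosen to resemble a middle-aged replication cohort with
#' non-diabetic controls and diabetic cases.
#'
#' @param n_per_arm subjects per arm.
#' @param trait_params named list: for each trait, a list with `control`
#'   and `case` entries, each `c(mean, sd)`. Defaults cover Glu0, Glu60,
#'   Glu120, Ins0, HbA1c, BMI, WBC, RBC in their usual clinical units
#'   (mg/dL, uU/mL, percent, kg/m2, 10^3/uL, 10^6/uL).
#' @param methylation_trait_slope named numeric vector: change in each trait
#'   per percentage point of target-CpG methylation (traits absent from the
#'   vector get slope 0).
#' @param seed master integer seed.
#' @return an object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_per_arm = 220L,
                             trait_params = NULL,
                             methylation_trait_slope = numeric(0),
                             seed = 1L) {
  if (n_per_arm < 1) abort_fmt("n_per_arm must be positive")
  if (is.null(trait_params)) {
    trait_params <- list(
      Glu0   = list(control = c(92, 7.6),  case = c(165, 54)),
      Glu60  = list(control = c(140, 25),  case = c(280, 60)),
      Glu120 = list(control = c(115, 25),  case = c(260, 50)),
      Ins0   = list(control = c(8.3, 3.4), case = c(16.7, 12)),
      HbA1c  = list(control = c(5.4, 0.46), case = c(7.6, 1.3)),
      BMI    = list(control = c(23.8, 3.0), case = c(25.6, 3.0)),
      WBC    = list(control = c(6.3, 1.6),  case = c(6.9, 1.8)),
      RBC    = list(control = c(4.6, 0.45), case = c(4.7, 0.45)))
  }
  structure(list(n_per_arm = as.integer(n_per_arm),
                 trait_params = trait_params,
                 methylation_trait_slope = methylation_trait_slope,
                 seed = as.integer(seed)),
            class = "trait_sim_config")
}

#' Simulate a clinical trait table linked to target-CpG methylation
#'
#' Draws per-subject traits from arm-specific normal distributions and adds
#' the configured linear methylation effect, centred on the cohort mean
#' methylation so the configured arm means are preserved. Strictly positive
#' traits (Glu0, Glu60, Glu120, Ins0) are redrawn when a draw falls at or
#' below zero (up to 100 attempts per subject, then clamped to a small
#' positive floor with a warning) so that HOMA-IR and QUICKI stay defined.
#'
#' @param config a [trait_sim_config()].
#' @param methylation numeric vector, percent methylation (0-100) at the
#'   target CpG, one value per subject (length `2 * n_per_arm`, controls
#'   first), or `NULL` to draw methylation internally around 29 (controls)
#'   and 26 (cases) with sd 3.5 — the blood-methylation contrast scale seen
#'   for a T2D-associated CpG.
#' @return data.frame with columns `subject_id`, `arm`, `age`, `sex`, one
#'   column per configured trait, and `methylation_target` (percent).
#' @export
simulate_traits <- function(config, methylation = NULL) {
  stopifnot(inherits(config, "trait_sim_config"))
  n <- config$n_per_arm
  arm <- rep(c("control", "case"), each = n)
  n_tot <- 2L * n

  set.seed(substream_seed(config$seed, "meth"))
  if (is.null(methylation)) {
    methylation <- c(stats::rnorm(n, 29, 3.5), stats::rnorm(n, 26, 3.5))
    methylation <- clip01(methylation, 0, 100)
  }
  if (length(methylation) != n_tot)
    abort_fmt("methylation vector must have length %d (got %d)",
              n_tot, length(methylation))

  set.seed(substream_seed(config$seed, "demog"))
  age <- round(stats::rnorm(n_tot, 60, 9))
  sex <- rep(rep(c("male", "female"), length.out = n), 2L)

  positive_traits <- c("Glu0", "Glu60", "Glu120", "Ins0")
  meth_centered <- methylation - mean(methylation)
  out <- data.frame(subject_id = sprintf("subj_%04d", seq_len(n_tot)),
                    arm = arm, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  for (trait in names(config$trait_params)) {
    p <- config$trait_params[[trait]]
    mean_v <- ifelse(arm == "case", p$case[1], p$control[1])
    sd_v <- ifelse(arm == "case", p$case[2], p$control[2])
    slope <- config$methylation_trait_slope[trait]
    if (is.na(slope) || is.null(slope)) slope <- 0
    set.seed(substream_seed(config$seed, paste0("trait_", trait)))
    v <- stats::rnorm(n_tot, mean_v, sd_v) + slope * meth_centered
    if (trait %in% positive_traits) {
      bad <- which(v <= 0)
      tries <- 0L
      while (length(bad) && tries < 100L) {
        v[bad] <- stats::rnorm(length(bad), mean_v[bad], sd_v[bad]) +
          slope * meth_centered[bad]
        bad <- which(v <= 0)
        tries <- tries + 1L
      }
      if (length(bad)) {
        warning(sprintf("%d %s draws clamped to 0.1 after resampling",
                        length(bad), trait))
        v[bad] <- 0.1
      }
    }
    out[[trait]] <- v
  }
  out$methylation_target <- methylation
  out
}
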