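#' Configuration for the paired methylation-array simulator
#'
#' Describes a two-timepoint (stage 1 and stage 5) case/control
#' methylation-array study: per-probe baseline beta levels, a set of probes
#' with a planted longitudinal (stage-5 minus stage-1) shift, a set of
#' probes with a planted case-only stage-5 shift, and a measurement noise
#' level. The defaults mirror a small discovery cohort: 8 subjects per arm
#' in a single subgroup, betas centred mid-range, noise standard deviation
#' 0.03 on the beta scale.
#'
#' @param n_probes number of probes.
#' @param n_subjects_per_arm subjects per arm (case and control) per
#'   subgroup; a scalar, or one count per subgroup (e.g. `c(8, 5)` for an
#'   8+8 and a 5+5 subgroup).
#' @param subgroups character vector of subgroup labels.
#' @param baseline_mean per-probe baseline beta mean: scalar, vector of
#'   length `n_probes`, or `NULL` to draw Uniform(0.2, 0.8) from the seed.
#' @param stage_effect named numeric vector: names are probe indices (1-based)
#'   carrying a stage-5-minus-stage-1 shift in beta units, applied to every
#'   subject.
#' @param case_effect named numeric vector: probe indices carrying a stage-5
#'   shift applied to case-arm subjects only (negative = hypo-methylation in
#'   cases, the direction seen for a T2D-associated CpG).
#' @param noise_sd measurement noise standard deviation on the beta scale
#'   (applied as logit-normal jitter; see Details).
#' @param seed master integer seed.
#'
#' @details Noise is drawn on the logit scale with a per-probe standard
#' deviation `noise_sd / (mu * (1 - mu))`, the delta-method scaling that
#' makes the beta-scale standard deviation approximately `noise_sd`
#' regardless of the probe's baseline level. This keeps every generated
#' value inside (0, 1) and reproduces the mean-dependent heteroscedasticity
#' of array betas.
#'
#' @return an object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_probes = 1000L,
                             n_subjects_per_arm = 8L,
                             subgroups = "hiGlu60",
                             baseline_mean = NULL,
                             stage_effect = numeric(0),
                             case_effect = numeric(0),
                             noise_sd = 0.03,
                             seed = 1L) {
  if (n_probes < 1 || any(n_subjects_per_arm < 1))
    abort_fmt("n_probes and n_subjects_per_arm must be positive")
  if (noise_sd < 0) abort_fmt("noise_sd must be nonnegative")
  if (length(subgroups) < 1) abort_fmt("at least one subgroup label required")
  if (!length(n_subjects_per_arm) %in% c(1L, length(subgroups)))
    abort_fmt("n_subjects_per_arm must be scalar or one count per subgroup")
  n_subjects_per_arm <- rep(as.integer(n_subjects_per_arm),
                            length.out = length(subgroups))
  check_effect <- function(eff, what) {
    if (length(eff) == 0) return(invisible())
    idx <- as.integer(names(eff))
    if (anyNA(idx) || any(idx < 1) || any(idx > n_probes))
      abort_fmt("%s probe indices must lie in [1, n_probes]", what)
    if (anyDuplicated(idx)) abort_fmt("duplicated probe index in %s", what)
  }
  check_effect(stage_effect, "stage_effect")
  check_effect(case_effect, "case_effect")
  structure(list(n_probes = as.integer(n_probes),
                 n_subjects_per_arm = as.integer(n_subjects_per_arm),
                 subgroups = as.character(subgroups),
                 baseline_mean = baseline_mean,
                 stage_effect = stage_effect,
                 case_effect = case_effect,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "array_sim_config")
}

#' Simulate a paired two-timepoint methylation-array study
#'
#' Generates a probe x sample beta matrix with the paired structure of a
#' longitudinal case/control array study: every subject contributes one
#' stage-1 and one stage-5 column, arms and subgroups are recorded in a
#' sample sheet, and planted effects are reported in a truth table so that
#' downstream discovery can be scored against ground truth.
#'
#' @param config an [array_sim_config()].
#' @return list with elements
#'   \item{beta}{numeric matrix, probes x samples, values in [0, 1];}
#'   \item{samples}{sample sheet data.frame with columns `sample_id`,
#'     `subject_id`, `stage` (1 or 5), `arm` ("case"/"control"),
#'     `subgroup`;}
#'   \item{truth}{data.frame of planted probes: `probe_id`, `effect`
#'     ("stage" or "case"), `delta`.}
#' @examples
#' cfg <- array_sim_config(n_probes = 50, n_subjects_per_arm = 4, seed = 7)
#' sim <- simulate_array_study(cfg)
#' dim(sim$beta)  # 50 x 16
#' @export
simulate_array_study <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  n <- config$n_probes

  set.seed(substream_seed(config$seed, "baseline"))
  mu <- config$baseline_mean
  if (is.null(mu)) {
    mu <- stats::runif(n, 0.2, 0.8)
  } else if (length(mu) == 1L) {
    mu <- rep(mu, n)
  } else if (length(mu) != n) {
    abort_fmt("baseline_mean must have length 1 or n_probes")
  }
  if (any(mu < 0) || any(mu > 1)) abort_fmt("baseline means must lie in [0, 1]")

  stage_idx <- as.integer(names(config$stage_effect))
  case_idx <- as.integer(names(config$case_effect))
  mu5 <- mu
  if (length(stage_idx)) mu5[stage_idx] <- mu5[stage_idx] + config$stage_effect
  mu5_case <- mu5
  if (length(case_idx)) mu5_case[case_idx] <- mu5_case[case_idx] + config$case_effect
  if (any(mu5 < 0 | mu5 > 1) || any(mu5_case < 0 | mu5_case > 1))
    abort_fmt("planted deltas push a probe mean outside [0, 1]")

  probe_ids <- sprintf("probe_%05d", seq_len(n))

  sheet <- do.call(rbind, lapply(seq_along(config$subgroups), function(g) {
    sg <- config$subgroups[g]
    n_arm <- config$n_subjects_per_arm[g]
    subj <- sprintf("%s_%s%02d", sg,
                    rep(c("ctrl", "case"), each = n_arm),
                    rep(seq_len(n_arm), 2L))
    data.frame(subject_id = rep(subj, each = 2L),
               stage = rep(c(1L, 5L), times = length(subj)),
               arm = rep(rep(c("control", "case"), each = n_arm), each = 2L),
               subgroup = sg, stringsAsFactors = FALSE)
  }))
  sheet$sample_id <- paste0(sheet$subject_id, "_st", sheet$stage)
  sheet <- sheet[, c("sample_id", "subject_id", "stage", "arm", "subgroup")]

  # per-column mean profile: baseline at stage 1; stage (+ case) shifts at stage 5
  mean_for <- function(stage, arm) {
    if (stage == 1L) mu else if (arm == "case") mu5_case else mu5
  }
  eps <- 1e-6
  set.seed(substream_seed(config$seed, "noise"))
  beta <- vapply(seq_len(nrow(sheet)), function(j) {
    m <- clip01(mean_for(sheet$stage[j], sheet$arm[j]), eps, 1 - eps)
    sd_logit <- config$noise_sd / (m * (1 - m))
    clip01(stats::plogis(stats::qlogis(m) + stats::rnorm(n, 0, sd_logit)))
  }, numeric(n))
  dimnames(beta) <- list(probe_ids, sheet$sample_id)

  truth <- rbind(
    if (length(stage_idx))
      data.frame(probe_id = probe_ids[stage_idx], effect = "stage",
                 delta = unname(config$stage_effect),
                 stringsAsFactors = FALSE),
    if (length(case_idx))
      data.frame(probe_id = probe_ids[case_idx], effect = "case",
                 delta = unname(config$case_effect),
                 stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(probe_id = character(0), effect = character(0),
                        delta = numeric(0), stringsAsFactors = FALSE)

  list(beta = beta, samples = sheet, truth = truth)
}
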