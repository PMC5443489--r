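#' Paired longitudinal test per probe
#'
#' For one (subgroup, arm) group, tests every probe for a stage-5 versus
#' stage-1 methylation change with a two-sided paired t-test on the
#' per-subject stage differences. The computation is vectorised over
#' probes; it is algebraically the textbook paired t (mean difference over
#' its standard error on n-1 degrees of freedom).
#'
#' @param beta probe x sample beta matrix (column names = sample ids).
#' @param samples sample sheet data.frame (`sample_id`, `subject_id`,
#'   `stage`, `arm`, `subgroup`).
#' @param subgroup subgroup label to test.
#' @param arm `"case"` or `"control"`.
#' @return data.frame with one row per probe: `probe_id`, `p_value`,
#'   `delta_stage` (mean stage-5 minus stage-1 beta), `degenerate` (TRUE
#'   where the differences had zero variance or missing data; `p_value` is
#'   NA there). The number of probes dropped for missing data is attached
#'   as attribute `n_dropped`.
#' @export
paired_stage_test <- function(beta, samples, subgroup, arm) {
  grp <- samples[samples$subgroup == subgroup & samples$arm == arm, ,
                 drop = FALSE]
  if (nrow(grp) == 0) abort_fmt("no samples for subgroup '%s', arm '%s'",
                                subgroup, arm)
  subjects <- unique(grp$subject_id)
  for (s in subjects) {
    st <- sort(grp$stage[grp$subject_id == s])
    if (!identical(st, c(1L, 5L)))
      abort_fmt("subject '%s' is not paired: stages present = %s",
                s, paste(st, collapse = ","))
  }
  id1 <- grp$sample_id[match(paste0(subjects, 1), paste0(grp$subject_id, grp$stage))]
  id5 <- grp$sample_id[match(paste0(subjects, 5), paste0(grp$subject_id, grp$stage))]
  missing_cols <- setdiff(c(id1, id5), colnames(beta))
  if (length(missing_cols))
    abort_fmt("sample(s) absent from beta matrix: %s",
              paste(missing_cols, collapse = ", "))
  d <- beta[, id5, drop = FALSE] - beta[, id1, drop = FALSE]
  n <- length(subjects)
  if (n < 2) abort_fmt("paired test needs at least 2 subjects")
  complete <- rowSums(is.na(d)) == 0
  dbar <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - dbar)^2) / (n - 1))
  tt <- dbar / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  degenerate <- !complete | sd_d == 0
  p[degenerate] <- NA_real_
  out <- data.frame(probe_id = rownames(beta),
                    p_value = p,
                    delta_stage = dbar,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' Stage-5 case-control methylation contrast per probe
#'
#' Mean case beta minus mean control beta across the stage-5 samples of a
#' subgroup — the ranking key of the DMP selection.
#'
#' @inheritParams paired_stage_test
#' @return named numeric vector (probe id -> delta), case minus control.
#' @export
stage5_case_control_delta <- function(beta, samples, subgroup) {
  s5 <- samples[samples$subgroup == subgroup & samples$stage == 5L, ,
                drop = FALSE]
  if (nrow(s5) == 0) abort_fmt("no stage-5 samples for subgroup '%s'", subgroup)
  case_ids <- s5$sample_id[s5$arm == "case"]
  ctrl_ids <- s5$sample_id[s5$arm == "control"]
  if (!length(case_ids) || !length(ctrl_ids))
    abort_fmt("subgroup '%s' needs stage-5 samples in both arms", subgroup)
  delta <- rowMeans(beta[, case_ids, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, ctrl_ids, drop = FALSE], na.rm = TRUE)
  stats::setNames(delta, rownames(beta))
}

#' Select the top-k stage-specific DMPs
#'
#' Applies the discovery filter: probes significant in the longitudinal
#' paired test (p < alpha, nominal — no multiple-testing correction, by
#' design) are ranked by the magnitude of the stage-5 case-control
#' methylation difference and truncated to the top k. Ties are broken
#' deterministically by (|delta| descending, p ascending, probe id).
#'
#' @param results output of [paired_stage_test()] for the group.
#' @param case_control_delta named vector from [stage5_case_control_delta()].
#' @param k maximum set size (default 250).
#' @param alpha significance gate on the paired-test p-value (default 0.05).
#' @param rank_by `"abs"` (default) ranks by |delta|; `"signed"` by delta.
#' @return data.frame (class `dmp_set`): `probe_id`, `p_value`,
#'   `delta_stage`, `delta_case_control`, `rank`; attributes `k`, `alpha`.
#'   An `fdr` column (Benjamini-Hochberg over all tested probes) is carried
#'   for information only; it plays no role in selection.
#' @export
select_stage5_dmps <- function(results, case_control_delta, k = 250L,
                               alpha = 0.05, rank_by = c("abs", "signed")) {
  rank_by <- match.arg(rank_by)
  if (k <= 0) abort_fmt("k must be positive")
  if (nrow(results) == 0) abort_fmt("empty results table")
  fdr_all <- stats::p.adjust(results$p_value, method = "BH")
  keep <- !is.na(results$p_value) & results$p_value < alpha
  sel <- results[keep, , drop = FALSE]
  sel$fdr <- fdr_all[keep]
  sel$delta_case_control <- unname(case_control_delta[sel$probe_id])
  key <- if (rank_by == "abs") abs(sel$delta_case_control) else sel$delta_case_control
  ord <- order(-key, sel$p_value, sel$probe_id)
  sel <- sel[ord, , drop = FALSE]
  sel <- utils::head(sel, k)
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel <- sel[, c("probe_id", "p_value", "delta_stage", "delta_case_control",
                 "fdr", "rank")]
  attr(sel, "k") <- k
  attr(sel, "alpha") <- alpha
  class(sel) <- c("dmp_set", "data.frame")
  sel
}

#' Case-specific DMPs by set subtraction
#'
#' Probes selected in the case arm but not in the control arm of the same
#' subgroup — removing longitudinal changes shared with controls (ageing,
#' batch) and keeping those specific to the hyperglycemic cases.
#'
#' @param case_set,control_set `dmp_set` objects (or anything with a
#'   `probe_id` column / character vector of probe ids).
#' @return character vector of probe ids, sorted.
#' @export
case_specific_dmps <- function(case_set, control_set) {
  sort(setdiff(dmp_ids(case_set), dmp_ids(control_set)))
}

#' Overlap of two DMP sets
#'
#' @param set_a,set_b probe sets (character vectors or `dmp_set` objects).
#' @return sorted character vector of shared probe ids.
#' @export
overlap_dmps <- function(set_a, set_b) {
  sort(intersect(dmp_ids(set_a), dmp_ids(set_b)))
}

dmp_ids <- function(x) {
  if (is.character(x)) x else x$probe_id
}

#' Methylation direction of a case-control contrast
#'
#' @param delta_case_control numeric vector, case mean minus control mean.
#' @return character vector: `"hypo"` where cases are lower, `"hyper"`
#'   where higher, `"tie"` at exactly zero.
#' @examples
#' annotate_direction(c(-0.11, 0.05, 0))  # hypo, hyper, tie
#' @export
annotate_direction <- function(delta_case_control) {
  out <- ifelse(delta_case_control < 0, "hypo",
                ifelse(delta_case_control > 0, "hyper", "tie"))
  as.character(out)
}

#' Run the full DMP discovery cascade
#'
#' For every subgroup in the sample sheet: (1) paired stage-5 vs stage-1
#' tests within each arm; (2) top-k selection per arm gated at the nominal
#' alpha and ranked by the stage-5 case-control contrast; (3) case-specific
#' probes by subtracting the control-arm set from the case-arm set. If two
#' or more subgroups are present, the case-specific sets of the first two
#' are intersected to give the cross-subgroup overlap.
#'
#' @inheritParams paired_stage_test
#' @inheritParams select_stage5_dmps
#' @return list with
#'   \item{subgroups}{per-subgroup list: `case_set`, `control_set`
#'     (`dmp_set`s), `case_specific` (probe ids), `delta_case_control`
#'     (named vector), `direction` (named hypo/hyper/tie for the
#'     case-specific probes);}
#'   \item{overlap}{probe ids shared by the first two subgroups' case-
#'     specific sets (NULL with a single subgroup);}
#'   \item{summary}{data.frame of per-arm selected counts and case-specific
#'     counts per subgroup.}
#' @export
run_dmp_cascade <- function(beta, samples, k = 250L, alpha = 0.05,
                            rank_by = "abs") {
  subgroups <- unique(samples$subgroup)
  res <- lapply(subgroups, function(sg) {
    delta_cc <- stage5_case_control_delta(beta, samples, sg)
    case_res <- paired_stage_test(beta, samples, sg, "case")
    ctrl_res <- paired_stage_test(beta, samples, sg, "control")
    case_set <- select_stage5_dmps(case_res, delta_cc, k, alpha, rank_by)
    ctrl_set <- select_stage5_dmps(ctrl_res, delta_cc, k, alpha, rank_by)
    spec <- case_specific_dmps(case_set, ctrl_set)
    list(case_set = case_set, control_set = ctrl_set,
         case_specific = spec,
         delta_case_control = delta_cc,
         direction = stats::setNames(annotate_direction(delta_cc[spec]), spec))
  })
  names(res) <- subgroups
  overlap <- if (length(subgroups) >= 2)
    overlap_dmps(res[[1]]$case_specific, res[[2]]$case_specific) else NULL
  summary <- do.call(rbind, lapply(subgroups, function(sg) {
    r <- res[[sg]]
    data.frame(subgroup = sg,
               control_selected = nrow(r$control_set),
               case_selected = nrow(r$case_set),
               case_specific = length(r$case_specific),
               stringsAsFactors = FALSE)
  }))
  list(subgroups = res, overlap = overlap, summary = summary)
}
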