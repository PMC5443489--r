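#' Site x donor methylation matrix over a genomic window
#'
#' Collects each donor's reliable per-cytosine calls inside a 1-based
#' inclusive window into a matrix of percent methylation (ratio x 100).
#' Every (position, strand) record is its own row — the two strands of a
#' CpG are never merged. Sites missing a reliable call in some donors are
#' kept with NA cells; downstream tests use the donors available.
#'
#' @param calls named list of per-donor call data.frames (columns `chrom`,
#'   `pos`, `strand`, `ratio`, `eff_CT`).
#' @param chrom chromosome of the window.
#' @param start,end 1-based inclusive bounds (`start <= end`).
#' @param min_ct reliability threshold passed to [filter_reliable()].
#' @return numeric matrix, sites x donors, in percent; rownames
#'   `"<pos>:<strand>"`, with integer positions as attribute `pos` and
#'   strands as attribute `strand`.
#' @export
extract_window <- function(calls, chrom, start, end, min_ct = 10L) {
  if (start > end) abort_fmt("window start exceeds end")
  stopifnot(is.list(calls), length(calls) > 0)
  sub <- lapply(calls, function(df) {
    df <- filter_reliable(df, min_ct)
    df[df$chrom == chrom & df$pos >= start & df$pos <= end, , drop = FALSE]
  })
  keys <- unique(do.call(rbind, lapply(sub, function(df)
    df[, c("pos", "strand"), drop = FALSE])))
  if (is.null(keys) || nrow(keys) == 0)
    abort_fmt("window %s:%d-%d contains no reliable calls", chrom, start, end)
  keys <- keys[order(keys$pos, keys$strand), , drop = FALSE]
  rn <- paste0(keys$pos, ":", keys$strand)
  m <- matrix(NA_real_, nrow(keys), length(sub),
              dimnames = list(rn, names(calls)))
  for (j in seq_along(sub)) {
    df <- sub[[j]]
    idx <- match(paste0(df$pos, ":", df$strand), rn)
    m[idx, j] <- df$ratio * 100
  }
  attr(m, "pos") <- keys$pos
  attr(m, "strand") <- keys$strand
  m
}

#' Two-sided Mann-Whitney U test for one site
#'
#' Rank-sum test of a control against a case group. For small designs
#' (all distinct group assignments enumerable, up to
#' `max_combinations`) the p-value is exact: every assignment of the
#' pooled values to the two groups is enumerated and the two-sided
#' p-value is the fraction of assignments whose rank sum deviates from
#' its permutation mean at least as much as observed (midranks handle
#' ties). Larger designs fall back to the normal approximation with tie
#' correction.
#'
#' @param values_control,values_case numeric vectors (NAs dropped; at
#'   least one value per group).
#' @param max_combinations enumeration budget for the exact path.
#' @return list with `p`, `method` ("exact" or "normal"), and `tie`
#'   (TRUE when all pooled values are identical; `p` is then 1).
#' @export
site_test <- function(values_control, values_case, max_combinations = 20000) {
  a <- values_control[!is.na(values_control)]
  b <- values_case[!is.na(values_case)]
  if (!length(a) || !length(b))
    abort_fmt("site_test needs at least one value per group")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(p = 1, method = "degenerate", tie = TRUE))
  n <- length(pooled); na <- length(a)
  if (choose(n, na) <= max_combinations) {
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(na)])
    mu <- na * (n + 1) / 2
    combos <- utils::combn(n, na)
    w_perm <- colSums(matrix(r[combos], nrow = na))
    p <- mean(abs(w_perm - mu) >= abs(w_obs - mu) - 1e-9)
    list(p = p, method = "exact", tie = FALSE)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    list(p = wt$p.value, method = "normal", tie = FALSE)
  }
}

#' Split donors into control and case sets
#'
#' Stratification schemes for the window analysis: disease status
#' (`"t2d"`: non-T2D vs T2D), age (`"age"`: young, under 40, vs old, 40
#' and over), sex (`"sex"`: male vs female), and sex-matched disease
#' status (`"t2d_sex_matched"`: restrict to the sex of the cases — which
#' must be uniform — then non-T2D vs T2D).
#'
#' @param donors data.frame with `donor_id`, `age`, `sex`, `t2d`.
#' @param scheme one of `"t2d"`, `"age"`, `"sex"`, `"t2d_sex_matched"`.
#' @return list with character vectors `control` and `case` of donor ids.
#' @export
stratify <- function(donors, scheme = c("t2d", "age", "sex",
                                        "t2d_sex_matched")) {
  scheme <- match.arg(scheme)
  need <- switch(scheme, t2d = "t2d", age = "age", sex = "sex",
                 t2d_sex_matched = c("t2d", "sex"))
  if (any(vapply(donors[need], anyNA, logical(1))))
    abort_fmt("incomplete donor metadata for scheme '%s'", scheme)
  id <- donors$donor_id
  switch(scheme,
    t2d = list(control = id[!donors$t2d], case = id[donors$t2d]),
    age = list(control = id[donors$age < 40], case = id[donors$age >= 40]),
    sex = list(control = id[donors$sex == "male"],
               case = id[donors$sex == "female"]),
    t2d_sex_matched = {
      case_sex <- unique(donors$sex[donors$t2d])
      if (length(case_sex) != 1L)
        abort_fmt("t2d_sex_matched undefined: cases of mixed sex")
      keep <- donors$sex == case_sex
      list(control = id[keep & !donors$t2d], case = id[keep & donors$t2d])
    })
}

#' Windowed differential-methylation summary
#'
#' The window-level analysis: per-site Mann-Whitney tests between donor
#' groups, direction tallies, significant-DMP (sDMP) counting at the
#' nominal alpha, the mean methylation change over sDMPs, and a seeded
#' percentile-bootstrap confidence interval for that mean obtained by
#' resampling donors within each group (the sDMP site set stays fixed).
#'
#' @param mat site x donor percent-methylation matrix from
#'   [extract_window()].
#' @param groups list with `control` and `case` donor-id vectors (e.g.
#'   from [stratify()]); both must be non-empty and present as columns.
#' @param alpha per-site significance level (default 0.05).
#' @param change_sign `"control_minus_case"` (default) or
#'   `"case_minus_control"`.
#' @param n_boot bootstrap replicates for the CI (default 1000).
#' @param conf CI coverage (default 0.95).
#' @param boot_seed seed for the bootstrap resampling.
#' @return list of class `window_summary`:
#'   \item{sites}{per-site data.frame: `pos`, `strand`, `mean_control`,
#'     `mean_case`, `change`, `p`;}
#'   \item{n_controls,n_cases}{group sizes;}
#'   \item{n_sites}{sites tested (>= 1 donor per group);}
#'   \item{increased_dmps,decreased_dmps,ties}{direction tallies by the
#'     sign of `change`;}
#'   \item{sdmp_count}{sites with p < alpha;}
#'   \item{mean_change_sdmp}{mean `change` over sDMPs (NA if none);}
#'   \item{ci_low,ci_high}{percentile bootstrap CI of that mean;}
#'   \item{n_excluded}{sites dropped for lacking a donor in some group.}
#' @export
summarize_window <- function(mat, groups, alpha = 0.05,
                             change_sign = c("control_minus_case",
                                             "case_minus_control"),
                             n_boot = 1000L, conf = 0.95, boot_seed = 1L) {
  change_sign <- match.arg(change_sign)
  ctrl <- groups$control
  case <- groups$case
  if (!length(ctrl) || !length(case))
    abort_fmt("both donor groups must be non-empty")
  missing_donor <- setdiff(c(ctrl, case), colnames(mat))
  if (length(missing_donor))
    abort_fmt("donor(s) absent from matrix: %s",
              paste(missing_donor, collapse = ", "))
  mc <- mat[, ctrl, drop = FALSE]
  mk <- mat[, case, drop = FALSE]
  ok <- rowSums(!is.na(mc)) >= 1 & rowSums(!is.na(mk)) >= 1
  n_excluded <- sum(!ok)
  pos <- attr(mat, "pos"); strand <- attr(mat, "strand")
  mc <- mc[ok, , drop = FALSE]; mk <- mk[ok, , drop = FALSE]
  if (nrow(mc) == 0) abort_fmt("no testable sites in window")

  sgn <- if (change_sign == "control_minus_case") 1 else -1
  mean_ctrl <- rowMeans(mc, na.rm = TRUE)
  mean_case <- rowMeans(mk, na.rm = TRUE)
  change <- sgn * (mean_ctrl - mean_case)
  p <- vapply(seq_len(nrow(mc)), function(i)
    site_test(mc[i, ], mk[i, ])$p, numeric(1))

  sites <- data.frame(pos = pos[ok], strand = strand[ok],
                      mean_control = mean_ctrl, mean_case = mean_case,
                      change = change, p = p, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  sdmp <- which(p < alpha)
  mean_change <- if (length(sdmp)) mean(change[sdmp]) else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (length(sdmp)) {
    set.seed(substream_seed(boot_seed, "window_boot"))
    reps <- vapply(seq_len(n_boot), function(b) {
      ic <- sample(ncol(mc), replace = TRUE)
      ik <- sample(ncol(mk), replace = TRUE)
      d <- sgn * (rowMeans(mc[sdmp, ic, drop = FALSE], na.rm = TRUE) -
                    rowMeans(mk[sdmp, ik, drop = FALSE], na.rm = TRUE))
      mean(d, na.rm = TRUE)
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    ci <- qs
  }

  structure(list(sites = sites,
                 n_controls = length(ctrl), n_cases = length(case),
                 n_sites = nrow(sites),
                 increased_dmps = sum(change > 0),
                 decreased_dmps = sum(change < 0),
                 ties = sum(change == 0),
                 sdmp_count = length(sdmp),
                 mean_change_sdmp = mean_change,
                 ci_low = ci[1], ci_high = ci[2],
                 alpha = alpha, change_sign = change_sign,
                 n_excluded = n_excluded),
            class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  cat(sprintf("Window summary: %d sites, %d controls vs %d cases\n",
              x$n_sites, x$n_controls, x$n_cases))
  cat(sprintf("  increased %d / decreased %d / ties %d (change = %s)\n",
              x$increased_dmps, x$decreased_dmps, x$ties, x$change_sign))
  cat(sprintf("  sDMPs (p < %.3g): %d; mean change %.2f%% (CI %.2f ~ %.2f)\n",
              x$alpha, x$sdmp_count, x$mean_change_sdmp, x$ci_low, x$ci_high))
  invisible(x)
}

#' Recount a per-site differential-methylation table
#'
#' Recomputes the headline counts of a published per-site window table
#' (control mean, case mean, p per site): total sites, direction tallies,
#' sDMP count at alpha, hypo-methylated sDMPs, and the mean change over
#' all sDMPs and over the hypo-methylated ones. Useful for auditing a
#' supplementary site table without rerunning the donors.
#'
#' @param site_table data.frame with columns `pos`, `mean_control`,
#'   `mean_case` (percent), `p`.
#' @param alpha significance level (default 0.05).
#' @param subwindow optional `c(start, end)`: additionally count sites in
#'   this 1-based inclusive sub-window.
#' @return list: `n_sites`, `increased`, `decreased`, `sdmp_count`,
#'   `sdmp_hypo` (sDMPs with cases lower), `mean_change_sdmp`,
#'   `mean_change_sdmp_hypo`, and `n_subwindow` when requested.
#' @export
summarize_site_table <- function(site_table, alpha = 0.05, subwindow = NULL) {
  need <- c("pos", "mean_control", "mean_case", "p")
  stopifnot(all(need %in% names(site_table)))
  change <- site_table$mean_control - site_table$mean_case
  sdmp <- which(site_table$p < alpha)
  hypo <- sdmp[change[sdmp] > 0]
  out <- list(n_sites = nrow(site_table),
              increased = sum(change > 0),
              decreased = sum(change < 0),
              sdmp_count = length(sdmp),
              sdmp_hypo = length(hypo),
              mean_change_sdmp = if (length(sdmp)) mean(change[sdmp]) else NA_real_,
              mean_change_sdmp_hypo = if (length(hypo)) mean(change[hypo]) else NA_real_)
  if (!is.null(subwindow))
    out$n_subwindow <- sum(site_table$pos >= subwindow[1] &
                             site_table$pos <= subwindow[2])
  out
}
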