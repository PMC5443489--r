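#' Configuration for the per-cytosine bisulfite count simulator
#'
#' Describes a windowed whole-genome bisulfite sequencing (WGBS) contrast:
#' a genomic region populated with CpG sites at geometrically distributed
#' spacing, a control group methylation profile, a planted control-minus-
#' case methylation difference, between-donor biological variation, and a
#' Poisson coverage model. Defaults emulate a deep-coverage islet
#' methylome panel: a 10 kb window centred on a target CpG, roughly 34 bp
#' mean CpG spacing (about 292 CpGs per 10 kb), 16 control and 2 case
#' donors, 30X mean coverage, a 72% control methylation level, and a
#' planted 16-point case hypo-methylation.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive region bounds.
#' @param anchor optional position forced to be a CpG site (e.g. the target
#'   CpG the window is centred on); `NULL` to disable.
#' @param mean_spacing mean CpG-to-CpG spacing in bp (geometric gaps).
#' @param n_control,n_case donors per group.
#' @param control_level control-group mean methylation per site, scalar in
#'   [0, 1] (recycled over sites).
#' @param planted_delta control-minus-case mean methylation difference
#'   (positive = cases hypo-methylated), applied at `planted_sites`.
#' @param planted_sites integer site indices receiving the delta, or
#'   `"all"` (default).
#' @param donor_sd between-donor sd of per-site methylation (beta scale).
#' @param mean_coverage mean per-strand read coverage (Poisson).
#' @param seed master integer seed.
#' @return an object of class `wgbs_sim_config`.
#' @export
wgbs_sim_config <- function(chrom = "chr17",
                            start = 55479635L, end = 55489635L,
                            anchor = 55484635L,
                            mean_spacing = 34,
                            n_control = 16L, n_case = 2L,
                            control_level = 0.72,
                            planted_delta = 0.16,
                            planted_sites = "all",
                            donor_sd = 0.05,
                            mean_coverage = 30,
                            seed = 1L) {
  if (end < start) abort_fmt("region end precedes start")
  if (mean_coverage <= 0) abort_fmt("mean_coverage must be positive")
  if (n_control < 1 || n_case < 1) abort_fmt("need at least one donor per group")
  if (any(control_level < 0 | control_level > 1))
    abort_fmt("control_level must lie in [0, 1]")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 anchor = if (is.null(anchor)) NULL else as.integer(anchor),
                 mean_spacing = mean_spacing,
                 n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 control_level = control_level,
                 planted_delta = planted_delta,
                 planted_sites = planted_sites,
                 donor_sd = donor_sd,
                 mean_coverage = mean_coverage,
                 seed = as.integer(seed)),
            class = "wgbs_sim_config")
}

# default donor panel: 18 donors, 2 male T2D cases, 8 males / 10 females,
# 5 donors under 40 — the composition of the islet methylome panel the
# window analysis stratifies.
default_donor_meta <- function(n_control, n_case, seed) {
  n <- n_control + n_case
  set.seed(substream_seed(seed, "donors"))
  donor_id <- sprintf("donor_%02d", seq_len(n))
  t2d <- rep(c(FALSE, TRUE), c(n_control, n_case))
  sex <- rep("female", n)
  n_male_ctrl <- min(6L, n_control)
  sex[seq_len(n_male_ctrl)] <- "male"
  sex[t2d] <- "male"
  n_young <- min(5L, n_control)
  age <- integer(n)
  age[seq_len(n_young)] <- sample(25:39, n_young, replace = TRUE)
  old <- which(age == 0L)
  age[old] <- sample(41:75, length(old), replace = TRUE)
  data.frame(donor_id = donor_id, age = age, sex = sex, t2d = t2d,
             stringsAsFactors = FALSE)
}

#' Simulate per-cytosine WGBS methylation counts over a window
#'
#' Lays CpG sites across the configured region with geometric spacing,
#' assigns each site a control-group methylation level and a case-group
#' level shifted down by the planted delta, draws per-donor per-site true
#' methylation with between-donor noise, and emits both strands of every
#' CpG as separate records (position p on "+" and p+1 on "-") with
#' Poisson coverage and binomial methylated counts — the per-cytosine
#' record format produced by ratio-style bisulfite callers.
#'
#' @param config a [wgbs_sim_config()].
#' @param donor_meta optional donor metadata data.frame (`donor_id`, `age`,
#'   `sex`, `t2d`); by default an 18-donor islet-like panel is built
#'   (16 controls, 2 male T2D cases, 8 males, 5 donors under 40).
#' @return list with elements
#'   \item{calls}{named list of per-donor data.frames with columns `chrom`,
#'     `pos`, `strand`, `context`, `ratio`, `eff_CT`, `C`;}
#'   \item{donors}{the donor metadata;}
#'   \item{truth}{per-site truth: `pos` (CpG "+"-strand position),
#'     `control_level`, `case_level`, `delta` (control minus case).}
#' @export
simulate_wgbs_counts <- function(config, donor_meta = NULL) {
  stopifnot(inherits(config, "wgbs_sim_config"))
  if (is.null(donor_meta))
    donor_meta <- default_donor_meta(config$n_control, config$n_case,
                                     config$seed)
  stopifnot(all(c("donor_id", "age", "sex", "t2d") %in% names(donor_meta)))

  set.seed(substream_seed(config$seed, "sites"))
  span <- config$end - config$start
  n_guess <- ceiling(span / config$mean_spacing) + 20L
  gaps <- stats::rgeom(n_guess, 1 / max(config$mean_spacing - 1, 1)) + 1L
  pos <- config$start + cumsum(c(0L, gaps))
  pos <- pos[pos <= config$end - 1L]  # leave room for the minus strand base
  if (!is.null(config$anchor) &&
      config$anchor >= config$start && config$anchor < config$end)
    pos <- sort(unique(c(pos, config$anchor)))
  n_sites <- length(pos)
  if (n_sites == 0) abort_fmt("region too small: no CpG sites generated")

  ctrl_level <- rep(config$control_level, length.out = n_sites)
  case_level <- ctrl_level
  planted <- if (identical(config$planted_sites, "all")) seq_len(n_sites)
             else as.integer(config$planted_sites)
  case_level[planted] <- clip01(case_level[planted] - config$planted_delta)

  truth <- data.frame(pos = pos, control_level = ctrl_level,
                      case_level = case_level,
                      delta = ctrl_level - case_level)

  calls <- lapply(seq_len(nrow(donor_meta)), function(i) {
    level <- if (donor_meta$t2d[i]) case_level else ctrl_level
    set.seed(substream_seed(config$seed,
                            paste0("donor_", donor_meta$donor_id[i])))
    p_site <- clip01(level + stats::rnorm(n_sites, 0, config$donor_sd))
    # both strands of each CpG: independent coverage draws, shared truth
    strand <- rep(c("+", "-"), each = n_sites)
    position <- c(pos, pos + 1L)
    p <- rep(p_site, 2L)
    cov <- stats::rpois(2L * n_sites, config$mean_coverage)
    c_cnt <- stats::rbinom(2L * n_sites, cov, p)
    df <- data.frame(chrom = config$chrom, pos = position, strand = strand,
                     context = "CG",
                     ratio = ifelse(cov > 0, c_cnt / cov, NA_real_),
                     eff_CT = cov, C = c_cnt,
                     stringsAsFactors = FALSE)
    df[order(df$pos, df$strand), , drop = FALSE]
  })
  names(calls) <- donor_meta$donor_id

  list(calls = calls, donors = donor_meta, truth = truth)
}
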