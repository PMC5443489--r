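#' Infinium-style beta value from allele intensities
#'
#' Computes the methylation beta value from the fluorescent intensities of
#' the methylated (M) and unmethylated (U) allele probes:
#' \deqn{\beta = \frac{\max(M, 0)}{|U| + |M| + 100}}
#' The +100 offset regularises low-intensity probes and is part of the
#' definition, not a tunable. Intensities may be negative (after background
#' subtraction); the max/abs in the formula make it total on the reals, and
#' the result always lies in [0, 1).
#'
#' @param M numeric vector of methylated-allele intensities.
#' @param U numeric vector of unmethylated-allele intensities (recycled
#'   against `M` by the usual rules).
#' @return numeric vector of beta values in [0, 1).
#' @examples
#' beta_value(900, 0)    # 0.9
#' beta_value(100, 100)  # 1/3
#' beta_value(-50, 200)  # 0: negative M is floored
#' @export
beta_value <- function(M, U) {
  stopifnot(is.numeric(M), is.numeric(U))
  pmax(M, 0) / (abs(U) + abs(M) + 100)
}

#' Subtract negative-control background from probe intensities
#'
#' Estimates array background from a set of negative-control probe
#' intensities and subtracts it from every analytical M and U intensity.
#' Results may be negative; [beta_value()] handles that downstream.
#'
#' @param intensities data.frame with columns `probe_id`, `M`, `U` (raw,
#'   nonnegative intensities).
#' @param negative_controls numeric vector of negative-control intensities;
#'   must be non-empty.
#' @param statistic background estimator, `"mean"` (default) or `"median"`.
#' @return the input data.frame with `M` and `U` background-subtracted and
#'   an attribute `background` holding the estimate used.
#' @export
subtract_background <- function(intensities, negative_controls,
                                statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(negative_controls) == 0 || all(is.na(negative_controls)))
    abort_fmt("at least one negative-control intensity is required")
  stopifnot(is.data.frame(intensities),
            all(c("probe_id", "M", "U") %in% names(intensities)))
  if (any(intensities$M < 0, na.rm = TRUE) ||
      any(intensities$U < 0, na.rm = TRUE))
    abort_fmt("raw intensities must be nonnegative (already background-subtracted?)")
  bg <- switch(statistic,
               mean   = mean(negative_controls, na.rm = TRUE),
               median = stats::median(negative_controls, na.rm = TRUE))
  intensities$M <- intensities$M - bg
  intensities$U <- intensities$U - bg
  attr(intensities, "background") <- bg
  intensities
}

#' Beta matrix from per-sample intensity tables
#'
#' Convenience wrapper: background-subtracts each sample's intensity table
#' against its negative controls and assembles a probe x sample beta matrix.
#'
#' @param samples named list of data.frames (one per sample, columns
#'   `probe_id`, `M`, `U`); names become column names.
#' @param negative_controls numeric vector, or named list of vectors (one
#'   per sample).
#' @param statistic passed to [subtract_background()].
#' @return numeric matrix, probes x samples, rownames = probe ids.
#' @export
beta_matrix_from_intensities <- function(samples, negative_controls,
                                         statistic = "mean") {
  stopifnot(is.list(samples), length(samples) > 0)
  probe_ids <- samples[[1]]$probe_id
  cols <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (!identical(s$probe_id, probe_ids))
      abort_fmt("sample %d has a different probe order", i)
    nc <- if (is.list(negative_controls)) negative_controls[[i]] else negative_controls
    s <- subtract_background(s, nc, statistic)
    beta_value(s$M, s$U)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(probe_ids, names(samples))
  m
}
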