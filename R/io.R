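#' Read and write probe x sample beta matrices
#'
#' Beta matrices are stored as TSV with probes as rows: a `probe_id`
#' column followed by one column per sample.
#'
#' @param path file path.
#' @return `read_beta_matrix`: numeric matrix with probe-id rownames.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv_table(path)
  if (!"probe_id" %in% names(df))
    abort_fmt("%s: missing 'probe_id' column", path)
  m <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  if (any(m < 0 | m > 1, na.rm = TRUE))
    abort_fmt("%s: beta values outside [0, 1]", path)
  m
}

#' @rdname read_beta_matrix
#' @param beta numeric matrix, probes x samples.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' Read and write the sample sheet
#'
#' CSV with columns `sample_id`, `subject_id`, `stage` (1 or 5), `arm`
#' ("case"/"control"), `subgroup`.
#'
#' @param path file path.
#' @return `read_sample_sheet`: a validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "stage", "arm", "subgroup")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_fmt("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (!all(df$stage %in% c(1L, 5L)))
    abort_fmt("%s: stage must be 1 or 5", path)
  if (!all(df$arm %in% c("case", "control")))
    abort_fmt("%s: arm must be 'case' or 'control'", path)
  df[, need]
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published replication-cohort summary statistics
#'
#' Per-trait mean, SD and group size of a 220 vs 220 case/control
#' pyrosequencing replication cohort (age- and sex-matched; cases
#' diabetic by fasting and 2-hour OGTT glucose), including the percent
#' methylation of the target CpG chr17:55484635. These printed summaries
#' are the inputs to the summary-form Welch test and the arithmetic
#' blood-contrast checks.
#'
#' @return data.frame: `trait`, `unit`, `mean_control`, `sd_control`,
#'   `n_control`, `mean_case`, `sd_case`, `n_case`.
#' @export
load_replication_summary <- function() {
  path <- system.file("extdata", "replication_cohort_summary.tsv",
                      package = "glycomethyl", mustWork = TRUE)
  read_tsv_table(path)
}

#' Published islet group averages at the target CpG
#'
#' Group mean percent methylation at chr17:55484635 in pancreatic islets:
#' 16 normal donors vs 2 donors with type 2 diabetes.
#'
#' @return data.frame: `group`, `n`, `mean_methylation_pct`.
#' @export
load_islet_target_summary <- function() {
  path <- system.file("extdata", "islet_target_methylation.tsv",
                      package = "glycomethyl", mustWork = TRUE)
  read_tsv_table(path)
}
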