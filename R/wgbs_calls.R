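COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify the sequence context of a cytosine
#'
#' Bisulfite methylation calls are stratified by the two bases downstream
#' of the cytosine on its own strand: CG (next base G), CHG (next base not
#' G, the one after G), CHH (neither). On the minus strand the context is
#' read on the reverse complement, i.e. upstream on the plus-strand
#' coordinates.
#'
#' @param reference reference sequence as a single character string
#'   (plus strand, 1-based indexing).
#' @param pos 1-based position of the cytosine. On `"+"` the reference
#'   base must be C; on `"-"` it must be G (a C on the minus strand).
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"`, `"CHH"`, or `"undetermined"` when the context
#'   runs off the end of the sequence.
#' @examples
#' classify_context("ACGT", 2, "+")   # CG
#' classify_context("ACAGT", 2, "+")  # CHG
#' classify_context("ACATT", 2, "+")  # CHH
#' @export
classify_context <- function(reference, pos, strand = "+") {
  stopifnot(length(reference) == 1L, pos >= 1, pos <= nchar(reference))
  base_at <- function(i) {
    if (i < 1 || i > nchar(reference)) NA_character_
    else toupper(substr(reference, i, i))
  }
  if (strand == "+") {
    if (!identical(base_at(pos), "C"))
      abort_fmt("position %d on '+' is %s, not C", pos, base_at(pos))
    nxt <- c(base_at(pos + 1), base_at(pos + 2))
  } else if (strand == "-") {
    if (!identical(base_at(pos), "G"))
      abort_fmt("position %d on '-' is %s, not G (no C on minus strand)",
                pos, base_at(pos))
    nxt <- unname(COMPLEMENT[c(base_at(pos - 1), base_at(pos - 2))])
  } else abort_fmt("strand must be '+' or '-'")
  if (is.na(nxt[1])) return("undetermined")
  if (nxt[1] == "G") return("CG")
  if (is.na(nxt[2])) return("undetermined")
  if (nxt[2] == "G") "CHG" else "CHH"
}

#' Per-cytosine methylation calls from aligned read observations
#'
#' Tallies per-cytosine methylated (C) and converted (T) base observations
#' into methylation calls: `ratio = C / effective CT`, where the effective
#' CT count includes only C and T observations. Where both mates of a read
#' pair cover the same position, only one mate contributes (mate 1 by
#' default) so overlapping pair ends are not double-counted. Pairs whose
#' mates align to different chromosomes are skipped with a message.
#'
#' @param reads data.frame of per-position base observations with columns
#'   `read_id`, `mate` (1 or 2), `chrom`, `pos` (1-based), `strand`,
#'   `base` (observed base at a cytosine site: C = methylated,
#'   T = converted; other bases are ignored for the effective count).
#' @param reference optional named character vector of reference sequences
#'   (one string per chromosome); when given, each call gets its sequence
#'   context via [classify_context()], otherwise context is `NA`.
#' @param overlap_mate which mate contributes where both cover a position
#'   (default 1).
#' @return data.frame of calls: `chrom`, `pos`, `strand`, `context`,
#'   `ratio`, `eff_CT`, `C`, sorted by chrom, pos, strand.
#' @export
count_calls <- function(reads, reference = NULL, overlap_mate = 1L) {
  need <- c("read_id", "mate", "chrom", "pos", "strand", "base")
  stopifnot(all(need %in% names(reads)))
  reads$base <- toupper(reads$base)

  # drop pairs whose mates sit on different chromosomes
  chrom_per_read <- tapply(reads$chrom, reads$read_id,
                           function(x) length(unique(x)))
  bad <- names(chrom_per_read)[chrom_per_read > 1]
  if (length(bad)) {
    message(sprintf("skipping %d read pair(s) with mates on different chromosomes",
                    length(bad)))
    reads <- reads[!reads$read_id %in% bad, , drop = FALSE]
  }

  # mate-overlap rule: where both mates of a pair observe the same
  # position, keep only the configured mate
  key <- paste(reads$read_id, reads$chrom, reads$pos, reads$strand, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    drop <- key %in% dup_keys & reads$mate != overlap_mate
    reads <- reads[!drop, , drop = FALSE]
  }

  ct <- reads[reads$base %in% c("C", "T"), , drop = FALSE]
  if (nrow(ct) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      ratio = numeric(0), eff_CT = integer(0),
                      C = integer(0), stringsAsFactors = FALSE))
  grp <- paste(ct$chrom, ct$pos, ct$strand, sep = "\r")
  c_cnt <- tapply(ct$base == "C", grp, sum)
  tot <- tapply(rep(1L, nrow(ct)), grp, sum)
  parts <- do.call(rbind, strsplit(names(c_cnt), "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3],
                    context = NA_character_,
                    ratio = as.numeric(c_cnt) / as.numeric(tot),
                    eff_CT = as.integer(tot), C = as.integer(c_cnt),
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    out$context <- vapply(seq_len(nrow(out)), function(i) {
      ref <- reference[[out$chrom[i]]]
      if (is.null(ref)) NA_character_
      else classify_context(ref, out$pos[i], out$strand[i])
    }, character(1))
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only reliable methylation calls
#'
#' A call is reliable when its effective CT count strictly exceeds the
#' threshold (default 10). Idempotent and order-preserving.
#'
#' @param calls data.frame of per-cytosine calls (needs `eff_CT`).
#' @param min_ct reliability threshold; calls with `eff_CT > min_ct` are
#'   retained.
#' @return the filtered data.frame.
#' @export
filter_reliable <- function(calls, min_ct = 10L) {
  stopifnot("eff_CT" %in% names(calls))
  calls[calls$eff_CT > min_ct, , drop = FALSE]
}

#' Read / write per-cytosine methylation-ratio tables
#'
#' The on-disk dialect is a ratio-style tab-separated table with a header:
#' `chrom  pos  strand  context  ratio  eff_CT  C`, positions 1-based.
#'
#' @param path file path.
#' @return `read_methratio`: data.frame of calls.
#' @export
read_methratio <- function(path) {
  x <- read_tsv_table(path)
  need <- c("chrom", "pos", "strand", "context", "ratio", "eff_CT", "C")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort_fmt("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (any(x$C > x$eff_CT, na.rm = TRUE))
    abort_fmt("%s: C count exceeds effective CT count", path)
  x[, need]
}

#' @rdname read_methratio
#' @param calls data.frame of per-cytosine calls.
#' @export
write_methratio <- function(calls, path) {
  need <- c("chrom", "pos", "strand", "context", "ratio", "eff_CT", "C")
  write_tsv_table(calls[, need], path)
}

#' Export calls as a bedGraph methylation track
#'
#' Converts 1-based call positions to 0-based half-open bedGraph
#' intervals, value = methylation ratio.
#'
#' @param calls data.frame of per-cytosine calls.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$pos - 1L,
                   end = calls$pos, value = calls$ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
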