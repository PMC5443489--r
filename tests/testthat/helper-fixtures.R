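# Shared fixtures and independent oracles for the test suite.

# Random toy pileup: a few read pairs and singletons over a handful of
# cytosine positions, with controllable mate overlap.
random_pileup <- function(n_reads = 12, n_pos = 5, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_reads), function(i) {
    paired <- runif(1) < 0.5
    positions <- sort(sample.int(n_pos, sample(2:n_pos, 1)))
    mk <- function(mate, pos) {
      data.frame(read_id = sprintf("r%03d", i), mate = mate,
                 chrom = "chr1", pos = pos, strand = "+",
                 base = sample(c("C", "T", "N"), length(pos),
                               replace = TRUE, prob = c(.45, .45, .1)),
                 stringsAsFactors = FALSE)
    }
    if (paired) {
      # mate 2 covers an overlapping span
      pos2 <- sort(sample.int(n_pos, sample(2:n_pos, 1)))
      rbind(mk(1L, positions), mk(2L, pos2))
    } else mk(1L, positions)
  })
  do.call(rbind, rows)
}

# Brute-force per-position tally: explicit loop over positions and reads,
# applying the mate-overlap and C/T rules record by record. Kept deliberately
# naive and structurally different from count_calls().
oracle_tally <- function(reads, overlap_mate = 1L) {
  reads$base <- toupper(reads$base)
  keys <- unique(reads[, c("chrom", "pos", "strand")])
  keys <- keys[order(keys$chrom, keys$pos, keys$strand), , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    here <- reads[reads$chrom == keys$chrom[i] & reads$pos == keys$pos[i] &
                    reads$strand == keys$strand[i], , drop = FALSE]
    c_n <- 0L; t_n <- 0L
    for (rid in unique(here$read_id)) {
      obs <- here[here$read_id == rid, , drop = FALSE]
      if (nrow(obs) > 1) obs <- obs[obs$mate == overlap_mate, , drop = FALSE]
      for (b in obs$base) {
        if (b == "C") c_n <- c_n + 1L
        if (b == "T") t_n <- t_n + 1L
      }
    }
    if (c_n + t_n > 0)
      out <- rbind(out, data.frame(chrom = keys$chrom[i], pos = keys$pos[i],
                                   strand = keys$strand[i],
                                   eff_CT = c_n + t_n, C = c_n,
                                   stringsAsFactors = FALSE))
  }
  out
}

# Tiny paired-design beta matrix with explicit values, for cascade tests.
toy_paired_study <- function(n_probes = 30, n_subj = 4, seed = 1,
                             case_delta = numeric(0)) {
  cfg <- array_sim_config(n_probes = n_probes, n_subjects_per_arm = n_subj,
                          case_effect = case_delta, noise_sd = 0.03,
                          seed = seed)
  simulate_array_study(cfg)
}
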