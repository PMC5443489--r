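#!/usr/bin/env Rscript
# Stage 1: simulate the discovery inputs.
#
# Builds a paired two-timepoint methylation-array study with the discovery
# design — a high-glucose-response subgroup (8 cases vs 8 controls) and a
# T2D subgroup (5 vs 5), 1,000 probes — planting 20 case-specific
# hypo-methylation effects of 11 percentage points (the blood effect size
# observed at the strongest replicated CpG). Writes the beta matrix, sample
# sheet and truth table for the downstream stages.

library(glycomethyl)

seed <- 20260926L
out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

set.seed(substream_seed(seed, "plant"))
planted <- sample.int(1000, 20)
cfg <- array_sim_config(n_probes = 1000,
                        n_subjects_per_arm = c(8L, 5L),
                        subgroups = c("hiGlu60", "T2D"),
                        case_effect = setNames(rep(-0.11, 20), planted),
                        noise_sd = 0.03,
                        seed = seed)
sim <- simulate_array_study(cfg)

write_beta_matrix(sim$beta, file.path(out_dir, "beta_matrix.tsv"))
write_sample_sheet(sim$samples, file.path(out_dir, "sample_sheet.csv"))
write_tsv_table(sim$truth, file.path(out_dir, "truth_planted_probes.tsv"))

cat(sprintf("simulated %d probes x %d samples (%d subjects, paired stages 1 and 5)\n",
            nrow(sim$beta), ncol(sim$beta),
            length(unique(sim$samples$subject_id))))
cat(sprintf("planted %d case-specific hypo-methylation effects of -0.11 beta\n",
            nrow(sim$truth)))
cat(sprintf("outputs in %s\n", out_dir))
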