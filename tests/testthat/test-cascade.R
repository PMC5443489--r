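test_that("paired stage test matches the textbook paired t on hand data", {
  # 4 subjects, known per-subject stage differences [0.10, 0.09, 0.11, 0.12]
  base <- c(0.50, 0.52, 0.48, 0.51)
  diffs <- c(0.10, 0.09, 0.11, 0.12)
  beta <- rbind(probe_a = c(base, base + diffs))
  samples <- data.frame(
    sample_id = c(paste0("s", 1:4, "_1"), paste0("s", 1:4, "_5")),
    subject_id = rep(paste0("s", 1:4), 2),
    stage = rep(c(1L, 5L), each = 4),
    arm = "case", subgroup = "g", stringsAsFactors = FALSE)
  colnames(beta) <- samples$sample_id
  res <- paired_stage_test(beta, samples, "g", "case")
  # hand-computed: d-bar = 0.105, s_d = 0.0129099, t = 16.2665 on 3 df
  expect_equal(res$delta_stage, 0.105)
  expect_equal(res$p_value, 2 * pt(-0.105 / (sd(diffs) / 2), df = 3))
  oracle <- t.test(base + diffs, base, paired = TRUE)
  expect_equal(res$p_value, oracle$p.value)

  # degenerate: all differences zero
  beta0 <- rbind(flat = c(base, base))
  colnames(beta0) <- samples$sample_id
  res0 <- paired_stage_test(beta0, samples, "g", "case")
  expect_true(res0$degenerate)
  expect_equal(res0$delta_stage, 0)
  expect_true(is.na(res0$p_value))

  # swapping stage labels negates the delta, p unchanged
  sw <- samples
  sw$stage <- ifelse(sw$stage == 1L, 5L, 1L)
  res_sw <- paired_stage_test(beta, sw, "g", "case")
  expect_equal(res_sw$delta_stage, -res$delta_stage)
  expect_equal(res_sw$p_value, res$p_value)
})

test_that("paired stage test agrees with stats::t.test across random probes", {
  sim <- toy_paired_study(n_probes = 25, n_subj = 5, seed = 7)
  res <- paired_stage_test(sim$beta, sim$samples, "hiGlu60", "control")
  subj <- unique(sim$samples$subject_id[sim$samples$arm == "control"])
  for (i in sample(25, 6)) {
    v5 <- sim$beta[i, paste0(subj, "_st5")]
    v1 <- sim$beta[i, paste0(subj, "_st1")]
    o <- t.test(v5, v1, paired = TRUE)
    expect_equal(res$p_value[i], o$p.value, tolerance = 1e-12)
    expect_equal(res$delta_stage[i], unname(o$estimate), tolerance = 1e-12)
  }
})

test_that("unpaired subjects are rejected by name", {
  sim <- toy_paired_study(n_probes = 5, n_subj = 3, seed = 2)
  broken <- sim$samples[-1, ]  # drop one stage-1 sample
  missing_subject <- sim$samples$subject_id[1]
  expect_error(paired_stage_test(sim$beta, broken, "hiGlu60",
                                 sim$samples$arm[1]),
               missing_subject, fixed = TRUE)
})

test_that("top-k selection gates on p, ranks by |delta|, breaks ties deterministically", {
  res <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    p_value = c(0.01, 0.02, 0.03, 0.5),
                    delta_stage = c(0.1, 0.1, 0.1, 0.1),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  delta <- c(p1 = 0.2, p2 = 0.1, p3 = 0.3, p4 = 0.9)

  # k larger than the candidate pool: all significant probes kept
  all3 <- select_stage5_dmps(res, delta, k = 250)
  expect_equal(nrow(all3), 3L)
  expect_false("p4" %in% all3$probe_id)  # gated out by p

  # k = 2: ranked by |delta| descending -> p3 then p1
  top2 <- select_stage5_dmps(res, delta, k = 2)
  expect_equal(top2$probe_id, c("p3", "p1"))
  expect_equal(top2$rank, 1:2)

  # tie on |delta|: broken by smaller p, then probe id
  delta_tie <- c(p1 = 0.2, p2 = -0.2, p3 = 0.2, p4 = 0.9)
  t3 <- select_stage5_dmps(res, delta_tie, k = 3)
  expect_equal(t3$probe_id, c("p1", "p2", "p3"))

  expect_error(select_stage5_dmps(res, delta, k = 0), "positive")
})

test_that("set subtraction and overlap follow set algebra", {
  expect_equal(case_specific_dmps(c("a", "b", "c"), c("c", "d")), c("a", "b"))
  expect_equal(case_specific_dmps(c("a", "b"), c("a", "b")), character(0))
  big <- sprintf("x%03d", 1:250)
  expect_length(case_specific_dmps(big, sprintf("y%03d", 1:250)), 250L)
  expect_equal(overlap_dmps(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_equal(overlap_dmps(c("a"), c("b")), character(0))

  # identity: |case-specific| = |case| - |case ∩ control|
  set.seed(1)
  for (i in 1:10) {
    ca <- sample(letters, 15)
    co <- sample(letters, 10)
    expect_equal(length(case_specific_dmps(ca, co)),
                 length(ca) - length(overlap_dmps(ca, co)))
  }
})

test_that("direction annotation follows the case-control sign", {
  expect_equal(annotate_direction(-0.11), "hypo")
  expect_equal(annotate_direction(0.05), "hyper")
  expect_equal(annotate_direction(0), "tie")
  expect_equal(annotate_direction(c(-1, 1, 0)), c("hypo", "hyper", "tie"))
})

test_that("cascade output is invariant under probe reordering", {
  sim <- toy_paired_study(n_probes = 60, n_subj = 4, seed = 3,
                          case_delta = setNames(rep(-0.1, 5), c(3, 10, 20, 40, 55)))
  a <- run_dmp_cascade(sim$beta, sim$samples, k = 20)
  perm <- sample(nrow(sim$beta))
  b <- run_dmp_cascade(sim$beta[perm, ], sim$samples, k = 20)
  expect_equal(a$subgroups[[1]]$case_specific, b$subgroups[[1]]$case_specific)
  expect_equal(sort(a$subgroups[[1]]$case_set$probe_id),
               sort(b$subgroups[[1]]$case_set$probe_id))
})

test_that("planted case effects are over-represented in the case-arm top-k", {
  hits <- vapply(1:5, function(s) {
    sim <- toy_paired_study(n_probes = 200, n_subj = 8, seed = s,
                            case_delta = setNames(rep(-0.11, 10),
                                                  sample.int(200, 10)))
    cas <- run_dmp_cascade(sim$beta, sim$samples, k = 50)
    mean(sim$truth$probe_id %in% cas$subgroups[[1]]$case_set$probe_id)
  }, numeric(1))
  # 10/200 probes planted; enrichment in a top-50 set means >> 25% recovered
  expect_gt(mean(hits), 0.8)
})

test_that("cascade summary mirrors the per-arm and case-specific counts", {
  sim <- toy_paired_study(n_probes = 80, n_subj = 5, seed = 13)
  cas <- run_dmp_cascade(sim$beta, sim$samples, k = 10)
  r <- cas$subgroups[[1]]
  expect_equal(cas$summary$case_selected, nrow(r$case_set))
  expect_equal(cas$summary$control_selected, nrow(r$control_set))
  expect_equal(cas$summary$case_specific, length(r$case_specific))
  expect_equal(length(r$case_specific),
               nrow(r$case_set) -
                 length(overlap_dmps(r$case_set, r$control_set)))
})
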