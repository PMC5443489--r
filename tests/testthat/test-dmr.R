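make_panel <- function(seed = 1, ...) {
  simulate_wgbs_counts(wgbs_sim_config(seed = seed, ...))
}

test_that("window extraction keeps strands separate and honours the bounds", {
  w <- make_panel(seed = 2, start = 55484335, end = 55484935)
  # a window covering exactly one CpG yields its two strand records
  m2 <- extract_window(w$calls, "chr17", 55484635, 55484636)
  expect_equal(nrow(m2), 2L)
  expect_equal(attr(m2, "pos"), c(55484635L, 55484636L))
  expect_equal(attr(m2, "strand"), c("+", "-"))
  expect_true(all(m2 >= 0 & m2 <= 100, na.rm = TRUE))

  # full region: every simulated CpG inside contributes both strands
  mall <- extract_window(w$calls, "chr17", 55484335, 55484935)
  expect_true(all(w$truth$pos %in% attr(mall, "pos")))

  # degenerate single-position window
  m1 <- extract_window(w$calls, "chr17", 55484635, 55484635)
  expect_equal(nrow(m1), 1L)

  expect_error(extract_window(w$calls, "chr17", 100, 50), "start exceeds")
  expect_error(extract_window(w$calls, "chrX", 1, 100), "no reliable calls")
})

test_that("site test is exact on tiny groups and matches hand enumeration", {
  # control {1,2} vs case {3,4}: most extreme of the 6 assignments, p = 2/6
  r <- site_test(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")

  same <- site_test(c(5, 5, 5), c(5, 5))
  expect_equal(same$p, 1)
  expect_true(same$tie)

  expect_error(site_test(numeric(0), 1), "at least one value")
})

test_that("site test agrees with the exact Mann-Whitney distribution (n <= 10)", {
  set.seed(31)
  for (i in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- round(rnorm(na), 6); b <- round(rnorm(nb), 6)  # tie-free
    got <- site_test(a, b)
    want <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got$p, want, tolerance = 1e-12,
                 label = sprintf("case %d (%d vs %d)", i, na, nb))
    expect_equal(got$method, "exact")
  }
})

test_that("a 16-vs-2 design is handled by exact enumeration over 153 assignments", {
  set.seed(7)
  a <- rnorm(16, 70, 5); b <- rnorm(2, 55, 5)
  got <- site_test(a, b)
  expect_equal(got$method, "exact")
  expect_equal(got$p, wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # smallest achievable two-sided p in this design is 2/153
  extreme <- site_test(1:16 + 10, c(1, 2))
  expect_equal(extreme$p, 2 / 153)
})

test_that("donor stratification reproduces the panel splits", {
  w <- make_panel(seed = 4, start = 55484335, end = 55484935)
  t2d <- stratify(w$donors, "t2d")
  expect_length(t2d$control, 16L)
  expect_length(t2d$case, 2L)
  age <- stratify(w$donors, "age")
  expect_length(age$control, 5L)   # young, under 40
  expect_length(age$case, 13L)     # 40 and over
  sex <- stratify(w$donors, "sex")
  expect_length(sex$control, 8L)   # males
  expect_length(sex$case, 10L)     # females
  sm <- stratify(w$donors, "t2d_sex_matched")
  expect_length(sm$control, 6L)    # male non-T2D
  expect_length(sm$case, 2L)       # male T2D

  mixed <- w$donors
  mixed$sex[mixed$t2d][1] <- "female"
  expect_error(stratify(mixed, "t2d_sex_matched"), "mixed sex")
  incomplete <- w$donors
  incomplete$age[3] <- NA
  expect_error(stratify(incomplete, "age"), "incomplete")
})

test_that("window summary is invariant to site and donor order, and sign-symmetric", {
  w <- make_panel(seed = 6, start = 55484435, end = 55484835)
  m <- extract_window(w$calls, "chr17", 55484435, 55484835)
  g <- stratify(w$donors, "t2d")
  s <- summarize_window(m, g, n_boot = 50, boot_seed = 9)

  perm_sites <- sample(nrow(m)); perm_donors <- sample(ncol(m))
  m2 <- m[perm_sites, perm_donors]
  attr(m2, "pos") <- attr(m, "pos")[perm_sites]
  attr(m2, "strand") <- attr(m, "strand")[perm_sites]
  s2 <- summarize_window(m2, g, n_boot = 50, boot_seed = 9)
  expect_equal(s2$sdmp_count, s$sdmp_count)
  expect_equal(s2$increased_dmps, s$increased_dmps)
  expect_equal(s2$mean_change_sdmp, s$mean_change_sdmp)
  expect_equal(sort(s2$sites$pos), sort(s$sites$pos))

  flip <- summarize_window(m, g, change_sign = "case_minus_control",
                           n_boot = 50, boot_seed = 9)
  expect_equal(flip$mean_change_sdmp, -s$mean_change_sdmp)
  expect_equal(flip$increased_dmps, s$decreased_dmps)
  expect_equal(flip$decreased_dmps, s$increased_dmps)
  expect_equal(flip$sites$p, s$sites$p)

  expect_equal(s$increased_dmps + s$decreased_dmps + s$ties, s$n_sites)
  expect_lte(s$sdmp_count, s$n_sites)
})

test_that("a single non-significant site yields zero sDMPs and an undefined mean", {
  calls <- lapply(1:6, function(i) {
    set.seed(i)
    data.frame(chrom = "chr1", pos = 50L, strand = "+", context = "CG",
               ratio = runif(1, .4, .6), eff_CT = 30L, C = 15L,
               stringsAsFactors = FALSE)
  })
  names(calls) <- paste0("d", 1:6)
  m <- extract_window(calls, "chr1", 50, 50)
  s <- summarize_window(m, list(control = paste0("d", 1:3),
                                case = paste0("d", 4:6)),
                        n_boot = 20)
  expect_equal(s$sdmp_count, 0L)
  expect_true(is.na(s$mean_change_sdmp))
  expect_true(is.na(s$ci_low))
})

test_that("summarize_window validates its donor groups", {
  w <- make_panel(seed = 8, start = 55484435, end = 55484835)
  m <- extract_window(w$calls, "chr17", 55484435, 55484835)
  expect_error(summarize_window(m, list(control = character(0),
                                        case = "donor_17")), "non-empty")
  expect_error(summarize_window(m, list(control = "nope", case = "donor_17")),
               "absent")
})

test_that("site-table recount reports counts, directions and sub-window size", {
  tab <- data.frame(pos = c(10, 20, 30, 40, 50),
                    mean_control = c(70, 72, 60, 55, 65),
                    mean_case = c(50, 60, 62, 55, 40),
                    p = c(0.01, 0.04, 0.20, 0.9, 0.03))
  r <- summarize_site_table(tab, subwindow = c(15, 45))
  expect_equal(r$n_sites, 5L)
  expect_equal(r$increased, 3L)
  expect_equal(r$decreased, 1L)
  expect_equal(r$sdmp_count, 3L)
  expect_equal(r$sdmp_hypo, 3L)
  expect_equal(r$mean_change_sdmp, mean(c(20, 12, 25)))
  expect_equal(r$n_subwindow, 3L)
})

test_that("null window simulation rejects near the nominal rate", {
  ps <- unlist(lapply(1:4, function(s) {
    w <- simulate_wgbs_counts(wgbs_sim_config(seed = s, planted_delta = 0,
                                              start = 55483135,
                                              end = 55486135))
    m <- extract_window(w$calls, "chr17", 55483135, 55486135)
    g <- stratify(w$donors, "t2d")
    mc <- m[, g$control]; mk <- m[, g$case]
    vapply(seq_len(nrow(m)), function(i) site_test(mc[i, ], mk[i, ])$p,
           numeric(1))
  }))
  # 16-vs-2 exact test: attainable p-values make the test conservative,
  # so the rejection rate sits at or below alpha
  expect_lt(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(ps)))
})
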