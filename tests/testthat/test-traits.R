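test_that("HOMA-IR and QUICKI match their closed forms", {
  expect_equal(homa_ir(8.1, 100), 2)
  expect_equal(homa_ir(4.05, 100), 1)
  expect_equal(homa_ir(20.25, 200), 10)
  expect_error(homa_ir(0, 100), "positive")

  expect_equal(quicki(10, 100), 1 / 3)
  expect_equal(quicki(1, 10), 1)
  # cohort-mean inputs: QUICKI of the mean, not the mean of QUICKIs
  expect_equal(quicki(8.34, 92.23), 1 / (log10(8.34) + log10(92.23)))
  expect_equal(quicki(8.34, 92.23), 0.3465, tolerance = 1e-4)
  expect_error(quicki(-1, 100), "positive")
  expect_error(quicki(10, 0.1), "degenerate")
})

test_that("indices scale as expected", {
  expect_equal(homa_ir(16.2, 100), 2 * homa_ir(8.1, 100))
  # QUICKI strictly decreasing in each argument above 1
  expect_lt(quicki(20, 100), quicki(10, 100))
  expect_lt(quicki(10, 200), quicki(10, 100))
})

test_that("OGTT-based classification rules apply their thresholds strictly", {
  expect_equal(classify_hiGlu60(84, 102), "control")   # delta 18
  expect_equal(classify_hiGlu60(90, 204), "case")      # delta 114
  expect_equal(classify_hiGlu60(100, 150), "excluded") # delta 50
  expect_equal(classify_hiGlu60(100, 120), "excluded") # delta 20: boundary
  expect_equal(classify_hiGlu60(100, 200), "excluded") # delta 100: boundary

  expect_equal(classify_t2d_replication(130, 210), "case")
  expect_equal(classify_t2d_replication(130, 150), "non_case")
  expect_equal(classify_t2d_replication(126, 201), "non_case") # strict
  expect_equal(classify_t2d_replication(127, 200), "non_case") # strict
})

test_that("Welch test: raw and summary forms coincide and match stats::t.test", {
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    raw <- welch_t(a, b)
    summ <- welch_t_from_summary(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b))
    expect_equal(raw, summ)
    o <- t.test(a, b, var.equal = FALSE)
    expect_equal(raw$t, unname(o$statistic), tolerance = 1e-12)
    expect_equal(raw$df, unname(o$parameter), tolerance = 1e-12)
    expect_equal(raw$p, o$p.value, tolerance = 1e-12)
    # symmetry: swapping groups negates t, preserves p
    sw <- welch_t(b, a)
    expect_equal(sw$t, -raw$t)
    expect_equal(sw$p, raw$p)
  }
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  deg <- welch_t_from_summary(1, 0, 5, 1, 0, 5)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("trait regression recovers exact and noisy effects", {
  set.seed(4)
  n <- 60
  d <- data.frame(methylation_target = runif(n, 20, 40),
                  age = rnorm(n, 60, 8),
                  sex = sample(c("male", "female"), n, TRUE),
                  BMI = rnorm(n, 24, 3),
                  WBC = rnorm(n, 6, 1.5), RBC = rnorm(n, 4.6, 0.4))
  # noise-free linear response with no covariate effects
  d$y <- 2 * d$methylation_target
  r <- suppressWarnings(trait_regression(d, "y"))  # perfect fit by design
  expect_equal(r$coefficient, 2, tolerance = 1e-9)
  expect_lt(r$p, 1e-12)

  # against a normal-equations oracle
  d$glu <- 150 - 1.5 * d$methylation_target + 0.3 * d$BMI + rnorm(n, 0, 5)
  r2 <- trait_regression(d, "glu")
  X <- cbind(1, d$methylation_target, d$age,
             as.numeric(d$sex == "male"), d$BMI, d$WBC, d$RBC)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$glu)
  expect_equal(r2$coefficient, beta_hat[2, 1], tolerance = 1e-9)

  # affine recoding of a covariate leaves coefficient and p unchanged
  d3 <- d
  d3$age <- (d3$age - 50) / 10
  r3 <- trait_regression(d3, "glu")
  expect_equal(r3$coefficient, r2$coefficient, tolerance = 1e-9)
  expect_equal(r3$p, r2$p, tolerance = 1e-9)
})

test_that("BMI drops out of the covariate set when it is the response", {
  set.seed(5)
  n <- 50
  d <- data.frame(methylation_target = runif(n, 20, 40),
                  age = rnorm(n, 60, 8),
                  sex = sample(c("male", "female"), n, TRUE),
                  WBC = rnorm(n, 6, 1.5), RBC = rnorm(n, 4.6, 0.4))
  d$BMI <- 30 - 0.1 * d$methylation_target + rnorm(n, 0, 2)
  r <- trait_regression(d, "BMI")
  expect_false("BMI" %in% attr(terms(r$fit), "term.labels"))
  expect_true("methylation_target" %in% attr(terms(r$fit), "term.labels"))
})

test_that("collinear designs are rejected with the offending column named", {
  set.seed(6)
  n <- 40
  d <- data.frame(methylation_target = runif(n, 20, 40),
                  age = rnorm(n, 60, 8),
                  sex = sample(c("male", "female"), n, TRUE),
                  BMI = rnorm(n, 24, 3), WBC = rnorm(n, 6, 1.5))
  d$RBC <- d$WBC  # exact collinearity
  d$y <- rnorm(n)
  expect_error(trait_regression(d, "y"), "collinear")
})

test_that("association table has one row per trait", {
  cfg <- trait_sim_config(n_per_arm = 80,
                          methylation_trait_slope = c(Glu0 = -4, HbA1c = -0.09),
                          seed = 10)
  tr <- simulate_traits(cfg)
  tab <- trait_association_table(tr, c("Glu0", "HbA1c", "BMI"))
  expect_equal(tab$trait, c("Glu0", "HbA1c", "BMI"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
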