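worked_table <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2,
                       byrow = TRUE)

test_that("two-way mean squares match the hand-worked 4x2 table", {
  ms <- anova_mean_squares(worked_table)
  expect_equal(ms$MSR, 40 / 3)
  expect_equal(ms$MSC, 2)
  expect_equal(ms$MSE, 0)
  expect_identical(c(ms$dfR, ms$dfC, ms$dfE), c(3L, 1L, 3L))
  # identical columns: no column or residual variance
  ident <- cbind(1:5, 1:5, 1:5)
  mi <- anova_mean_squares(ident)
  expect_equal(mi$MSC, 0)
  expect_equal(mi$MSE, 0)
})

test_that("sum-of-squares decomposition and row exchangeability hold", {
  set.seed(42)
  for (i in 1:20) {
    x <- matrix(rnorm(5 * 3, 10, 2), 5, 3)
    ms <- anova_mean_squares(x)
    sst <- sum((x - mean(x))^2)
    expect_equal(ms$MSR * ms$dfR + ms$MSC * ms$dfC + ms$MSE * ms$dfE,
                 sst, tolerance = 1e-9)
    perm <- x[sample(5), ]
    msp <- anova_mean_squares(perm)
    expect_equal(msp$MSR, ms$MSR, tolerance = 1e-12)
    expect_equal(msp$MSC, ms$MSC, tolerance = 1e-12)
    expect_equal(msp$MSE, ms$MSE, tolerance = 1e-12)
  }
})

test_that("ICC(A,1) equals the aov-based oracle on random 5x3 tables", {
  set.seed(7)
  for (i in 1:25) {
    x <- matrix(rnorm(15, 50, 5) + rep(rnorm(5, 0, 4), 3), 5, 3)
    got <- icc_agreement_single(x)$estimate
    expect_equal(got, icc_oracle(x), tolerance = 1e-10)
  }
})

test_that("worked examples and degenerate tables behave as specified", {
  r <- icc_agreement_single(worked_table)
  expect_equal(r$estimate, (40 / 3) / (40 / 3 + 1), tolerance = 1e-12)
  expect_equal(round(r$estimate, 4), 0.9302)
  expect_lte(r$ci_low, r$estimate)
  expect_gte(r$ci_high, r$estimate)

  perfect <- matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  expect_equal(icc_agreement_single(perfect)$estimate, 1)

  expect_error(icc_agreement_single(matrix(5, 4, 3)), "zero total")
  expect_error(rating_table(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(rating_table(matrix(1:3, 3, 1)), ">= 2")
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(11)
  x <- matrix(rnorm(18, 100, 10) + rep(rnorm(6, 0, 6), 3), 6, 3)
  base <- icc_agreement_single(x)$estimate
  expect_equal(icc_agreement_single(x + 13.7)$estimate, base,
               tolerance = 1e-12)
  expect_equal(icc_agreement_single(x * 3.2)$estimate, base,
               tolerance = 1e-12)
})

test_that("Monte-Carlo mean estimate approaches the variance-ratio truth", {
  # x_ij = s_i + e_ij with var(s) = 9, var(e) = 1 -> population ICC 0.9
  set.seed(123)
  ests <- replicate(200, {
    s <- rnorm(500, 0, 3)
    x <- s + matrix(rnorm(1000), 500, 2)
    icc_agreement_single(x)$estimate
  })
  expect_lt(abs(mean(ests) - 0.9), 0.03)
})

test_that("95% CI covers a population ICC of 0.8 in 93-97% of replicates", {
  # s ~ N(0, 4), e ~ N(0, 1): absolute-agreement ICC = 4/5 = 0.8
  set.seed(2024)
  hits <- replicate(1000, {
    s <- rnorm(30, 0, 2)
    x <- s + matrix(rnorm(90), 30, 3)
    r <- icc_agreement_single(x)
    r$ci_low <= 0.8 && 0.8 <= r$ci_high
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("classification bands follow the published cut-offs", {
  expect_identical(classify_icc(c(0.45, 0.60, 0.85, 0.95)),
                   c("poor", "moderate", "good", "excellent"))
  expect_identical(classify_icc(0.5), "moderate")
  expect_identical(classify_icc(0.75), "good")
  expect_identical(classify_icc(0.9), "excellent")
  expect_identical(classify_icc(-0.2), "poor")
  expect_error(classify_icc(1.2), "exceeds")
})

test_that("ICC sample size reproduces the closed form and is monotone", {
  expect_identical(icc_sample_size(0.5, 0.8, k = 3), 18L)
  expect_identical(icc_sample_size(0.5, 0.8, k = 2), 28L)
  expect_lt(icc_sample_size(0.5, 0.8, k = 5),
            icc_sample_size(0.5, 0.8, k = 3))
  expect_lt(icc_sample_size(0.5, 0.9, k = 3),
            icc_sample_size(0.5, 0.8, k = 3))
  expect_error(icc_sample_size(0.8, 0.8, k = 3), "exceed")
  expect_error(icc_sample_size(0.8, 0.5, k = 3), "exceed")
  expect_error(icc_sample_size(0, 0.8, k = 3))
})

test_that("reliability_table analyses complete panels and names missing cells", {
  set.seed(5)
  reports <- list(); subj <- rater <- character(0)
  vals <- function(base) {
    v <- stats::setNames(base + seq_len(15), MEASUREMENT_NAMES)
    v["arch_height_index"] <- 0.2 + base / 1000
    v["ankle_angle"] <- 10 + base / 10
    measurement_report(v)
  }
  for (s in 1:4) for (r in c("A", "B", "C")) {
    reports[[length(reports) + 1L]] <- vals(10 * s + rnorm(1, 0, 0.1))
    subj <- c(subj, paste0("S", s)); rater <- c(rater, r)
  }
  panel <- panel_from_reports(reports, subj, rater,
                              rep(1, 12), rep("NWB", 12))
  tab <- reliability_table(panel, design = "inter")
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$model == "random"))
  expect_true(all(tab$estimate > 0.99))
  expect_true(all(tab$class == "excellent"))

  broken <- panel[!(panel$subject == "S2" & panel$rater == "C"), ]
  expect_error(reliability_table(broken, design = "inter"), "S2 C")
})

test_that("panels round-trip through CSV", {
  panel <- data.frame(subject = "S1", rater = "A", repetition = 1L,
                      condition = "NWB", measurement = "foot_length",
                      value = 250.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, p)
  expect_equal(read_panel(p), panel)
})
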