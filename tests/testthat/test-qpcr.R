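test_that("2^-ddCt follows the defining arithmetic", {
  # equal dCt in sample and calibrator: exactly 1
  expect_identical(ddct(c(20, 20, 20), c(18, 18, 18),
                        c(25, 25, 25), c(23, 23, 23)), 1)
  # dCt 2 vs 4: ddCt = -2, relative expression 4
  expect_equal(ddct(c(20, 20), c(18, 18), c(22, 22), c(18, 18)), 4)
  # shift invariance: adding a constant to every Ct changes nothing
  set.seed(3)
  for (i in 1:10) {
    t1 <- rnorm(3, 24); r1 <- rnorm(3, 18)
    t0 <- rnorm(3, 25); r0 <- rnorm(3, 18)
    c0 <- runif(1, -5, 5)
    expect_equal(ddct(t1, r1, t0, r0),
                 ddct(t1 + c0, r1 + c0, t0 + c0, r0 + c0),
                 tolerance = 1e-12)
  }
  expect_error(ddct(numeric(0), 1, 1, 1), "nonempty")
})

test_that("qPCR analysis recovers planted ratios on noiseless tables", {
  scn <- noiseless_scenario()
  res <- qpcr_analysis(scn$expression$ct)
  truth <- scn$expression$truth$qpcr
  merged <- merge(res, truth,
                  by.x = c("target", "sample"),
                  by.y = c("target", "timepoint"))
  expect_equal(merged$relative_expression, merged$true_ratio,
               tolerance = 1e-9)
  # the calibrator is exactly 1 for every target
  ntc <- res[res$sample == "NTC", ]
  expect_true(all(abs(ntc$relative_expression - 1) < 1e-12))
})

test_that("Duncan critical values match the published tables", {
  # significant studentized ranges at alpha = 0.05, to the 2-decimal
  # printed precision of the classical tables
  expect_lt(abs(duncan_critical_q(0.05, 2, 6) - 3.46), 0.01)
  expect_lt(abs(duncan_critical_q(0.05, 3, 6) - 3.59), 0.01)
  expect_lt(abs(duncan_critical_q(0.05, 2, 9) - 3.20), 0.01)
  expect_lt(abs(duncan_critical_q(0.05, 3, 9) - 3.34), 0.01)
  # strictly increasing in p, strictly decreasing in df
  qs_p <- vapply(2:6, function(p) duncan_critical_q(0.05, p, 10), 0)
  expect_true(all(diff(qs_p) > 0))
  qs_df <- vapply(c(5, 10, 20, 60), function(df) {
    duncan_critical_q(0.05, 3, df)
  }, 0)
  expect_true(all(diff(qs_df) < 0))
})

test_that("Duncan letter groups separate and merge as expected", {
  # identical groups: everyone shares 'a'
  same <- duncan_mrt(list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2)))
  expect_true(all(same$letter == "a"))
  # wildly separated means with tiny error: all letters distinct
  far <- duncan_mrt(list(a = c(0, 0.01, -0.01), b = c(100, 100.01, 99.99),
                         c = c(200, 200.01, 199.99)))
  expect_equal(sort(far$letter), c("a", "b", "c"))
  # zero error variance with unequal means: all pairs significant
  zv <- duncan_mrt(list(a = c(1, 1), b = c(2, 2), c = c(3, 3)))
  expect_equal(length(unique(zv$letter)), 3)
  # unbalanced designs are rejected
  expect_error(duncan_mrt(list(a = c(1, 2), b = c(1, 2, 3))),
               "unbalanced")
  expect_error(duncan_mrt(list(a = c(1, 2))), ">= 2 groups")

  # contiguity: letters cover contiguous runs of the sorted means
  set.seed(8)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(4, mean = j * 0.8))
    names(groups) <- paste0("g", seq_len(k))
    res <- duncan_mrt(groups)
    for (letter in unique(unlist(strsplit(res$letter, "")))) {
      has <- grepl(letter, res$letter)
      expect_true(all(diff(which(has)) == 1))
    }
  }
})
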