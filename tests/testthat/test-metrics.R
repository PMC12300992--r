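test_that("confusion counts the four outcomes", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 2, fp = 0, fn = 0))
  cm <- confusion(c(1, 0), c(0, 1))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 1, fn = 1))
  cm <- confusion(c("active", "inactive"), c("active", "active"))
  expect_equal(cm$fp, 1)
  expect_error(confusion(c(1, 0), c(1)), "equal")
  withr::with_seed(2, {
    y <- rbinom(100, 1, 0.4); p <- rbinom(100, 1, 0.5)
    cm <- confusion(y, p)
    expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 100)
  })
})

test_that("metrics match direct substitution into their formulas", {
  m <- metric_set(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(m), c(mcc = 1, precision = 1, recall = 1,
                            accuracy = 1, specificity = 1, npv = 1))
  m <- metric_set(list(tp = 0, tn = 0, fp = 5, fn = 5))
  expect_equal(m$mcc, -1)
  m <- metric_set(list(tp = 3, tn = 2, fp = 1, fn = 1))
  expect_equal(m$mcc, 5 / 12, tolerance = 1e-12)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$npv, 2 / 3)
})

test_that("zero denominators yield NA, never silent zero", {
  m <- metric_set(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_true(is.na(m$mcc))
  expect_equal(m$accuracy, 1)
})

test_that("prediction polarity swap negates MCC and swaps metric pairs", {
  withr::with_seed(4, {
    for (i in 1:20) {
      y <- rbinom(60, 1, 0.5); p <- rbinom(60, 1, 0.5)
      cm <- confusion(y, p)
      if (any(unlist(cm) == 0)) next
      m <- metric_set(cm)
      mflip <- metric_set(confusion(y, 1 - p))
      expect_equal(mflip$mcc, -m$mcc, tolerance = 1e-12)
      expect_equal(mflip$recall, 1 - m$recall, tolerance = 1e-12)
      expect_equal(mflip$specificity, 1 - m$specificity, tolerance = 1e-12)
    }
  })
})

test_that("accuracy decomposes over class prevalences", {
  withr::with_seed(6, {
    for (i in 1:20) {
      y <- rbinom(80, 1, runif(1, 0.2, 0.8))
      p <- rbinom(80, 1, 0.5)
      cm <- confusion(y, p)
      m <- metric_set(cm)
      P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
      if (P == 0 || N == 0) next
      expect_equal(m$accuracy,
                   (m$recall * P + m$specificity * N) / (P + N),
                   tolerance = 1e-12)
    }
  })
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      y <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
      m <- metric_set(confusion(y, p))
      r <- suppressWarnings(stats::cor(y, p))
      if (is.na(r)) {
        expect_true(is.na(m$mcc))
      } else {
        expect_equal(m$mcc, r, tolerance = 1e-10)
      }
    }
  })
})
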