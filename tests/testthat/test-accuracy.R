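test_that("clopper_pearson matches the bisection oracle and binom.test", {
  for (n in c(1, 2, 5, 11, 12, 29, 33, 45)) {
    for (k in 0:n) {
      got <- unname(clopper_pearson(k, n))
      expect_equal(got, bisect_clopper_pearson(k, n), tolerance = 1e-9,
                   label = sprintf("CP(%d,%d)", k, n))
      expect_equal(got,
                   as.numeric(stats::binom.test(k, n)$conf.int),
                   tolerance = 1e-9)
    }
  }
  # alternative confidence level
  expect_equal(unname(clopper_pearson(3, 10, conf = 0.9)),
               bisect_clopper_pearson(3, 10, conf = 0.9), tolerance = 1e-9)
})

test_that("exact intervals satisfy their boundary invariants", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(0, 0), "k <= n")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:60, 1); k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_true(ci[["lower"]] <= k / n && k / n <= ci[["upper"]])
  }
})

test_that("interval rendering reproduces the printed bound pairs", {
  render <- function(k, n) {
    ci <- clopper_pearson(k, n)
    c(percent_half_up(ci[["lower"]]), percent_half_up(ci[["upper"]]))
  }
  expect_equal(render(6, 12), c(21L, 79L))
  expect_equal(render(8, 11), c(39L, 94L))
  expect_equal(render(29, 29), c(88L, 100L))
  expect_equal(render(8, 8), c(63L, 100L))
  expect_equal(render(0, 10), c(0L, 31L))
  expect_equal(unname(clopper_pearson(0, 10)[2]), 0.3084971, tolerance = 1e-6)
})

test_that("percentages round half away from zero as in the reports", {
  expect_equal(percent_half_up(37 / 40), 93L)
  expect_equal(percent_half_up(35 / 40), 88L)
  expect_equal(percent_half_up(0.5), 50L)
  expect_true(is.na(percent_half_up(NA)))
})

test_that("accuracy_profile computes the five screening metrics", {
  prof <- accuracy_profile(list(tp = 8, fp = 0, fn = 4, tn = 33))
  get <- function(m, f) prof[prof$metric == m, f]
  expect_equal(get("sensitivity", "point"), 8 / 12)
  expect_equal(get("specificity", "point"), 1)
  expect_equal(get("ppv", "point"), 1)
  expect_equal(get("npv", "point"), 33 / 37)
  expect_equal(get("accuracy", "point"), 41 / 45)
  # accuracy * total == tp + tn exactly
  expect_equal(get("accuracy", "point") * 45, 8 + 33)
  prof2 <- accuracy_profile(list(tp = 6, fp = 0, fn = 5, tn = 29))
  expect_equal(prof2[prof2$metric == "npv", "point"], 29 / 34)
  expect_equal(prof2[prof2$metric == "accuracy", "point"], 35 / 40)
})

test_that("zero-denominator metrics are flagged, the rest still returned", {
  prof <- accuracy_profile(list(tp = 0, fp = 0, fn = 0, tn = 10))
  get <- function(m, f) prof[prof$metric == m, f]
  expect_true(is.na(get("sensitivity", "point")))
  expect_true(is.na(get("ppv", "point")))
  expect_equal(get("specificity", "point"), 1)
  expect_equal(get("accuracy", "point"), 1)
  expect_error(accuracy_profile(list(tp = 0, fp = 0, fn = 0, tn = 0)), "empty")
})

test_that("build_table counts reference classes from aligned vectors", {
  calls <- rep(c("positive", "negative"), c(3, 5))
  truths <- c("positive", "positive", "negative", rep("negative", 4),
              "positive")
  tab <- build_table(calls, truths)
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 1L, tn = 4L))
  tab0 <- build_table(rep("negative", 6), rep("negative", 6))
  expect_equal(tab0$tn, 6L)
  expect_error(build_table("positive", c("positive", "negative")), "length")
})

test_that("exact interval coverage is at least nominal (computed exactly)", {
  # coverage of the 95% interval over the full binomial distribution
  n <- 30
  for (p in c(0.1, 0.5, 0.9)) {
    covers <- vapply(0:n, function(k) {
      ci <- clopper_pearson(k, n)
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, TRUE)
    coverage <- sum(stats::dbinom(0:n, n, p)[covers])
    expect_gte(coverage, 0.95)
  }
})

test_that("render_table formats integer-percent cells with em-dash for NA", {
  profs <- list(`PET and CT` = accuracy_profile(list(tp = 8, fp = 0,
                                                     fn = 4, tn = 33)))
  lines <- render_table(profs, "n = 45 patients")
  expect_match(lines[3], "67 \\(35–90\\)")
  expect_match(lines[3], "100 \\(89–100\\)")
  expect_match(lines[3], "91 \\(79–98\\)")
  nodef <- render_table(list(X = accuracy_profile(list(tp = 0, fp = 0,
                                                       fn = 0, tn = 10))))
  expect_match(nodef[3], "—")
})
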