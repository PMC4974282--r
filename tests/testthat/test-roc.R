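test_that("patient scores take the most suspicious lesion per modality", {
  rows <- list(
    quick_patient("A", ct_call = "positive",
                  ct_lesions = lesion_set("lung", c(10, 14), FALSE, c(2L, 4L)),
                  dm_at_screening = TRUE),
    quick_patient("B"))
  co <- as_cohort(rows)
  sc <- patient_scores(co, "ct")
  expect_equal(sc$score, c(4L, 0L))
  expect_equal(sc$truth, c("positive", "negative"))
  expect_equal(nrow(patient_scores(co[0, ], "pet")), 0L)
})

test_that("trapezoidal AUC equals brute-force pair counting", {
  # frozen derived example: 48 of 60 pairs favour the positives
  score <- c(5, 5, 4, 3, 1, 0, 0, 0, 0, 0, 0, 1, 1, 2, 2, 3)
  truth <- rep(c("positive", "negative"), c(6, 10))
  expect_equal(empirical_roc(score, truth)$auc, 0.8)
  expect_equal(pairwise_auc(score, truth), 0.8)
  # property: equality on random instances
  set.seed(31)
  for (i in 1:60) {
    inst <- random_score_instance()
    expect_equal(empirical_roc(inst$score, inst$truth)$auc,
                 pairwise_auc(inst$score, inst$truth), tolerance = 1e-12)
  }
})

test_that("AUC hits its anchors and is invariant to monotone relabelling", {
  perfect <- empirical_roc(c(5, 5, 5, 1, 1, 1),
                           rep(c("positive", "negative"), each = 3))
  expect_equal(perfect$auc, 1)
  same <- empirical_roc(c(0:5, 0:5), rep(c("positive", "negative"), each = 6))
  expect_equal(same$auc, 0.5)
  set.seed(13)
  relabel <- c(0, 2, 3, 7, 10, 40) # strictly increasing map of 0:5
  for (i in 1:25) {
    inst <- random_score_instance()
    expect_equal(empirical_roc(relabel[inst$score + 1], inst$truth,
                               thresholds = c(relabel, 99))$auc,
                 empirical_roc(inst$score, inst$truth)$auc,
                 tolerance = 1e-12)
  }
})

test_that("operating points are monotone and the curve rejects degenerate truth", {
  set.seed(77)
  for (i in 1:20) {
    inst <- random_score_instance()
    pts <- empirical_roc(inst$score, inst$truth)$operating_points
    expect_true(all(diff(pts$sensitivity) <= 1e-12))
    expect_true(all(diff(pts$specificity) >= -1e-12))
  }
  expect_error(empirical_roc(c(1, 2, 3), rep("positive", 3)), "degenerate")
})

test_that("the Q-point maximises Youden's J with a sensitivity tie-break", {
  perfect <- empirical_roc(c(5, 5, 4, 1, 0, 0),
                           rep(c("positive", "negative"), each = 3))
  q <- q_point(perfect)
  expect_equal(q$sensitivity, 1)
  expect_equal(q$specificity, 1)
  expect_equal(q$threshold, 2) # lowest of the tied separating thresholds
  # hand-built curve where two thresholds tie on J: pick the more sensitive
  tied <- list(operating_points = data.frame(
    threshold = 0:3,
    sensitivity = c(1, 0.8, 0.6, 0.2),
    specificity = c(0, 0.4, 0.6, 1)))
  expect_equal(q_point(tied)$threshold, 1)
  # clearly dominated high-specificity point loses
  curve <- list(operating_points = data.frame(
    threshold = c(1, 3),
    sensitivity = c(0.58, 0.40),
    specificity = c(0.94, 0.98)))
  expect_equal(q_point(curve)$threshold, 1)
})

test_that("paired AUC inference reduces sensibly on self-comparison", {
  set.seed(19)
  inst <- random_score_instance()
  inf <- auc_inference(inst$score, inst$score, inst$truth)
  expect_equal(inf$diff, 0)
  expect_equal(inf$p_a_vs_b, 1)
  expect_equal(inf$se_a, inf$se_b)
  expect_equal(inf$cov_ab, inf$se_a^2, tolerance = 1e-12)
  expect_error(auc_inference(inst$score, inst$score[-1], inst$truth),
               "unpaired")
})

test_that("placement-value inference agrees with a permutation reference", {
  # modality a separates perfectly, b is at chance, 20 paired patients
  set.seed(23)
  truth <- rep(c("positive", "negative"), each = 10)
  score_a <- ifelse(truth == "positive", sample(4:5, 20, TRUE),
                    sample(0:1, 20, TRUE))
  score_b <- sample(0:5, 20, TRUE)
  inf <- auc_inference(score_a, score_b, truth)
  expect_lt(inf$p_a_vs_b, 0.05)
  # permutation reference: swap the two modality labels patientwise
  obs <- abs(pairwise_auc(score_a, truth) - pairwise_auc(score_b, truth))
  perm <- replicate(500, {
    swap <- runif(20) < 0.5
    a <- ifelse(swap, score_b, score_a)
    b <- ifelse(swap, score_a, score_b)
    abs(pairwise_auc(a, truth) - pairwise_auc(b, truth))
  })
  expect_lt(mean(perm >= obs - 1e-12), 0.05)
})

test_that("AUC and DeLong-type errors agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  sc <- simulate_paired_scores(120, seed = 8)
  inf <- auc_inference(sc$score_a, sc$score_b, sc$truth)
  resp <- as.integer(sc$truth == "positive")
  ra <- pROC::roc(resp, sc$score_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(resp, sc$score_b, quiet = TRUE, direction = "<")
  expect_equal(inf$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-10)
  expect_equal(inf$auc_b, as.numeric(pROC::auc(rb)), tolerance = 1e-10)
  expect_equal(inf$se_a, sqrt(pROC::var(ra, method = "delong")),
               tolerance = 1e-8)
  cmp <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(inf$p_a_vs_b, cmp$p.value, tolerance = 1e-8)
})
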