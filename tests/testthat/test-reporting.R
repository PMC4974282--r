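test_that("run_accuracy reproduces the reference rows end to end", {
  fx <- build_paper_fixture()
  res <- run_accuracy(fx, set = "evaluable")
  comb <- res$profiles[["PET and CT"]]
  expect_equal(percent_half_up(comb$point),
               c(67L, 100L, 100L, 89L, 91L))
  res40 <- run_accuracy(fx, set = "lrc")
  expect_equal(percent_half_up(res40$profiles[["PET and CT"]]$point),
               c(73L, 100L, 100L, 91L, 93L))
  expect_equal(nrow(res40$set$patients), 40L)
})

test_that("report files are written and byte-identical across reruns", {
  fx <- build_paper_fixture()
  d1 <- tempfile(); d2 <- tempfile()
  run_accuracy(fx, set = "evaluable", out_dir = d1)
  run_accuracy(fx, set = "evaluable", out_dir = d2)
  for (f in c("accuracy.txt", "accuracy.json", "audit.csv",
              "exclusions.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  parsed <- jsonlite::fromJSON(file.path(d1, "accuracy.json"),
                               simplifyVector = FALSE)
  expect_equal(parsed$n, 45L)
  expect_length(parsed$methods, 3L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the audit trail covers every selected patient exactly once", {
  fx <- build_paper_fixture()
  res <- run_accuracy(fx, set = "lrc")
  expect_setequal(res$audit$patient_id, res$set$patients$patient_id)
  expect_equal(anyDuplicated(res$audit$patient_id), 0L)
  expect_true(all(res$audit$class_combined %in% c("TP", "FP", "FN", "TN")))
})

test_that("an all-negative cohort runs with undefined sensitivity cells", {
  co <- as_cohort(lapply(1:8, function(i) quick_patient(paste0("N", i))))
  res <- run_accuracy(co, set = "evaluable")
  sens <- res$profiles$CT[res$profiles$CT$metric == "sensitivity", ]
  expect_true(is.na(sens$point))
  expect_match(res$rendered[3], "—")
  # and the empty analysis set is an explicit error
  expect_error(run_accuracy(co[0, ], set = "evaluable"), "empty")
})

test_that("run_accuracy reads cohorts from disk in both formats", {
  fx <- build_paper_fixture()
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(fx, path)
    res <- run_accuracy(path, set = "evaluable")
    expect_equal(res$tables[["PET and CT"]]$tp, 8L)
    unlink(path)
  }
})

test_that("run_roc is deterministic and rejects one-class truth", {
  co <- simulate_cohort(simulation_params(n_patients = 120, seed = 44))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_roc(co, set = "evaluable", out_dir = d1)
  run_roc(co, set = "evaluable", out_dir = d2)
  expect_identical(readLines(file.path(d1, "roc.json")),
                   readLines(file.path(d2, "roc.json")))
  expect_true(r1$ct$auc >= 0 && r1$ct$auc <= 1)
  neg_only <- simulate_cohort(simulation_params(n_patients = 20, seed = 2,
                                                dm_prevalence = 0))
  expect_error(run_roc(neg_only, set = "evaluable"), "one truth class")
  # fixture smoke contract: runs and emits curves (scores are
  # reconstruction artifacts, values not asserted)
  fr <- run_roc(build_paper_fixture(), set = "evaluable")
  expect_s3_class(fr$ct, "dm_roc")
  expect_s3_class(fr$pet, "dm_roc")
  unlink(c(d1, d2), recursive = TRUE)
})
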