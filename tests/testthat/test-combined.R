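test_that("rule table matches a hand-enumerated oracle over the full grid", {
  # admissible cells: PET x CT x {sub-limit, at/above limit, absent}
  grid <- expand.grid(pet = c("positive", "negative"),
                      ct = c("positive", "negative"),
                      size = c(3, 4.9, 5, 11, NA),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$ct == "positive" & is.na(grid$size)), ]
  oracle <- function(pet, ct, size) {
    if (pet == "positive" && ct == "positive") c("positive", "both_positive")
    else if (pet == "positive") c("positive", "pet_only_positive")
    else if (ct == "positive" && size < 5) c("positive", "ct_small_lesion")
    else if (ct == "positive") c("negative", "ct_large_lesion_discounted")
    else c("negative", "both_negative")
  }
  for (i in seq_len(nrow(grid))) {
    got <- classify_pair(grid$pet[i], grid$ct[i], grid$size[i])
    want <- oracle(grid$pet[i], grid$ct[i], grid$size[i])
    expect_identical(c(got$call, got$rule_fired), want,
                     label = paste(grid[i, ], collapse = "/"))
  }
})

test_that("the published discordant readings classify as reported", {
  # both positive: metastasis very likely, any size
  expect_equal(classify_pair("positive", "positive", 18)$rule_fired,
               "both_positive")
  # 15-mm PET-negative lung lesion is discounted
  r15 <- classify_pair("negative", "positive", 15)
  expect_equal(r15$call, "negative")
  expect_equal(r15$rule_fired, "ct_large_lesion_discounted")
  # multiple 4-mm lesions below the PET detection limit stay positive
  r4 <- classify_pair("negative", "positive", 4)
  expect_equal(r4$call, "positive")
  expect_equal(r4$rule_fired, "ct_small_lesion")
  # PET positivity dominates regardless of CT
  expect_equal(classify_pair("positive", "negative")$call, "positive")
  # no findings at all
  expect_equal(classify_pair("negative", "negative")$rule_fired,
               "both_negative")
  # the cut is strict: exactly 5 mm is not below the detection limit
  expect_equal(classify_pair("negative", "positive", 5)$call, "negative")
  expect_equal(classify_pair("negative", "positive", 4.999)$call, "positive")
})

test_that("a positive CT without a lesion size is a contract error", {
  expect_error(classify_pair("negative", "positive"), "size")
  expect_error(classify_pair("negative", "positive", -3), "positive")
  ct <- modality_reading("positive", no_lesions(), "ct")
  pet <- modality_reading("negative", modality = "pet")
  expect_error(classify_patient(ct, pet), "size")
})

test_that("PET dominance and monotonicity hold on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    ct <- sample(c("positive", "negative"), 1)
    size <- if (ct == "positive") round(runif(1, 1, 25), 1) else NA
    neg <- classify_pair("negative", ct, size)
    pos <- classify_pair("positive", ct, size)
    # switching PET to positive never flips positive -> negative
    expect_false(neg$call == "positive" && pos$call == "negative")
    expect_equal(pos$call, "positive") # dominance
    if (ct == "positive" && size < 5)
      expect_equal(neg$call, "positive") # sub-limit CT dominance
  }
})

test_that("classify_patient extracts calls and the minimum lesion size", {
  # 6-mm lesion scored benign on CT, PET positive at the site: positive
  ct6 <- modality_reading("negative", lesion_set("lung", 6, FALSE, 2L), "ct")
  pet6 <- modality_reading("positive", lesion_set("lung", NA, FALSE, 4L), "pet")
  got <- classify_patient(ct6, pet6)
  expect_equal(got$call, "positive")
  expect_equal(got$rule_fired, "pet_only_positive")
  # several suspicious lesions: the smallest one drives the branch
  ct_multi <- modality_reading("positive",
                               lesion_set("lung", c(4, 7), TRUE, c(4L, 3L)),
                               "ct")
  pet_neg <- modality_reading("negative", modality = "pet")
  expect_equal(classify_patient(ct_multi, pet_neg)$rule_fired,
               "ct_small_lesion")
  # nothing on either modality
  expect_equal(classify_patient(modality_reading("negative", modality = "ct"),
                                pet_neg)$call, "negative")
})

test_that("combined_calls fires exactly one rule per patient on the fixture", {
  fx <- build_paper_fixture()
  cc <- combined_calls(fx)
  expect_equal(nrow(cc), 47L)
  expect_true(all(cc$rule_fired %in% c("both_positive", "pet_only_positive",
                                       "ct_small_lesion",
                                       "ct_large_lesion_discounted",
                                       "both_negative")))
  expect_equal(as.list(table(cc$rule_fired))[
    c("both_positive", "pet_only_positive", "ct_small_lesion",
      "ct_large_lesion_discounted")],
    list(both_positive = 4L, pet_only_positive = 2L,
         ct_small_lesion = 2L, ct_large_lesion_discounted = 1L))
})
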